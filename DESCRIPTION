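Package: nnipheno
Title: Image-Based Nitrogen Nutrition Index Phenotyping for Leafy Vegetables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing plant nitrogen status from top-view RGB
    images of rosette-forming leafy vegetables such as pakchoi. Segments
    plants from a bright background with an excess-green-index band and a
    brightness threshold, extracts 65 colour, grey-level co-occurrence
    texture and contour-geometry features, computes the nitrogen nutrition
    index (NNI) from a critical nitrogen dilution curve, screens features by
    per-date one-way ANOVA, and trains and evaluates random-forest,
    support-vector and neural-network regressors of NNI. Includes a
    synthetic top-view image generator with known ground-truth NNI so the
    whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage,
    randomForest,
    e1071,
    nnet,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
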