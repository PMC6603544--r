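#' Names of the 65 phenotypic features
#'
#' Ordered feature names: 45 colour statistics (mean, population standard
#' deviation, median, range and coefficient of variation for each of the R,
#' G, B; L, a, b; H, S, V channels), 6 grey-level co-occurrence texture
#' features and 14 contour-geometry features.
#'
#' @return character vector of length 65.
#' @export
feature_names <- function() {
  channels <- c("R", "G", "B", "L", "a", "b", "H", "S", "V")
  stats <- c("mean", "std", "median", "range", "cv")
  col <- as.vector(t(outer(channels, stats, paste, sep = "_")))
  tex <- c("contrast", "dissimilarity", "homogeneity", "energy",
           "correlation", "ASM")
  geo <- c("contour_area", "perimeter", "w", "h", "hull_area",
           "rect_w", "rect_h", "MA", "ma", "r", "equivalent_diameter",
           "aspect_ratio", "extent", "solidity")
  c(col, tex, geo)
}

#' Feature presets
#'
#' `"paper23"` is the published screened set: the 23 features that were
#' significant (p < 0.05) across all six sampling dates in the pakchoi
#' study — 16 colour, 3 texture (homogeneity, energy, ASM) and 4 geometry
#' features. Usable downstream without re-running the screening.
#'
#' @param name preset name; currently only `"paper23"`.
#' @return character vector of feature names.
#' @export
preset_features <- function(name = "paper23") {
  name <- match.arg(name)
  idx <- c(1, 3, 6, 8, 11, 13, 16, 18, 26, 28, 31, 33, 36, 38, 41, 43,
           48, 49, 51, 52, 56, 61, 62)
  feature_names()[idx]
}

#' Category of each feature
#'
#' @param names feature names (default all 65).
#' @return factor with levels colour, texture, morphology.
#' @export
feature_category <- function(names = feature_names()) {
  all <- feature_names()
  idx <- match(names, all)
  if (anyNA(idx)) stop("unknown feature name(s): ",
                       paste(names[is.na(idx)], collapse = ", "))
  factor(ifelse(idx <= 45, "colour", ifelse(idx <= 51, "texture",
                                            "morphology")),
         levels = c("colour", "texture", "morphology"))
}

#' Published shoot growth records (pakchoi pot trial)
#'
#' Treatment-by-date means and standard deviations (n = 3) of shoot dry
#' biomass (g/plant) and shoot nitrogen concentration (g/kg DW) for four
#' nitrogen doses (CK = 0, T1 = 0.134, T2 = 0.163, T3 = 0.191 g N/pot)
#' sampled 7-42 days after the first application.
#'
#' @return data.frame with columns treatment, dose, day, biomass_dm,
#'   biomass_sd, n_conc, n_conc_sd, n.
#' @export
reference_growth <- function() {
  trt <- c("CK", "T1", "T2", "T3")
  dose <- c(0, 0.134, 0.163, 0.191)
  day <- c(7, 14, 21, 28, 35, 42)
  biomass <- c(0.065, 0.161, 0.186, 0.338, 0.479, 0.617,
               0.067, 0.174, 0.293, 0.580, 0.973, 1.363,
               0.080, 0.189, 0.306, 0.574, 0.994, 1.280,
               0.079, 0.215, 0.440, 0.620, 0.970, 1.282)
  biomass_sd <- c(0.007, 0.006, 0.008, 0.012, 0.037, 0.037,
                  0.004, 0.019, 0.010, 0.023, 0.019, 0.032,
                  0.004, 0.023, 0.014, 0.018, 0.051, 0.025,
                  0.010, 0.011, 0.025, 0.014, 0.017, 0.027)
  n_conc <- c(43.30, 39.70, 39.07, 30.80, 20.50, 20.50,
              57.50, 61.27, 69.63, 67.30, 72.70, 83.77,
              57.63, 62.20, 74.87, 71.97, 81.87, 88.07,
              60.57, 64.00, 73.30, 76.63, 79.47, 88.80)
  n_conc_sd <- c(2.31, 2.76, 1.59, 1.57, 1.08, 0.79,
                 0.26, 1.01, 1.90, 0.17, 2.66, 2.57,
                 0.85, 1.23, 2.25, 0.99, 1.65, 2.67,
                 1.27, 0.85, 4.98, 0.50, 0.74, 2.11)
  data.frame(
    treatment = rep(trt, each = 6),
    dose = rep(dose, each = 6),
    day = rep(day, times = 4),
    biomass_dm = biomass,
    biomass_sd = biomass_sd,
    n_conc = n_conc,
    n_conc_sd = n_conc_sd,
    n = 3L,
    stringsAsFactors = FALSE
  )
}

#' Published per-date critical nitrogen concentrations
#'
#' Critical shoot N concentration (g/kg DW) at each sampling date, derived
#' in the source study from the N-limiting treatment's dilution curve and
#' the non-N-limiting treatments' biomass.
#'
#' @return data.frame with columns day, nc.
#' @export
reference_nc <- function() {
  data.frame(day = c(7, 14, 21, 28, 35, 42),
             nc = c(56.08, 63.36, 69.16, 72.14, 76.44, 79.46))
}

#' Published NNI reference table
#'
#' The printed per-treatment, per-date NNI values. One printed cell (CK at
#' day 21, 0.57) differs by one unit in the second decimal from the ratio
#' of its own printed inputs (39.07/69.16 = 0.56); `matches_inputs` flags
#' which cells agree with the Nt/Nc ratio of the printed inputs.
#'
#' @return data.frame with columns treatment, day, nni, matches_inputs.
#' @export
reference_nni <- function() {
  trt <- c("CK", "T1", "T2", "T3")
  day <- c(7, 14, 21, 28, 35, 42)
  nni <- c(0.77, 0.63, 0.57, 0.43, 0.27, 0.26,
           1.03, 0.97, 1.01, 0.93, 0.95, 1.05,
           1.03, 0.98, 1.08, 1.00, 1.07, 1.11,
           1.08, 1.01, 1.06, 1.06, 1.04, 1.12)
  out <- data.frame(treatment = rep(trt, each = 6),
                    day = rep(day, times = 4),
                    nni = nni)
  out$matches_inputs <- !(out$treatment == "CK" & out$day == 21)
  out
}
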