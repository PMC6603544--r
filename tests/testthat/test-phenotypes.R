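test_that("colour statistics match hand arithmetic on a two-pixel mask", {
  img <- flat_image(2, 2, c(0, 0, 0))
  img[1, 1, ] <- c(10, 80, 5)
  img[1, 2, ] <- c(30, 80, 5)
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # the two top pixels
  fv <- color_features(img, mask)
  expect_equal(unname(fv["R_mean"]), 20)
  expect_equal(unname(fv["R_std"]), 10)      # population sd
  expect_equal(unname(fv["R_median"]), 20)
  expect_equal(unname(fv["R_range"]), 20)
  expect_equal(unname(fv["R_cv"]), 0.5)
  expect_length(fv, 45)
})

test_that("uniform regions have zero dispersion in every channel", {
  img <- flat_image(10, 10, c(60, 160, 60))
  mask <- matrix(TRUE, 10, 10)
  fv <- color_features(img, mask)
  stats <- c("std", "range", "cv")
  for (ch in c("R", "G", "B", "L", "a", "b", "H", "S", "V"))
    for (s in stats)
      expect_equal(unname(fv[paste(ch, s, sep = "_")]), 0)
  expect_error(color_features(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("hue moves toward deeper green as greenness rises", {
  lo <- render_at_nni(0.4, seed = 9)
  hi <- render_at_nni(1.1, seed = 9)
  f_lo <- color_features(lo$image, lo$truth_mask)
  f_hi <- color_features(hi$image, hi$truth_mask)
  # H is on the half-degree scale: deep green 120 deg = 60, pale 80 deg = 40
  expect_gt(unname(f_hi["H_mean"]), unname(f_lo["H_mean"]))
  # direct per-pixel cross-check of the mean hue
  px <- which(hi$truth_mask)
  hsv <- grDevices::rgb2hsv(rbind(hi$image[, , 1][px], hi$image[, , 2][px],
                                  hi$image[, , 3][px]), maxColorValue = 255)
  expect_equal(unname(f_hi["H_mean"]), mean(hsv[1, ] * 180))
})

test_that("uniform grey patches give degenerate texture values", {
  img <- flat_image(6, 6, c(100, 100, 100))
  mask <- matrix(TRUE, 6, 6)
  fv <- texture_features(img, mask)
  expect_equal(unname(fv["contrast"]), 0)
  expect_equal(unname(fv["dissimilarity"]), 0)
  expect_equal(unname(fv["homogeneity"]), 1)
  expect_equal(unname(fv["ASM"]), 1)
  expect_equal(unname(fv["energy"]), 1)
  expect_equal(unname(fv["correlation"]), 1)  # convention, flagged
  expect_true(attr(fv, "degenerate_correlation"))
})

test_that("texture features equal the exhaustive-pair oracle", {
  withr::with_seed(42, {
    cases <- list(
      list(n = 4, levels = 2, distance = 1, angles = c(0, 45, 90, 135)),
      list(n = 6, levels = 4, distance = 1, angles = c(0, 90)),
      list(n = 8, levels = 8, distance = 2, angles = c(45, 135)),
      list(n = 8, levels = 256, distance = 1, angles = c(0, 45, 90, 135))
    )
    for (cs in cases) {
      g <- matrix(sample(0:255, cs$n^2, replace = TRUE), cs$n, cs$n)
      img <- array(rep(g, 3), dim = c(cs$n, cs$n, 3))
      mask <- matrix(runif(cs$n^2) < 0.8, cs$n, cs$n)
      mask[2:3, 2:3] <- TRUE  # guarantee pairs
      got <- texture_features(img, mask,
                              glcm_params(distance = cs$distance,
                                          angles = cs$angles,
                                          levels = cs$levels))
      want <- glcm_oracle(g, mask, cs$distance, cs$angles, cs$levels)
      expect_equal(unname(got), unname(want[names(got)]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(unname(got["energy"])^2, unname(got["ASM"]),
                   tolerance = 1e-12)
    }
  })
})

test_that("checkerboard texture matches the oracle and intuition", {
  g <- matrix(rep(c(0, 255), length.out = 16), 4, 4)  # alternating rows
  img <- array(rep(g, 3), dim = c(4, 4, 3))
  mask <- matrix(TRUE, 4, 4)
  got <- texture_features(img, mask, glcm_params(levels = 2))
  want <- glcm_oracle(g, mask, 1, c(0, 45, 90, 135), 2)
  expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(got["contrast"], 0)
  expect_lt(got["homogeneity"], 1)
})

test_that("square geometry matches closed forms", {
  s <- 50
  m <- square_mask(80, s)
  g <- geometry_features(m)
  expect_equal(unname(g["contour_area"]), s^2)
  expect_equal(unname(g["w"]), s)
  expect_equal(unname(g["h"]), s)
  expect_equal(unname(g["aspect_ratio"]), 1)
  expect_equal(unname(g["extent"]), 1)
  expect_equal(unname(g["hull_area"]), s^2)
  expect_equal(unname(g["solidity"]), 1)
  expect_equal(unname(g["equivalent_diameter"]), s * sqrt(4 / pi))
  expect_equal(unname(g["perimeter"]), 4 * (s - 1))  # boundary chain
  expect_equal(unname(g["rect_w"]) * unname(g["rect_h"]), s^2,
               tolerance = 1e-9)
  # min enclosing circle of the square: half diagonal of the s x s extent
  expect_equal(unname(g["r"]), s * sqrt(2) / 2, tolerance = 0.02)
})

test_that("disc geometry is within 2% of closed forms", {
  r0 <- 50
  m <- disc_mask(121, r0)
  g <- geometry_features(m)
  expect_equal(unname(g["r"]), r0, tolerance = 0.02)
  expect_equal(unname(g["equivalent_diameter"]), 2 * r0, tolerance = 0.02)
  expect_equal(unname(g["solidity"]), 1, tolerance = 0.02)
  # bounding box of a rasterised disc spans 2r + 1 pixels
  expect_equal(unname(g["extent"]), pi * r0^2 / (2 * r0 + 1)^2,
               tolerance = 0.01)
  expect_equal(unname(g["hull_area"]), pi * r0^2, tolerance = 0.02)
  expect_equal(unname(g["MA"]), 2 * r0, tolerance = 0.02)
  expect_equal(unname(g["ma"]), 2 * r0, tolerance = 0.02)
})

test_that("geometry respects hull bounds and the calibration scale", {
  withr::with_seed(5, {
    for (k in 1:4) {
      rs <- render_at_nni(runif(1, 0.3, 1.1), biomass = runif(1, 0.1, 0.8),
                          seed = k)
      g <- geometry_features(rs$truth_mask)
      expect_lte(g[["solidity"]], 1)
      expect_gte(g[["hull_area"]], g[["contour_area"]])
    }
  })
  m <- disc_mask(61, 20)
  g1 <- geometry_features(m, mm_per_px = 1)
  g2 <- geometry_features(m, mm_per_px = 0.5)
  expect_equal(unname(g2["contour_area"]), unname(g1["contour_area"]) / 4)
  expect_equal(unname(g2["r"]), unname(g1["r"]) / 2)
  expect_equal(unname(g2["solidity"]), unname(g1["solidity"]))
})

test_that("tiny components fall back to rectangle-based ellipse axes", {
  m <- matrix(FALSE, 10, 10)
  m[5, 4:6] <- TRUE  # 3 pixels
  g <- geometry_features(m)
  expect_true(attr(g, "ellipse_fallback"))
  expect_gte(g[["MA"]], g[["ma"]])
  # secondary components are dropped with a warning
  m2 <- m; m2[1, 1] <- TRUE
  expect_warning(geometry_features(m2), "secondary")
})

test_that("the full vector has 65 named features and is translation invariant", {
  rs <- render_at_nni(0.7, biomass = 0.3, seed = 77, canvas = c(160, 160))
  fv <- extract_features(rs$image, rs$truth_mask)
  expect_length(fv, 65)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(rs$image, rs$truth_mask))
  # rigid translation by (6, 9): every feature unchanged
  H <- dim(rs$image)[1]; W <- dim(rs$image)[2]
  img2 <- array(235, dim = dim(rs$image))
  img2[7:H, 10:W, ] <- rs$image[1:(H - 6), 1:(W - 9), ]
  mask2 <- matrix(FALSE, H, W)
  mask2[7:H, 10:W] <- rs$truth_mask[1:(H - 6), 1:(W - 9)]
  expect_false(any(rs$truth_mask[(H - 5):H, ]) ||
                 any(rs$truth_mask[, (W - 8):W]))  # nothing clipped
  fv2 <- extract_features(img2, mask2)
  expect_equal(fv2, fv, tolerance = 1e-12)
})

test_that("90-degree rotation preserves rotation-invariant geometry", {
  rs <- render_at_nni(0.9, biomass = 0.3, seed = 13, canvas = c(160, 160))
  g1 <- geometry_features(rs$truth_mask)
  rot <- t(rs$truth_mask)[ncol(rs$truth_mask):1, ]
  g2 <- geometry_features(rot)
  for (f in c("contour_area", "hull_area", "r", "equivalent_diameter",
              "solidity"))
    expect_equal(g2[[f]], g1[[f]], tolerance = 0.01)
})

test_that("the published preset is 23 features split 16/3/4", {
  p <- preset_features("paper23")
  expect_length(p, 23)
  expect_true(all(p %in% feature_names()))
  cat3 <- table(feature_category(p))
  expect_equal(unname(cat3[["colour"]]), 16)
  expect_equal(unname(cat3[["texture"]]), 3)
  expect_equal(unname(cat3[["morphology"]]), 4)
  expect_setequal(p[feature_category(p) == "texture"],
                  c("homogeneity", "energy", "ASM"))
})
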