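# replicate reconstruction: c(m - s, m, m + s) has mean m and sample sd s,
# letting the published per-cell means/SDs (n = 3) be expanded into records
expand_reference <- function(growth = reference_growth()) {
  do.call(rbind, lapply(seq_len(nrow(growth)), function(i) {
    g <- growth[i, ]
    data.frame(treatment = g$treatment, dose = g$dose, day = g$day,
               replicate = 1:3,
               biomass_dm = g$biomass_dm + g$biomass_sd * c(-1, 0, 1),
               n_conc = g$n_conc + g$n_conc_sd * c(-1, 0, 1))
  }))
}

test_that("NNI is the plain ratio of Nt to Nc with half-up reporting", {
  expect_equal(round_half_up(compute_nni(57.50, 56.08), 2), 1.03)
  expect_equal(round_half_up(compute_nni(71.97, 72.14), 2), 1.00)
  expect_equal(round_half_up(compute_nni(20.50, 79.46), 2), 0.26)
  expect_equal(compute_nni(60, 60), 1)
  # scale invariance
  expect_equal(compute_nni(3 * 57.5, 3 * 56.08), compute_nni(57.5, 56.08))
  expect_error(compute_nni(50, 0), "positive")
})

test_that("the published NNI table is reproduced from its inputs", {
  growth <- reference_growth()
  out <- nni_table(growth, nc_values = reference_nc())
  ref <- reference_nni()
  m <- merge(out, ref, by = c("treatment", "day"),
             suffixes = c("_got", "_ref"))
  expect_equal(nrow(m), 24)
  consistent <- m$matches_inputs
  expect_equal(sum(consistent), 23)
  expect_equal(m$nni_got[consistent], m$nni_ref[consistent])
  # the one internally inconsistent printed cell: the ratio of its printed
  # inputs is 0.56, one unit below the printed 0.57
  odd <- m[!consistent, ]
  expect_equal(odd$nni_got, 0.56)
  expect_equal(odd$nni_ref, 0.57)
  # status labels follow the table's rule
  expect_equal(as.character(out$status[out$treatment == "T3" &
                                         out$day == 42]), "excessive")
  expect_equal(as.character(out$status[out$treatment == "CK" &
                                         out$day == 28]), "deficient")
  expect_equal(as.character(out$status[out$treatment == "T2" &
                                         out$day == 28]), "optimal")
})

test_that("status classification splits at the optimal band", {
  expect_equal(as.character(classify_status(c(1.12, 1.000, 0.43))),
               c("excessive", "optimal", "deficient"))
  expect_equal(as.character(classify_status(1.005)), "optimal")
  expect_equal(as.character(classify_status(1.006)), "excessive")
  expect_error(classify_status(-0.1), ">= 0")
})

test_that("dilution-curve fitting recovers exact parameters", {
  dm <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  nc <- 75 * dm^0.11
  fit <- fit_dilution_curve(dm, nc)
  expect_equal(fit$a, 75, tolerance = 1e-9)
  expect_equal(fit$b, 0.11, tolerance = 1e-9)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)
  expect_error(fit_dilution_curve(c(1, 1), c(2, 2)), "3 points")
  expect_error(fit_dilution_curve(c(1, 1, 1), c(2, 2, 2)), "degenerate")
  expect_error(fit_dilution_curve(c(-1, 1, 2), c(2, 2, 2)), "positive")
})

test_that("the generator's curve is recovered from noiseless trajectories", {
  d <- agronomic_design(seed = 8)
  tr <- generate_trajectories(d, noise_cv = 0)
  # implied critical concentration of each record: Nc = Nt / NNI
  fit <- fit_dilution_curve(tr$biomass_dm, tr$n_conc / tr$nni_true)
  gen <- generator_curve()
  expect_equal(fit$a, gen$a, tolerance = 1e-6)
  expect_equal(fit$b, gen$b, tolerance = 1e-6)
})

test_that("the exponent is recovered within 0.02 under 2% noise", {
  withr::with_seed(2024, {
    dm <- exp(runif(50, log(0.05), log(1.5)))
    nc <- 75 * dm^0.11 * (1 + rnorm(50, 0, 0.02))
    fit <- fit_dilution_curve(dm, nc)
    expect_lt(abs(fit$b - 0.11), 0.02)
  })
})

test_that("critical_n evaluates the power curve", {
  flat <- structure(list(a = 70, b = 0), class = "dilution_curve")
  expect_equal(critical_n(flat, c(0.1, 1, 10)), c(70, 70, 70))
  curve <- structure(list(a = 75.9, b = 0.108), class = "dilution_curve")
  expect_equal(critical_n(curve, 1), 75.9)
  expect_equal(critical_n(curve, 0.080), 75.9 * 0.080^0.108)
  expect_error(critical_n(curve, 0), "positive")
})

test_that("dose-responsive synthetic data yields limiting labels below the top dose", {
  withr::with_seed(31, {
    doses <- c(A = 0, B = 0.1, C = 0.2)
    recs <- expand.grid(replicate = 1:4, day = c(7, 14), dose = doses)
    recs$treatment <- names(doses)[match(recs$dose, doses)]
    recs$biomass_dm <- (0.2 + recs$dose) * (1 + recs$day / 20) *
      (1 + rnorm(nrow(recs), 0, 0.01))
    lim <- classify_limiting(recs, alpha = 0.05)
    expect_equal(lim$n_limiting, c(TRUE, TRUE, FALSE))
    # cross-check the omnibus test against a direct F-test at day 7
    sub <- recs[recs$day == 7, ]
    p_direct <- anova(lm(biomass_dm ~ factor(dose), sub))[["Pr(>F)"]][1]
    expect_lt(p_direct, 0.05)
  })
})

test_that("flat biomass yields no limiting treatment and single reps error", {
  recs <- expand.grid(replicate = 1:3, day = c(7, 14),
                      dose = c(A = 0, B = 0.1))
  recs$treatment <- ifelse(recs$dose == 0, "A", "B")
  recs$biomass_dm <- 0.5
  lim <- classify_limiting(recs)
  expect_false(any(lim$n_limiting))
  one <- recs[recs$replicate == 1, ]
  expect_error(classify_limiting(one), "replicates")
})

test_that("published growth pattern marks the second dose as N-limiting", {
  recs <- expand_reference()
  lim <- classify_limiting(recs, alpha = 0.05)
  expect_true(lim$n_limiting[lim$treatment == "T1"])
  expect_false(lim$n_limiting[lim$treatment == "T3"])
  per_date <- attr(lim, "per_date")
  # limiting through day 28, saturating afterwards
  expect_true(all(per_date["T1", c("7", "14", "21", "28")]))
  expect_false(any(per_date["T1", c("35", "42")]))
})
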