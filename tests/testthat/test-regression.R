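# small synthetic regression problem: linear signal in two features plus
# pure-noise distractors
make_problem <- function(n = 120, seed = 5, noise = 0.02) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- 0.8 + 0.2 * x[, 1] + 0.1 * x[, 2] + rnorm(n, 0, noise)
  })
  list(x = x, y = y)
}

test_that("the split applies half-up rounding, partitions, and reproduces", {
  s <- split_dataset(382, train_frac = 0.75, seed = 1)
  expect_length(s$train, 287)
  expect_length(s$test, 95)
  expect_setequal(c(s$train, s$test), 1:382)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(split_dataset(382, seed = 7), split_dataset(382, seed = 7))
  expect_false(identical(split_dataset(382, seed = 7)$train,
                         split_dataset(382, seed = 8)$train))
  expect_error(split_dataset(5), "at least 8")
  expect_error(split_dataset(100, train_frac = 1.2), "train_frac")
})

test_that("default grids match the published search spaces", {
  g <- default_grid("svr")
  expect_length(g$cost, 17)
  expect_length(g$gamma, 17)
  expect_equal(sort(g$cost), sort(2^(-8:8)))
  expect_equal(min(g$cost), 0.00390625)
  expect_equal(max(g$gamma), 256)
  expect_equal(default_grid("rf"), list(ntree = 300, mtry = c(2, 5, 8)))
  expect_equal(default_grid("nn"),
               list(decay = c(0, 0.1, 0.01), size = c(2, 5, 9)))
})

test_that("cross-validation finds near-zero RMSE on constant targets", {
  withr::with_seed(2, {
    x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  y <- rep(0.8, 60)
  # randomForest warns about degenerate targets; the degenerate case is
  # exactly what is under test here
  cv <- suppressWarnings(
    cross_validate(x, y, "rf", grid = list(ntree = 50, mtry = c(1, 2)),
                   folds = 5, seed = 3))
  expect_lt(min(cv$table$rmse_mean), 1e-6)
  expect_true(all(cv$table$rmse_sd >= 0))
  expect_error(cross_validate(x, y, "rf", grid = list()), "empty grid")
})

test_that("cross-validation is reproducible and picks a grid candidate", {
  pr <- make_problem(n = 80)
  grid <- list(cost = c(0.25, 4, 64), gamma = c(0.03125, 0.5))
  cv1 <- cross_validate(pr$x, pr$y, "svr", grid = grid, folds = 5, seed = 9)
  cv2 <- cross_validate(pr$x, pr$y, "svr", grid = grid, folds = 5, seed = 9)
  expect_identical(cv1$table, cv2$table)
  expect_identical(cv1$best, cv2$best)
  expect_true(cv1$best$cost %in% grid$cost)
  expect_true(cv1$best$gamma %in% grid$gamma)
  expect_equal(min(cv1$table$rmse_mean),
               cv1$table$rmse_mean[which(cv1$table$cost == cv1$best$cost &
                                           cv1$table$gamma == cv1$best$gamma)])
})

test_that("models are deterministic under a fixed seed", {
  pr <- make_problem()
  for (alg in c("rf", "svr", "nn")) {
    params <- switch(alg, rf = list(ntree = 100, mtry = 2),
                     svr = list(cost = 4, gamma = 0.1),
                     nn = list(decay = 0.01, size = 5))
    m1 <- train_nni_model(pr$x, pr$y, alg, params, seed = 42)
    m2 <- train_nni_model(pr$x, pr$y, alg, params, seed = 42)
    expect_identical(predict_nni(m1, pr$x), predict_nni(m2, pr$x),
                     info = alg)
    expect_true(all(is.finite(predict_nni(m1, pr$x))), info = alg)
  }
})

test_that("forest predictions stay within the training target range", {
  pr <- make_problem()
  m <- train_nni_model(pr$x, pr$y, "rf", list(ntree = 100, mtry = 2),
                       seed = 1)
  new_x <- pr$x * 3  # extrapolation probe
  p <- predict_nni(m, new_x)
  expect_true(all(p >= min(pr$y) & p <= max(pr$y)))
})

test_that("the neural network trains to finite weights with decay 0.01, size 5", {
  pr <- make_problem()
  m <- train_nni_model(pr$x, pr$y, "nn", list(decay = 0.01, size = 5),
                       seed = 4)
  expect_true(all(is.finite(m$fit$wts)))
  p <- predict_nni(m, pr$x)
  # logistic output unit: predictions live in (0, 1)
  expect_true(all(p > 0 & p < 1))
  expect_lt(rmse <- sqrt(mean((pr$y - p)^2)), 0.2)
})

test_that("prediction validates features and handles empty input", {
  pr <- make_problem()
  m <- train_nni_model(pr$x, pr$y, "svr", list(cost = 4, gamma = 0.2))
  expect_error(predict_nni(m, pr$x[, 1:3]), "missing feature.*f4")
  expect_identical(predict_nni(m, pr$x[0, , drop = FALSE]), numeric(0))
  # extra columns are ignored
  xx <- cbind(as.data.frame(pr$x), junk = 1)
  expect_length(predict_nni(m, xx), nrow(pr$x))
})

test_that("permutation importance separates signal from noise", {
  pr <- make_problem(n = 150, noise = 0.01)
  x <- cbind(pr$x, konst = 1)
  m <- train_nni_model(x, pr$y, "rf", list(ntree = 150, mtry = 2), seed = 6)
  imp <- feature_importance(m, x, pr$y, n_permutations = 5, seed = 7)
  expect_s3_class(imp, "importance_table")
  # constant feature: permutation changes nothing, importance exactly 0
  expect_equal(imp$importance[imp$feature == "konst"], 0)
  # the strongest generator feature ranks first, noise features near zero
  expect_equal(imp$feature[1], "f1")
  noise_imp <- imp$importance[imp$feature %in% c("f3", "f4", "f5")]
  expect_lt(max(noise_imp), imp$importance[imp$feature == "f2"])
  expect_error(feature_importance(m, x, pr$y, n_permutations = 0), ">= 1")
})
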