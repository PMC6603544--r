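# NNI regressors: random forest, RBF support-vector regression and a
# single-hidden-layer neural network, with grid search by 10-fold
# cross-validation minimising RMSE, and permutation feature importance.

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' Random 75/25 train/test split
#'
#' @param n number of samples (or a data.frame, whose rows are split).
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (and the
#'   split data.frames when a data.frame was supplied). The training size
#'   is `train_frac * n` rounded half up.
#' @export
split_dataset <- function(n, train_frac = 0.75, seed = 1) {
  df <- NULL
  if (is.data.frame(n)) { df <- n; n <- nrow(df) }
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (n < 8) stop("need at least 8 samples")
  n_train <- as.integer(floor(train_frac * n + 0.5))
  train <- withr::with_seed(seed, sort(sample.int(n, n_train)))
  test <- setdiff(seq_len(n), train)
  out <- list(train = train, test = test)
  if (!is.null(df)) {
    out$train_data <- df[train, , drop = FALSE]
    out$test_data <- df[test, , drop = FALSE]
  }
  out
}

#' Default hyperparameter grids
#'
#' RF: 300 trees with mtry 2, 5, 8. SVR (RBF): cost and gamma each over
#' the 17 powers of two from 2^-8 to 2^8. NN: weight decay 0, 0.1, 0.01
#' crossed with hidden-layer size 2, 5, 9.
#'
#' @param algorithm one of `"rf"`, `"svr"`, `"nn"`.
#' @return named list of candidate values.
#' @export
default_grid <- function(algorithm = c("rf", "svr", "nn")) {
  switch(match.arg(algorithm),
         rf = list(ntree = 300, mtry = c(2, 5, 8)),
         svr = list(cost = 2^(-8:8), gamma = 2^(-8:8)),
         nn = list(decay = c(0, 0.1, 0.01), size = c(2, 5, 9)))
}

# candidate table ordered so that the first RMSE minimum is the most
# parsimonious candidate (smallest mtry / cost / size first)
.candidates <- function(algorithm, grid) {
  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  key <- switch(algorithm, rf = "mtry", svr = "cost", nn = "size")
  ord <- do.call(order, cand[, c(key, setdiff(names(cand), key)),
                             drop = FALSE])
  cand[ord, , drop = FALSE]
}

#' Train one NNI regressor
#'
#' Features are z-scored with the training statistics (stored in the model
#' and re-applied at prediction time). The neural network uses a logistic
#' output unit by default, so its predictions live in (0, 1); set
#' `linout = TRUE` for a linear output.
#'
#' @param x numeric matrix/data.frame of features (named columns).
#' @param y numeric NNI targets.
#' @param algorithm `"rf"`, `"svr"` or `"nn"`.
#' @param params named list of hyperparameters (see [default_grid()]).
#' @param seed integer seed (RF and NN are stochastic).
#' @param linout linear NN output instead of logistic.
#' @return object of class `nni_model`.
#' @export
train_nni_model <- function(x, y, algorithm = c("rf", "svr", "nn"),
                            params = list(), seed = 1, linout = FALSE) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("non-finite feature values")
  if (!all(is.finite(y))) stop("non-finite target values")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  defaults <- lapply(default_grid(algorithm), `[`, 1)
  params <- utils::modifyList(defaults, params)
  fit <- withr::with_seed(seed, switch(
    algorithm,
    rf = randomForest::randomForest(
      z, y, ntree = params$ntree,
      mtry = min(params$mtry, ncol(z))),
    svr = e1071::svm(z, y, type = "eps-regression", kernel = "radial",
                     cost = params$cost, gamma = params$gamma,
                     epsilon = 0.1, scale = FALSE),
    nn = nnet::nnet(z, matrix(y, ncol = 1), size = params$size,
                    decay = params$decay, linout = linout,
                    maxit = 500, trace = FALSE)
  ))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 feature_names = colnames(x), center = mu, scale = sdv,
                 seed = seed, linout = linout,
                 y_range = range(y)),
            class = "nni_model")
}

#' @export
print.nni_model <- function(x, ...) {
  cat("NNI regressor:", toupper(x$algorithm), "on",
      length(x$feature_names), "features;",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict NNI for new samples
#'
#' @param model an [train_nni_model()] fit.
#' @param x feature matrix/data.frame containing at least the model's
#'   feature columns (extra columns ignored; missing ones are an error).
#' @return numeric predictions, one per row.
#' @export
predict_nni <- function(model, x) {
  stopifnot(inherits(model, "nni_model"))
  x <- as.data.frame(x)
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(x[, model$feature_names, drop = FALSE])
  if (nrow(x) == 0) return(numeric(0))
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  as.vector(predict(model$fit, z))
}

#' Grid search by k-fold cross-validation
#'
#' Random (unstratified) fold assignment shared across all candidates;
#' per-candidate mean and SD of fold RMSE; the chosen candidate minimises
#' mean RMSE, with ties broken toward the most parsimonious candidate
#' (smallest mtry, cost or hidden-layer size).
#'
#' @param x feature matrix (named columns).
#' @param y NNI targets.
#' @param algorithm `"rf"`, `"svr"` or `"nn"`.
#' @param grid named list of candidate values (default [default_grid()]).
#' @param folds number of folds.
#' @param seed integer seed (folds and model fits).
#' @param linout passed to [train_nni_model()].
#' @return object of class `cv_result`: list with `table` (candidates with
#'   rmse_mean, rmse_sd), `best` (named list), `fold` assignment,
#'   `algorithm`.
#' @export
cross_validate <- function(x, y, algorithm = c("rf", "svr", "nn"),
                           grid = NULL, folds = 10, seed = 1,
                           linout = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!length(grid) || !all(lengths(grid) > 0)) stop("empty grid")
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("need at least as many samples as folds")
  fold <- withr::with_seed(seed, sample(rep(seq_len(folds),
                                            length.out = n)))
  cand <- .candidates(algorithm, grid)
  res <- matrix(NA_real_, nrow(cand), folds)
  for (ci in seq_len(nrow(cand))) {
    pars <- as.list(cand[ci, , drop = FALSE])
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- train_nni_model(x[tr, , drop = FALSE], y[tr], algorithm,
                           params = pars, seed = derive_seed(seed, f),
                           linout = linout)
      res[ci, f] <- rmse(y[!tr], predict_nni(m, x[!tr, , drop = FALSE]))
    }
  }
  tab <- cbind(cand, rmse_mean = rowMeans(res),
               rmse_sd = apply(res, 1, sd))
  best_i <- which.min(tab$rmse_mean)  # first minimum = most parsimonious
  structure(list(table = tab, best = as.list(cand[best_i, , drop = FALSE]),
                 fold = fold, algorithm = algorithm, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$table[do.call(order, list(x$table$rmse_mean)), ][1, ]
  cat("CV result (", toupper(x$algorithm), ", ",
      max(x$fold), "-fold): best ",
      paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "),
      sprintf("; RMSE %.4f +/- %.4f\n", b$rmse_mean, b$rmse_sd), sep = "")
  invisible(x)
}

#' Permutation feature importance (%IncMSE)
#'
#' For each feature, the percentage increase in mean squared prediction
#' error when that feature's values are randomly permuted,
#' `100 * (MSE_permuted - MSE_base) / MSE_base`, averaged over
#' `n_permutations` shuffles. Applied uniformly to all three algorithms so
#' scores are comparable across models.
#'
#' @param model an [train_nni_model()] fit.
#' @param x feature matrix (typically the held-out test set).
#' @param y observed NNI for `x`.
#' @param n_permutations shuffles per feature (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `importance_table`: feature, importance
#'   (%IncMSE), sorted decreasing.
#' @export
feature_importance <- function(model, x, y, n_permutations = 10, seed = 1) {
  stopifnot(inherits(model, "nni_model"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  x <- as.data.frame(x)[, model$feature_names, drop = FALSE]
  base_mse <- mean((y - predict_nni(model, x))^2)
  n <- nrow(x)
  imp <- withr::with_seed(seed, vapply(model$feature_names, function(fn) {
    inc <- vapply(seq_len(n_permutations), function(p) {
      xp <- x
      xp[[fn]] <- xp[[fn]][sample.int(n)]
      mean((y - predict_nni(model, xp))^2) - base_mse
    }, numeric(1))
    100 * mean(inc) / base_mse
  }, numeric(1)))
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "%IncMSE (permutation)"
  class(out) <- c("importance_table", "data.frame")
  out
}
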