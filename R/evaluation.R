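# Validation and scenario-evaluation metrics for NNI predictions:
# adjusted R2, RMSE, MAE, relative standard error and accuracy, overall
# and stratified by N status and growth stage.

#' Core validation metrics
#'
#' RMSE and MAE of the predictions plus the adjusted determination
#' coefficient of the linear regression of measured on simulated NNI
#' (one predictor: `R2_adj = 1 - (1 - R2)(n - 1)/(n - 2)`). If the
#' simulated values have zero variance the regression is undefined and R2
#' is reported as 0 with attribute `r2_undefined`.
#'
#' @param measured observed NNI.
#' @param simulated model-predicted NNI.
#' @return named vector: r2, rmse, mae.
#' @export
compute_metrics <- function(measured, simulated) {
  if (length(measured) != length(simulated)) stop("length mismatch")
  n <- length(measured)
  if (n < 3) stop("need at least 3 samples")
  rmse_v <- sqrt(mean((measured - simulated)^2))
  mae <- mean(abs(measured - simulated))
  undefined <- var(simulated) == 0
  if (undefined) {
    r2a <- 0
  } else {
    fit <- lm(measured ~ simulated)
    sst <- sum((measured - mean(measured))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
    r2a <- 1 - (1 - r2) * (n - 1) / (n - 2)
  }
  out <- c(r2 = r2a, rmse = rmse_v, mae = mae)
  attr(out, "r2_undefined") <- undefined
  out
}

#' Agreement metrics: relative standard error and accuracy
#'
#' RE is the residual standard error of the linear regression of measured
#' on simulated NNI (n - 2 denominator) as a percentage of the mean
#' measured value; accuracy is the Pearson correlation between measured
#' and simulated. Both are invariant to affine transformations of the
#' simulated values; zero variance in either vector makes accuracy
#' undefined (reported NA with attribute `accuracy_undefined`).
#'
#' @param measured observed NNI.
#' @param simulated model-predicted NNI.
#' @return named vector: re_pct, accuracy.
#' @export
agreement_metrics <- function(measured, simulated) {
  if (length(measured) != length(simulated)) stop("length mismatch")
  n <- length(measured)
  if (n < 3) stop("need at least 3 samples")
  if (mean(measured) == 0) stop("mean of measured values is zero")
  undefined <- var(simulated) == 0 || var(measured) == 0
  if (undefined) {
    acc <- NA_real_
    se <- sqrt(sum((measured - mean(measured))^2) / (n - 2))
  } else {
    fit <- lm(measured ~ simulated)
    se <- sqrt(sum(fit$residuals^2) / (n - 2))
    acc <- cor(measured, simulated)
  }
  out <- c(re_pct = 100 * se / mean(measured), accuracy = acc)
  attr(out, "accuracy_undefined") <- undefined
  out
}

#' Stratify predictions into evaluation scopes
#'
#' N-status scopes: `excessive` (measured NNI > 1) and `deficient`
#' (measured NNI < 1); samples at exactly 1.00 belong to neither (counted
#' in attribute `n_boundary`). Stage scopes come from `stage_map`, a
#' day-to-stage lookup; by default the last sampling day is the harvest
#' period and all earlier days are the seedling period.
#'
#' @param predictions data.frame with columns measured, simulated, day
#'   (and optionally treatment, sample_id).
#' @param stage_map optional data.frame(day, stage); default final day =
#'   "harvest", others "seedling".
#' @return named list of data.frames: overall, excessive, deficient, and
#'   one per stage.
#' @export
stratify_predictions <- function(predictions, stage_map = NULL) {
  req <- c("measured", "simulated", "day")
  if (!all(req %in% names(predictions)))
    stop("predictions need columns: ", paste(req, collapse = ", "))
  if (is.null(stage_map)) {
    days <- sort(unique(predictions$day))
    stage_map <- data.frame(day = days,
                            stage = ifelse(days == max(days),
                                           "harvest", "seedling"))
  }
  if (!all(predictions$day %in% stage_map$day))
    stop("stage_map must cover all days")
  stage <- stage_map$stage[match(predictions$day, stage_map$day)]
  scopes <- list(overall = predictions,
                 excessive = predictions[predictions$measured > 1, ,
                                         drop = FALSE],
                 deficient = predictions[predictions$measured < 1, ,
                                         drop = FALSE])
  for (s in unique(stage_map$stage))
    scopes[[s]] <- predictions[stage == s, , drop = FALSE]
  attr(scopes, "n_boundary") <- sum(predictions$measured == 1)
  scopes
}

# metrics for one scope; NULL-safe for empty scopes
.scope_row <- function(scope, name, model) {
  n <- nrow(scope)
  if (n < 3)
    return(data.frame(model = model, scope = name, n = n,
                      measured_min = NA, measured_max = NA,
                      simulated_min = NA, simulated_max = NA,
                      r2 = NA, re_pct = NA, accuracy = NA,
                      rmse = NA, mae = NA))
  m <- compute_metrics(scope$measured, scope$simulated)
  a <- agreement_metrics(scope$measured, scope$simulated)
  data.frame(model = model, scope = name, n = n,
             measured_min = min(scope$measured),
             measured_max = max(scope$measured),
             simulated_min = min(scope$simulated),
             simulated_max = max(scope$simulated),
             r2 = unname(m["r2"]), re_pct = unname(a["re_pct"]),
             accuracy = unname(a["accuracy"]),
             rmse = unname(m["rmse"]), mae = unname(m["mae"]))
}

#' Scenario evaluation report
#'
#' One row per model and scope with sample count, measured and simulated
#' ranges, adjusted R2, relative standard error (%), accuracy, RMSE and
#' MAE. `predictions` maps model names to prediction data.frames (columns
#' measured, simulated, day).
#'
#' @param predictions named list of prediction data.frames, one per model.
#' @param stage_map optional day-to-stage lookup (see
#'   [stratify_predictions()]).
#' @return data.frame of class `eval_report`.
#' @export
evaluation_report <- function(predictions, stage_map = NULL) {
  if (is.data.frame(predictions)) predictions <- list(model = predictions)
  if (!length(predictions)) stop("no predictions supplied")
  rows <- lapply(names(predictions), function(mod) {
    scopes <- stratify_predictions(predictions[[mod]], stage_map)
    do.call(rbind, lapply(names(scopes), function(s)
      .scope_row(scopes[[s]], s, mod)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back an evaluation report
#'
#' @param path JSON path written by [write_eval_report()].
#' @return data.frame of class `eval_report`.
#' @export
read_eval_report <- function(path) {
  out <- jsonlite::fromJSON(path)
  class(out) <- c("eval_report", "data.frame")
  out
}
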