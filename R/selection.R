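# Per-date one-way ANOVA screening of features across N treatments, with
# -log10(p) reporting and the select-if-significant-at-every-date rule.

#' Z-score normalisation of a feature matrix
#'
#' Per-feature `(x - mean) / sd` with the population standard deviation
#' across all samples. Constant features are mapped to zero and flagged in
#' the `constant_features` attribute (with a warning).
#'
#' @param x numeric matrix or data.frame of samples x features.
#' @return normalised matrix with attributes `center`, `scale`,
#'   `constant_features`.
#' @export
normalize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  const <- sdv == 0
  if (any(const))
    warning("constant feature(s) mapped to 0: ",
            paste(colnames(x)[const], collapse = ", "))
  z <- sweep(x, 2, mu)
  z <- sweep(z, 2, ifelse(const, 1, sdv), "/")
  z[, const] <- 0
  attr(z, "center") <- mu
  attr(z, "scale") <- sdv
  attr(z, "constant_features") <- colnames(x)[const]
  z
}

# vectorised one-way ANOVA across the columns of x for one grouping; the
# group labels must have >= 2 levels. Returns a p-value per column.
.oneway_p <- function(x, group) {
  group <- factor(group)
  k <- nlevels(group)
  n <- nrow(x)
  if (k < 2) stop("need >= 2 groups")
  gm <- rowsum(x, group) / as.vector(table(group))
  grand <- colMeans(x)
  ssb <- colSums(as.vector(table(group)) * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(x, 2, grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1; df2 <- n - k
  if (df2 < 1) stop("need more samples than groups")
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # zero within-group variance: p = 1 if the group means also coincide,
  # else effectively 0
  zero_w <- ssw <= .Machine$double.eps * pmax(sst, 1)
  p[zero_w & ssb <= .Machine$double.eps * pmax(sst, 1)] <- 1
  p[zero_w & ssb > .Machine$double.eps * pmax(sst, 1)] <- .Machine$double.xmin
  p
}

#' ANOVA screening of features across treatments, per date
#'
#' For every feature and sampling date, the p-value of the omnibus one-way
#' ANOVA F-test across treatments. A feature is selected when `p < alpha`
#' (strict) at every date. p-values are floored at 1e-300 before the
#' `-log10` transform.
#'
#' @param features samples x features matrix or data.frame.
#' @param treatment treatment label per sample.
#' @param day sampling day per sample.
#' @param alpha significance level.
#' @return object of class `screening_result`: list with `p_matrix`
#'   (features x dates), `neglog10`, `selected`, `alpha`.
#' @export
anova_screen <- function(features, treatment, day, alpha = 0.05) {
  x <- as.matrix(features)
  if (nrow(x) != length(treatment) || nrow(x) != length(day))
    stop("treatment/day labels must match the rows of features")
  if (anyNA(treatment) || anyNA(day)) stop("missing treatment/day labels")
  days <- sort(unique(day))
  p <- sapply(days, function(d) {
    idx <- day == d
    if (length(unique(treatment[idx])) < 2)
      stop("each date needs >= 2 treatments")
    .oneway_p(x[idx, , drop = FALSE], treatment[idx])
  })
  p <- matrix(p, ncol = length(days),
              dimnames = list(colnames(x), days))
  selected <- rownames(p)[apply(p < alpha, 1, all)]
  structure(list(p_matrix = p,
                 neglog10 = -log10(pmax(p, 1e-300)),
                 selected = selected,
                 alpha = alpha),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("ANOVA screening:", nrow(x$p_matrix), "features x",
      ncol(x$p_matrix), "dates; alpha =", x$alpha, "\n")
  cat("  per-date significant:",
      paste(colSums(x$p_matrix < x$alpha), collapse = ", "), "\n")
  cat("  selected at all dates:", length(x$selected), "\n")
  invisible(x)
}

#' Data for a per-date significance plot
#'
#' One row per feature and date with the feature number, `-log10(p)` and a
#' flag for exceeding the significance line at `-log10(alpha)` (1.301 for
#' alpha = 0.05). Ready for plotting Manhattan-style per-date panels.
#'
#' @param result a [anova_screen()] result.
#' @return data.frame: day, feature, feature_no, neglog10_p, significant;
#'   attribute `threshold` carries `-log10(alpha)`.
#' @export
significance_plot_data <- function(result) {
  stopifnot(inherits(result, "screening_result"))
  p <- result$p_matrix
  out <- data.frame(
    day = rep(colnames(p), each = nrow(p)),
    feature = rep(rownames(p), times = ncol(p)),
    feature_no = rep(seq_len(nrow(p)), times = ncol(p)),
    neglog10_p = as.vector(result$neglog10),
    significant = as.vector(p < result$alpha)
  )
  attr(out, "threshold") <- -log10(result$alpha)
  out
}
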