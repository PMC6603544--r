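# Critical nitrogen dilution curve (Justes approach) and the nitrogen
# nutrition index NNI = Nt / Nc.

#' Classify treatments as N-limiting or non-N-limiting
#'
#' A treatment is N-limiting at a date when supplying more N significantly
#' increases shoot biomass: operationally, the omnibus one-way ANOVA across
#' treatments is significant at that date and at least one higher dose has
#' significantly greater biomass by a one-sided Welch test at `alpha`.
#' Comparing against every higher dose (not only the adjacent one) matters
#' because biomass saturates: near the optimum the next dose up may sit on
#' the plateau while a further dose still shows the response. The highest
#' dose is non-N-limiting by construction. Per-date labels are aggregated
#' across dates by majority.
#'
#' @param records data.frame with columns treatment, dose, day, biomass_dm
#'   and at least 2 replicates per treatment-date cell.
#' @param alpha significance level.
#' @return data.frame per treatment: dose, n_limiting (overall majority
#'   label), prop_limiting (fraction of dates limiting), plus a `per_date`
#'   attribute with the date-wise logical matrix.
#' @export
classify_limiting <- function(records, alpha = 0.05) {
  req <- c("treatment", "dose", "day", "biomass_dm")
  if (!all(req %in% names(records))) stop("records need columns: ",
                                          paste(req, collapse = ", "))
  doses <- sort(unique(records$dose))
  trt_of <- vapply(doses, function(d)
    unique(records$treatment[records$dose == d])[1], character(1))
  if (length(doses) < 2) stop("need >= 2 treatments with distinct doses")
  days <- sort(unique(records$day))
  counts <- table(records$treatment, records$day)
  if (any(counts < 2)) stop("need >= 2 replicates per treatment-date cell")
  per_date <- matrix(FALSE, length(doses), length(days),
                     dimnames = list(trt_of, days))
  for (di in seq_along(days)) {
    sub <- records[records$day == days[di], ]
    omni <- .oneway_p(matrix(sub$biomass_dm, ncol = 1), sub$dose)
    for (k in seq_len(length(doses) - 1)) {
      lo <- sub$biomass_dm[sub$dose == doses[k]]
      p_hi <- vapply(seq(k + 1, length(doses)), function(k2) {
        hi <- sub$biomass_dm[sub$dose == doses[k2]]
        tryCatch(t.test(hi, lo, alternative = "greater")$p.value,
                 error = function(e) 1)
      }, numeric(1))
      per_date[k, di] <- is.finite(omni) && omni < alpha &&
        any(p_hi < alpha)
    }
  }
  out <- data.frame(treatment = trt_of, dose = doses,
                    prop_limiting = rowMeans(per_date),
                    stringsAsFactors = FALSE)
  out$n_limiting <- out$prop_limiting > 0.5
  attr(out, "per_date") <- per_date
  out
}

#' Fit a critical nitrogen dilution curve
#'
#' Least-squares fit of `ln(Nc) = ln(a) + b ln(DM)` to (biomass, N
#' concentration) points from N-limiting growth, giving `Nc = a DM^b`.
#' The exponent may take either sign: classical dilution gives b < 0,
#' while frequent small N doses can make N concentration rise with biomass
#' (b > 0).
#'
#' @param biomass_dm shoot dry biomass, g/plant (> 0).
#' @param n_conc shoot N concentration, g/kg DW (> 0).
#' @return object of class `dilution_curve`: list(a, b, fit_r2, n).
#' @export
fit_dilution_curve <- function(biomass_dm, n_conc) {
  if (length(biomass_dm) != length(n_conc)) stop("length mismatch")
  if (length(biomass_dm) < 3) stop("need at least 3 points")
  if (any(biomass_dm <= 0) || any(n_conc <= 0))
    stop("biomass and N concentration must be positive")
  if (length(unique(biomass_dm)) < 2)
    stop("degenerate design: biomass values are all identical")
  fit <- lm(log(n_conc) ~ log(biomass_dm))
  y <- log(n_conc)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(a = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]),
                 fit_r2 = r2,
                 n = length(biomass_dm)),
            class = "dilution_curve")
}

#' @export
print.dilution_curve <- function(x, ...) {
  cat(sprintf("Critical N dilution curve: Nc = %.4g * DM^%.4g  (R2 = %.3f, n = %d)\n",
              x$a, x$b, x$fit_r2, x$n))
  invisible(x)
}

#' Critical N concentration at a reference biomass
#'
#' @param curve a [fit_dilution_curve()] result (or list with a, b).
#' @param dm_ref shoot dry biomass, g/plant (> 0).
#' @return critical N concentration `a * dm_ref^b`, g/kg DW.
#' @export
critical_n <- function(curve, dm_ref) {
  if (any(dm_ref <= 0)) stop("dm_ref must be positive")
  curve$a * dm_ref^curve$b
}

#' Nitrogen nutrition index
#'
#' `NNI = Nt / Nc`: measured shoot N concentration over the critical
#' concentration. Unrounded; round to two decimals with
#' `round_half_up(nni, 2)` when reporting.
#'
#' @param nt measured shoot N concentration, g/kg DW.
#' @param nc critical N concentration, g/kg DW (> 0).
#' @return NNI values.
#' @export
compute_nni <- function(nt, nc) {
  if (any(nc <= 0)) stop("nc must be positive")
  nt / nc
}

#' Classify nitrogen status from NNI
#'
#' Optimal when NNI is within `tol` of 1 (default 0.005, i.e. values that
#' round to 1.00 at two decimals), deficient below, excessive above.
#'
#' @param nni NNI values (>= 0).
#' @param tol half-width of the optimal band around 1.
#' @return factor with levels deficient, optimal, excessive.
#' @export
classify_status <- function(nni, tol = 0.005) {
  if (any(nni < 0)) stop("nni must be >= 0")
  factor(ifelse(abs(nni - 1) <= tol, "optimal",
                ifelse(nni > 1, "excessive", "deficient")),
         levels = c("deficient", "optimal", "excessive"))
}

#' Per-date NNI table from growth records
#'
#' Computes NNI for every treatment-date mean using either an explicit
#' per-date list of critical N concentrations (the reproduction path for
#' published tables) or a fitted dilution curve evaluated at a per-date
#' reference biomass. When a curve is used, the reference biomass at each
#' date defaults to the mean biomass of the non-N-limiting treatments from
#' [classify_limiting()]; a single reference treatment can be named
#' instead.
#'
#' @param growth data.frame with columns treatment, day, n_conc and (for
#'   the curve path) dose, biomass_dm.
#' @param nc_values optional data.frame(day, nc) of explicit critical
#'   concentrations.
#' @param curve optional [fit_dilution_curve()] result.
#' @param reference_treatment optional treatment whose biomass anchors Nc.
#' @param alpha significance level for the limiting classification.
#' @param tol optimal-band half width for [classify_status()].
#' @return data.frame: treatment, day, nt, nc, nni (2 dp, half-up),
#'   status.
#' @export
nni_table <- function(growth, nc_values = NULL, curve = NULL,
                      reference_treatment = NULL, alpha = 0.05,
                      tol = 0.005) {
  if (is.null(nc_values) && is.null(curve))
    stop("supply either nc_values or a fitted curve")
  agg <- stats::aggregate(growth[c("n_conc")],
                          by = growth[c("treatment", "day")], FUN = mean)
  if (!is.null(nc_values)) {
    if (!all(agg$day %in% nc_values$day))
      stop("nc_values must cover every sampling day")
    nc <- nc_values$nc[match(agg$day, nc_values$day)]
  } else {
    bio <- stats::aggregate(growth[c("biomass_dm")],
                            by = growth[c("treatment", "day")], FUN = mean)
    if (is.null(reference_treatment)) {
      lim <- classify_limiting(growth, alpha = alpha)
      ref_trt <- lim$treatment[!lim$n_limiting]
      if (!length(ref_trt)) stop("no non-N-limiting treatment found")
    } else ref_trt <- reference_treatment
    ref <- bio[bio$treatment %in% ref_trt, ]
    dm_ref <- tapply(ref$biomass_dm, ref$day, mean)
    nc <- critical_n(curve, unname(dm_ref[as.character(agg$day)]))
  }
  nni <- round_half_up(compute_nni(agg$n_conc, nc), 2)
  out <- data.frame(treatment = agg$treatment, day = agg$day,
                    nt = agg$n_conc, nc = nc, nni = nni,
                    status = classify_status(nni, tol))
  out[order(out$treatment, out$day), , drop = FALSE]
}
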