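#' Define a pot-trial agronomic design
#'
#' A factorial nitrogen-dose by sampling-date design with replicated pots,
#' defaulting to the four doses (g N/pot) and six weekly sampling dates of
#' the pakchoi pot trial the package emulates.
#'
#' @param treatments named numeric vector of N doses in g N/pot.
#' @param dates sampling days after first N application.
#' @param replicates pots per treatment-by-date cell.
#' @param seed integer seed driving all downstream randomness.
#' @return object of class `agronomic_design`.
#' @export
agronomic_design <- function(treatments = c(CK = 0, T1 = 0.134,
                                            T2 = 0.163, T3 = 0.191),
                             dates = c(7, 14, 21, 28, 35, 42),
                             replicates = 3,
                             seed = 1) {
  if (length(treatments) < 2) stop("need at least 2 treatments")
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    stop("treatments must be a named dose vector")
  if (any(treatments < 0)) stop("doses must be >= 0")
  if (length(dates) < 2) stop("need at least 2 sampling dates")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(treatments = treatments, dates = sort(dates),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "agronomic_design")
}

#' @export
print.agronomic_design <- function(x, ...) {
  cat("Agronomic design:", length(x$treatments), "treatments x",
      length(x$dates), "dates x", x$replicates, "replicates\n")
  cat("  doses (g N/pot):",
      paste(names(x$treatments), x$treatments, sep = "=", collapse = ", "),
      "\n  days:", paste(x$dates, collapse = ", "), "\n")
  invisible(x)
}

#' Dilution-curve parameters used by the generator
#'
#' The generator links its latent N status to biomass and N concentration
#' through its own critical dilution curve Nc = a * DM^b, so that curve
#' fitting downstream can recover (a, b) exactly on noiseless data. The
#' exponent is positive: in the emulated pot trial, frequent small N doses
#' made shoot N concentration rise with biomass rather than dilute.
#'
#' @return list with elements `a` (g/kg at 1 g DM) and `b` (exponent).
#' @export
generator_curve <- function() list(a = 75, b = 0.12)

# deterministic mean structure of the trajectories -------------------------

# dose-response saturation on the 0..1 relative-dose scale
.dose_effect <- function(rel_dose) sqrt(pmin(rel_dose, 1.5))

# shoot dry biomass (g/plant): exponential growth, rate and day-7 intercept
# both increasing with dose (calibrated to the 0.065-1.36 g range of the
# emulated trial)
.mean_biomass <- function(day, rel_dose) {
  s <- .dose_effect(rel_dose)
  (0.065 + 0.014 * s) * exp((0.064 + 0.016 * s) * (day - 7))
}

# true NNI surface: unfertilized plants decline from ~0.77 to ~0.26 over
# days 7-42; fertilized plants sit near or a little above 1
.mean_nni <- function(day, rel_dose) {
  base <- pmax(0.88 - 0.0155 * day, 0.2)
  target <- 1 + 0.1 * rel_dose
  w <- 1 - exp(-5 * rel_dose)
  base + (target - base) * w
}

#' Generate growth trajectories with known true NNI
#'
#' Simulates shoot dry biomass and shoot N concentration for every
#' treatment x date x replicate cell of a design. The mean structure is
#' deterministic (biomass grows monotonically with day; the zero-dose
#' treatment's true NNI declines steadily while fertilized treatments stay
#' near or above 1); multiplicative Gaussian noise with coefficient of
#' variation `noise_cv` is applied independently to biomass and N
#' concentration. The true NNI of each record is recomputed from its noisy
#' biomass and N concentration through the generator's own dilution curve,
#' so it remains exactly consistent with the generative link.
#'
#' @param design an [agronomic_design()].
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   in `[0, 0.3]`.
#' @return data.frame with columns sample_id, treatment, dose, day,
#'   replicate, biomass_dm (g/plant), n_conc (g/kg DW), nni_true.
#' @export
generate_trajectories <- function(design, noise_cv = 0.05) {
  if (!inherits(design, "agronomic_design")) stop("design must be an agronomic_design")
  if (noise_cv < 0 || noise_cv > 0.3) stop("noise_cv must be in [0, 0.3]")
  curve <- generator_curve()
  ref_dose <- 0.191  # conventional-rate reference dose (g N/pot)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      day = design$dates,
                      treatment = names(design$treatments),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$treatment, names(design$treatments)),
                     grid$day, grid$replicate), , drop = FALSE]
  rel <- design$treatments[grid$treatment] / ref_dose
  mu_b <- .mean_biomass(grid$day, rel)
  mu_nni <- .mean_nni(grid$day, rel)
  mu_n <- mu_nni * curve$a * mu_b^curve$b
  n <- nrow(grid)
  withr::with_seed(design$seed, {
    b_obs <- mu_b * pmax(1 + rnorm(n, 0, noise_cv), 0.05)
    n_obs <- mu_n * pmax(1 + rnorm(n, 0, noise_cv), 0.05)
  })
  data.frame(
    sample_id = sprintf("%s_d%02d_r%02d", grid$treatment, grid$day,
                        grid$replicate),
    treatment = grid$treatment,
    dose = unname(design$treatments[grid$treatment]),
    day = grid$day,
    replicate = grid$replicate,
    biomass_dm = b_obs,
    n_conc = n_obs,
    nni_true = n_obs / (curve$a * b_obs^curve$b),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Latent plant state driving the renderer
#'
#' Maps one growth record to the latent variables the image renderer
#' consumes: `greenness` (0-1, increasing with true NNI; drives hue and
#' saturation), `texture_amp` (grey-level noise amplitude in 8-bit units;
#' chlorotic, N-starved plants are rendered more heterogeneous),
#' `n_leaves` and `scale_px` (both increasing with biomass).
#'
#' @param biomass_dm shoot dry biomass, g/plant.
#' @param n_conc shoot N concentration, g/kg DW.
#' @param nni_true true NNI; if `NULL`, computed from the generator curve.
#' @return object of class `latent_state`.
#' @export
latent_state <- function(biomass_dm, n_conc, nni_true = NULL) {
  stopifnot(biomass_dm > 0, n_conc > 0)
  curve <- generator_curve()
  if (is.null(nni_true))
    nni_true <- n_conc / (curve$a * biomass_dm^curve$b)
  greenness <- clamp((nni_true - 0.2) / 1.0, 0.05, 1)
  structure(list(
    biomass_dm = biomass_dm,
    n_conc = n_conc,
    nni_true = nni_true,
    greenness = greenness,
    texture_amp = 3 + 5 * (1 - greenness),
    n_leaves = as.integer(pmin(14, 5 + round(7 * sqrt(biomass_dm / 1.4)))),
    scale_px = 28 + 60 * sqrt(biomass_dm / 1.4)
  ), class = "latent_state")
}

#' Generate a full synthetic image dataset
#'
#' Renders one top-view PNG per record of the design's trajectories and
#' writes a ground-truth table. Per-sample render seeds are derived from
#' the design seed, so a fixed design reproduces the dataset byte for byte.
#'
#' @param design an [agronomic_design()].
#' @param out_dir output directory (created if needed).
#' @param noise_cv trajectory noise, as in [generate_trajectories()].
#' @param canvas_px integer `c(height, width)` of the rendered images.
#' @param background background grey level (0-255).
#' @param write_masks also write the truth masks as `<id>_mask.png`.
#' @return invisibly, a list with the truth `table`, `csv` path and `dir`.
#' @export
generate_dataset <- function(design, out_dir, noise_cv = 0.05,
                             canvas_px = c(224, 224), background = 235,
                             write_masks = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  recs <- generate_trajectories(design, noise_cv = noise_cv)
  recs$image_path <- file.path(out_dir, paste0(recs$sample_id, ".png"))
  for (k in seq_len(nrow(recs))) {
    st <- latent_state(recs$biomass_dm[k], recs$n_conc[k], recs$nni_true[k])
    rs <- render_plant(st, canvas_px = canvas_px, background = background,
                       seed = derive_seed(design$seed, k))
    write_rgb(rs$image, recs$image_path[k])
    if (write_masks)
      write_rgb(rs$truth_mask,
                file.path(out_dir, paste0(recs$sample_id, "_mask.png")))
  }
  truth <- recs[, c("sample_id", "treatment", "day", "biomass_dm",
                    "n_conc", "nni_true", "image_path")]
  csv <- file.path(out_dir, "truth.csv")
  on_disk <- truth
  on_disk$image_path <- basename(on_disk$image_path)  # location-independent
  write.csv(on_disk, csv, row.names = FALSE)
  invisible(list(table = truth, csv = csv, dir = out_dir))
}
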