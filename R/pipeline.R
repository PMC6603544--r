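# End-to-end pipeline: simulate -> segment -> extract -> nni -> select ->
# train -> evaluate, with a YAML-configurable parameter set and a
# reproducibility manifest.

#' Default pipeline configuration
#'
#' Every tunable of the individual stages, with its default. The one
#' global `seed` drives trajectory noise, rendering, the train/test split,
#' cross-validation folds and model fits.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    paths = list(out_dir = "nnipheno_run"),
    synthetic = list(
      treatments = c(CK = 0, T1 = 0.134, T2 = 0.163, T3 = 0.191),
      dates = c(7, 14, 21, 28, 35, 42),
      replicates = 3,
      noise_cv = 0.05,
      canvas_px = c(224, 224),
      background = 235
    ),
    segmentation = list(exg_min = 40, exg_max = 200, gray_max = 240,
                        open_kernel_px = 3, min_object_frac = 1 / 10,
                        max_hole_frac = 1 / 20),
    glcm = list(distance = 1, angles = c(0, 45, 90, 135), levels = 256,
                symmetric = TRUE, normalized = TRUE),
    nitrogen = list(alpha = 0.05, tol = 0.005),
    selection = list(alpha = 0.05),
    models = list(algorithms = c("rf", "svr", "nn"), train_frac = 0.75,
                  folds = 10, linout = FALSE, n_permutations = 5),
    evaluation = list(stage_map = NULL)
  )
}

# merge user values over defaults, rejecting unknown keys at any level
.merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' YAML values are merged over [default_config()]; unknown keys anywhere
#' in the tree are rejected before any stage runs.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param overrides optional named list merged last.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$synthetic$treatments))
      user$synthetic$treatments <- unlist(user$synthetic$treatments)
    cfg <- .merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides)
  cfg
}

.stage_msg <- function(stage, t0) {
  message(sprintf("[nnipheno] %-9s %6.1fs", stage,
                  (proc.time() - t0)[["elapsed"]]))
}

#' Run the full pipeline
#'
#' Executes simulate, segment+extract, nni, select, train and evaluate in
#' order, leaving each stage's artefact (CSV/PNG/JSON) in `out_dir`, and
#' writes a run manifest with MD5 hashes of all outputs. Re-running with
#' an identical configuration reproduces identical artefacts and an
#' identical manifest hash.
#'
#' @param config configuration list from [read_pipeline_config()] or
#'   [default_config()].
#' @param out_dir output directory (defaults to `config$paths$out_dir`).
#' @return the manifest, invisibly (list: seed, config, outputs with MD5s,
#'   `hash`, timings).
#' @export
run_pipeline <- function(config = default_config(),
                         out_dir = config$paths$out_dir) {
  config <- .merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()
  seed <- config$seed

  # simulate
  design <- agronomic_design(treatments = config$synthetic$treatments,
                             dates = config$synthetic$dates,
                             replicates = config$synthetic$replicates,
                             seed = seed)
  img_dir <- file.path(out_dir, "images")
  sim <- generate_dataset(design, img_dir,
                          noise_cv = config$synthetic$noise_cv,
                          canvas_px = config$synthetic$canvas_px,
                          background = config$synthetic$background)
  truth <- sim$table
  .stage_msg("simulate", t0)

  # segment + extract
  seg <- do.call(segmentation_params, config$segmentation)
  glcm <- do.call(glcm_params, config$glcm)
  features <- extract_features_batch(truth, params = seg, glcm = glcm)
  features_csv <- file.path(out_dir, "features.csv")
  write.csv(features, features_csv, row.names = FALSE)
  .stage_msg("extract", t0)

  # nitrogen: dilution curve from N-limiting treatments, per-sample NNI
  growth <- truth
  growth$dose <- design$treatments[growth$treatment]
  growth$replicate <- as.integer(sub(".*_r", "", growth$sample_id))
  lim <- classify_limiting(growth, alpha = config$nitrogen$alpha)
  lim_trt <- lim$treatment[lim$n_limiting]
  if (!length(lim_trt)) lim_trt <- lim$treatment[which.min(lim$dose)]
  ref_trt <- lim$treatment[!lim$n_limiting]
  fitdat <- growth[growth$treatment %in% lim_trt, ]
  curve <- fit_dilution_curve(fitdat$biomass_dm, fitdat$n_conc)
  ref <- growth[growth$treatment %in% ref_trt, ]
  dm_ref <- tapply(ref$biomass_dm, ref$day, mean)
  nc_by_day <- critical_n(curve, dm_ref)
  nc <- nc_by_day[as.character(growth$day)]
  nni_df <- data.frame(sample_id = growth$sample_id,
                       treatment = growth$treatment, day = growth$day,
                       nt = growth$n_conc, nc = unname(nc),
                       nni = compute_nni(growth$n_conc, unname(nc)))
  nni_df$status <- classify_status(nni_df$nni, config$nitrogen$tol)
  nni_csv <- file.path(out_dir, "nni.csv")
  write.csv(nni_df, nni_csv, row.names = FALSE)
  .stage_msg("nni", t0)

  # selection
  fx <- as.matrix(features[, feature_names()])
  fz <- suppressWarnings(normalize_features(fx))
  screen <- anova_screen(fz, growth$treatment, growth$day,
                         alpha = config$selection$alpha)
  screening_json <- file.path(out_dir, "screening.json")
  jsonlite::write_json(list(alpha = screen$alpha,
                            selected = screen$selected,
                            p_matrix = screen$p_matrix),
                       screening_json, digits = NA, pretty = TRUE)
  selected <- screen$selected
  if (length(selected) < 2) selected <- preset_features("paper23")
  .stage_msg("select", t0)

  # train + predict
  y <- nni_df$nni[match(features$sample_id, nni_df$sample_id)]
  split <- split_dataset(nrow(features),
                         train_frac = config$models$train_frac,
                         seed = derive_seed(seed, 11))
  xsel <- fx[, selected, drop = FALSE]
  preds <- list()
  chosen <- list()
  for (alg in config$models$algorithms) {
    cv <- cross_validate(xsel[split$train, , drop = FALSE], y[split$train],
                         alg, folds = config$models$folds,
                         seed = derive_seed(seed, 13),
                         linout = config$models$linout)
    model <- train_nni_model(xsel[split$train, , drop = FALSE],
                             y[split$train], alg, params = cv$best,
                             seed = derive_seed(seed, 17),
                             linout = config$models$linout)
    chosen[[alg]] <- cv$best
    preds[[alg]] <- data.frame(
      sample_id = features$sample_id[split$test],
      day = growth$day[split$test],
      treatment = growth$treatment[split$test],
      measured = y[split$test],
      simulated = predict_nni(model, xsel[split$test, , drop = FALSE]))
  }
  preds_csv <- file.path(out_dir, "predictions.csv")
  write.csv(do.call(rbind, Map(cbind, model = names(preds), preds)),
            preds_csv, row.names = FALSE)
  .stage_msg("train", t0)

  # evaluate
  report <- evaluation_report(preds, stage_map = config$evaluation$stage_map)
  report_json <- file.path(out_dir, "report.json")
  write_eval_report(report, report_json)
  .stage_msg("evaluate", t0)

  outputs <- c(truth = sim$csv, features = features_csv, nni = nni_csv,
               screening = screening_json, predictions = preds_csv,
               report = report_json)
  manifest <- list(
    seed = seed,
    config = config,
    curve = list(a = curve$a, b = curve$b, r2 = curve$fit_r2),
    selected_features = selected,
    chosen_hyperparameters = chosen,
    outputs = as.list(unname(Map(function(nm, p) list(
      name = nm, path = p, md5 = unname(tools::md5sum(p))),
      names(outputs), outputs))),
    version = as.character(utils::packageVersion("nnipheno")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest$hash <- manifest_hash(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Reproducibility hash of a run manifest
#'
#' MD5 over the seed, the serialised configuration and the MD5s of every
#' stage output; the timestamp and absolute paths are excluded, so two
#' runs of the same configuration hash identically.
#'
#' @param manifest manifest list from [run_pipeline()].
#' @return MD5 string.
#' @export
manifest_hash <- function(manifest) {
  cfg <- manifest$config
  cfg$paths <- NULL  # where a run lives must not change what it computes
  payload <- list(seed = manifest$seed, config = cfg,
                  md5 = vapply(manifest$outputs, function(o)
                    unname(o$md5), character(1)))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(payload), tmp)
  unname(tools::md5sum(tmp))
}

#' Write the in-study reference tables as machine-readable fixtures
#'
#' Produces `growth.csv` (treatment-by-date biomass and N concentration
#' means), `nc.csv` (the six per-date critical N concentrations),
#' `nni_expected.csv` (the published NNI table) and `preset23.txt` (the 23
#' screened feature names).
#'
#' @param out_dir writable directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(growth = file.path(out_dir, "growth.csv"),
             nc = file.path(out_dir, "nc.csv"),
             nni = file.path(out_dir, "nni_expected.csv"),
             preset = file.path(out_dir, "preset23.txt"))
  write.csv(reference_growth(), paths["growth"], row.names = FALSE)
  write.csv(reference_nc(), paths["nc"], row.names = FALSE)
  write.csv(reference_nni(), paths["nni"], row.names = FALSE)
  writeLines(preset_features("paper23"), paths["preset"])
  invisible(paths)
}
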