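#' Assemble a pipeline run configuration
#'
#' Collects all stage parameters with their defaults. The configuration can
#' also be read from a YAML file with [read_run_config()]; entries have the
#' same names.
#'
#' @param series,labels Paths to a 4D NIfTI series (+ JSON sidecar) and its
#'   label map, or `NULL` to simulate a phantom instead.
#' @param phantom Phantom type for simulation runs (see [phantom_truth()]).
#' @param noise_sd Simulation noise SD (a.u.).
#' @param simulate_volume If `TRUE`, the phantom is synthesized as a full
#'   4D volume and passed through ROI extraction; otherwise ROI curves are
#'   generated directly.
#' @param infusion,acquisition Protocol objects (or NULL for defaults).
#' @param reference_roi Label of the input-function ROI.
#' @param n_average Temporal averaging factor applied before analysis.
#' @param max_lag_frames,min_overlap,lag_mode,threshold See [cmbhc()].
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip bootstrap.
#' @param seed Integer master seed.
#' @param out_dir Output directory for all artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(series = NULL, labels = NULL,
                       phantom = "four_cluster", noise_sd = 10,
                       simulate_volume = FALSE,
                       infusion = NULL, acquisition = NULL,
                       reference_roi = 1L, n_average = 1L,
                       max_lag_frames = NULL, min_overlap = NULL,
                       lag_mode = "symmetric", threshold = 0.4,
                       bootstrap = NULL, seed = 1L, out_dir = "glymclust_out") {
  structure(list(series = series, labels = labels, phantom = phantom,
                 noise_sd = noise_sd, simulate_volume = simulate_volume,
                 infusion = infusion %||% infusion_protocol(),
                 acquisition = acquisition %||% phantom_acquisition(),
                 reference_roi = as.integer(reference_roi),
                 n_average = as.integer(n_average),
                 max_lag_frames = max_lag_frames,
                 min_overlap = min_overlap, lag_mode = lag_mode,
                 threshold = threshold, bootstrap = bootstrap,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()];
#'   `infusion`, `acquisition` and `bootstrap` may be nested maps.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$infusion)) y$infusion <- do.call(infusion_protocol, y$infusion)
  if (!is.null(y$acquisition))
    y$acquisition <- do.call(acquisition_protocol, y$acquisition)
  if (!is.null(y$bootstrap)) y$bootstrap <- do.call(bootstrap_config, y$bootstrap)
  do.call(run_config, y)
}

stage_log <- function(stage, t0) {
  message(sprintf("[glymclust] %-12s %6.2f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes (simulate) -> extract -> temporal average -> baseline
#' subtraction -> input-function normalization -> lagged cross-correlation
#' -> complete-linkage clustering (+ optional multiscale bootstrap) and
#' writes every intermediate artifact to `config$out_dir`: raw and
#' normalized curve TSVs, the combined mCC/lag table, dendrogram JSON and
#' Newick, the cluster assignment, a results JSON, and (for volume inputs)
#' the tMIP map. Identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()] list, or the path to a YAML file.
#' @return The fitted [cmbhc()] object, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  series <- NULL
  if (!is.null(config$series)) {
    if (!file.exists(config$series))
      stop("series file not found: ", config$series)
    if (is.null(config$labels) || !file.exists(config$labels))
      stop("label map file not found: ", config$labels %||% "<missing>")
    series <- read_dynamic_series(config$series)
    labels <- read_label_map(config$labels)
    stage_log("read", t0)
    curves <- extract_roi_timecourses(series, labels)
  } else if (isTRUE(config$simulate_volume)) {
    truth <- phantom_truth(config$phantom, seed = config$seed)
    labels <- ellipsoid_label_map(n_roi = nrow(truth$params),
                                  names = truth$params$roi_name)
    series <- simulate_dynamic_volume(truth, labels, config$infusion,
                                      config$acquisition, config$noise_sd,
                                      seed = config$seed)
    stage_log("simulate", t0)
    curves <- extract_roi_timecourses(series, labels)
  } else {
    truth <- phantom_truth(config$phantom, seed = config$seed)
    curves <- simulate_roi_curves(truth, config$infusion,
                                  config$acquisition, config$noise_sd,
                                  seed = config$seed)
    stage_log("simulate", t0)
  }
  stage_log("extract", t0)
  write_curves_tsv(curves, file.path(config$out_dir, "curves_raw.tsv"))

  curves <- temporal_average(curves, config$n_average)
  curves <- subtract_baseline(curves)
  curves <- normalize_by_input(curves, config$reference_roi)
  stage_log("preprocess", t0)
  write_curves_tsv(curves,
                   file.path(config$out_dir, "curves_normalized.tsv"))
  if (!is.null(series)) {
    tm <- compute_tmip(temporal_average(series, config$n_average))
    write_tmip(tm, file.path(config$out_dir, "tmip.nii.gz"))
  }

  fit <- cmbhc(curves, max_lag_frames = config$max_lag_frames,
               min_overlap = config$min_overlap,
               lag_mode = config$lag_mode, threshold = config$threshold,
               boot = config$bootstrap)
  stage_log("cluster", t0)

  write_results(fit, config$out_dir)
  stage_log("report", t0)
  invisible(fit)
}

#' Write analysis results to a directory
#'
#' Emits `mcc_lag.tsv` (mCC lower triangle / lag upper triangle),
#' `results.json` (all matrices, dendrogram, clusters),
#' `dendrogram.json`, `dendrogram.newick` and `clusters.tsv`.
#'
#' @param fit A fitted [cmbhc()] object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  stopifnot(inherits(fit, "cmbhc"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    cbind(roi = rownames(mcc_lag_table(fit$lagcorr)),
          as.data.frame(mcc_lag_table(fit$lagcorr))),
    file.path(out_dir, "mcc_lag.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(roi_name = fit$lagcorr$roi_name,
         roi_id = fit$lagcorr$roi_id,
         frame_interval_min = fit$lagcorr$frame_interval,
         mcc = fit$lagcorr$mcc,
         lag_min = fit$lagcorr$lag,
         overlap = fit$lagcorr$overlap,
         dissimilarity = unclass(fit$diss),
         threshold = fit$threshold,
         clusters = fit$clusters$clusters,
         singletons = fit$clusters$singletons,
         dendrogram = jsonlite::fromJSON(dendrogram_to_json(fit$tree),
                                         simplifyVector = FALSE)),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  dendrogram_to_json(fit$tree, file.path(out_dir, "dendrogram.json"))
  dendrogram_to_newick(fit$tree, file.path(out_dir, "dendrogram.newick"))
  memb <- fit$clusters$membership
  utils::write.table(
    data.frame(roi_name = names(memb), cluster = unname(memb)),
    file.path(out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
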