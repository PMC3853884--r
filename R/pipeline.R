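default_run_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    paths = list(ct = NULL, cbct = NULL, transform = NULL, outdir = "."),
    stages = c("simulate", "correct", "evaluate"),
    thresholds = unclass(segmentation_thresholds()),
    filter = unclass(filter_spec()),
    registration = unclass(registration_settings()),
    phantom = list(shape = c(128L, 128L, 64L), spacing_mm = c(2.5, 2.5, 2.5)),
    degradation = unclass(degradation_spec())
  )
}

merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults))
      cbct_stop("cbct_configuration_error", paste("unknown config key:", full))
    if (is.list(defaults[[key]]) && is.list(overrides[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], full)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an R list) of overrides on top of the
#' package defaults; unknown keys are rejected so typos fail loudly. The
#' effective (merged) config is serialized into every run manifest.
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a named list.
#' @return The effective configuration list.
#' @export
load_run_config <- function(config = NULL) {
  defaults <- default_run_config()
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    if (!file.exists(config))
      cbct_stop("cbct_io_error", paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    cbct_stop("cbct_configuration_error", "config must be a list or a YAML file path")
  merge_config(defaults, config)
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[cbctcorr %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

write_manifest <- function(outdir, stage, config, inputs = character(),
                           outputs = character()) {
  checks <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (!length(paths)) return(NULL)
    as.list(tools::md5sum(paths))
  }
  manifest <- list(tool = "cbctcorr",
                   version = as.character(packageVersion("cbctcorr")),
                   stage = stage,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed,
                   config = config,
                   input_checksums = checks(inputs),
                   output_checksums = checks(outputs))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

stage_simulate <- function(config) {
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(config, "simulate: rendering phantom and degraded CBCT")
  fx <- standard_fixture(seed = config$seed,
                         shape = config$phantom$shape,
                         spacing_mm = config$phantom$spacing_mm,
                         degradation = do.call(degradation_spec,
                                               config$degradation))
  paths <- c(ct = file.path(outdir, "ct.nii.gz"),
             cbct = file.path(outdir, "cbct.nii.gz"),
             labels = file.path(outdir, "labels.nii.gz"),
             bias = file.path(outdir, "bias.nii.gz"),
             transform = file.path(outdir, "transform.txt"))
  write_volume(fx$ct, paths[["ct"]])
  write_volume(fx$cbct, paths[["cbct"]])
  write_volume(masks_to_labels(fx$masks), paths[["labels"]])
  write_volume(fx$truth_bias, paths[["bias"]])
  write_transform(fx$truth_transform, paths[["transform"]])
  write_manifest(outdir, "simulate", config, outputs = paths)
  paths
}

stage_register <- function(config) {
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_volume(config$paths$ct)
  cbct <- read_volume(config$paths$cbct)
  pipeline_log(config, "register: estimating rigid transform")
  reg <- register_rigid(ct, cbct, do.call(registration_settings,
                                          config$registration))
  path <- file.path(outdir, "transform.txt")
  write_transform(reg$transform, path)
  write_manifest(outdir, "register", config,
                 inputs = c(config$paths$ct, config$paths$cbct),
                 outputs = path)
  c(transform = path)
}

stage_correct <- function(config) {
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_volume(config$paths$ct)
  cbct <- read_volume(config$paths$cbct)
  transform <- if (!is.null(config$paths$transform) &&
                   file.exists(config$paths$transform))
    read_transform(config$paths$transform) else rigid_transform()
  pipeline_log(config, "correct: running the ratio-field correction")
  res <- correct_cbct(ct, cbct, transform,
                      thresholds = do.call(segmentation_thresholds,
                                           config$thresholds),
                      spec = do.call(filter_spec, config$filter))
  paths <- c(corrected = file.path(outdir, "corrected.nii.gz"),
             labels_ct = file.path(outdir, "labels_ct.nii.gz"),
             labels_cbct = file.path(outdir, "labels_cbct.nii.gz"))
  write_volume(res$corrected, paths[["corrected"]])
  write_volume(masks_to_labels(res$masks_ct), paths[["labels_ct"]])
  write_volume(masks_to_labels(res$masks_cbct), paths[["labels_cbct"]])
  for (cls in names(res$ratio_fields)) {
    rf <- res$ratio_fields[[cls]]
    rf$voxels[is.na(rf$voxels)] <- 1
    p <- file.path(outdir, paste0("ratio_", cls, ".nii.gz"))
    write_volume(rf, p)
    paths[paste0("ratio_", cls)] <- p
  }
  report <- list(gain = res$gain, fov_fraction = mean(res$fov),
                 transform = unclass(res$transform), config = res$config)
  jsonlite::write_json(report, file.path(outdir, "correction_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(outdir, "correct", config,
                 inputs = c(config$paths$ct, config$paths$cbct),
                 outputs = paths)
  paths
}

stage_evaluate <- function(config, corrected_path = NULL) {
  outdir <- config$paths$outdir
  ct <- read_volume(config$paths$ct)
  cbct <- read_volume(config$paths$cbct)
  if (is.null(corrected_path))
    corrected_path <- file.path(outdir, "corrected.nii.gz")
  corrected <- read_volume(corrected_path)
  transform <- if (!is.null(config$paths$transform) &&
                   file.exists(config$paths$transform))
    read_transform(config$paths$transform) else rigid_transform()
  pipeline_log(config, "evaluate: HU error, histograms, WEPL")
  cbct_r <- resample_to_grid(cbct, ct$grid, transform, "linear")
  fov <- cbct_r$support &
    (resample_to_grid(cbct_volume(array(as.numeric(cbct$voxels != cbct$padding),
                                        dim = dim(cbct$voxels)), cbct$grid,
                                  unit = "HU", padding = 0),
                      ct$grid, transform, "nearest")$voxels > 0.5)
  body <- compute_body_mask(ct)
  masks <- segment_tissues(ct, segmentation_thresholds(), body)
  masks$fov <- fov
  region <- body & fov
  hist_ct <- intensity_histogram(ct, region, description = "body AND fov")
  metrics <- list(
    mae_original_hu = hu_error_metrics(cbct_r, ct, masks)$mae_hu,
    mae_corrected_hu = hu_error_metrics(corrected, ct, masks)$mae_hu,
    hist_l1_original = histogram_distance(intensity_histogram(cbct_r, region),
                                          hist_ct, "l1"),
    hist_l1_corrected = histogram_distance(intensity_histogram(corrected, region),
                                           hist_ct, "l1"),
    wepl_mean_abs_original_mm = wepl_discrepancy_map(cbct_r, ct)$mean_abs_mm,
    wepl_mean_abs_corrected_mm = wepl_discrepancy_map(corrected, ct)$mean_abs_mm)
  metrics$mae_reduction_pct <-
    100 * (1 - metrics$mae_corrected_hu / metrics$mae_original_hu)
  path <- file.path(outdir, "evaluation_report.json")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_manifest(outdir, "evaluate", config,
                 inputs = c(config$paths$ct, config$paths$cbct, corrected_path),
                 outputs = path)
  metrics
}

#' Run the simulate / register / correct / evaluate pipeline
#'
#' Executes the stages listed in `config$stages` in order. After `simulate`,
#' the generated CT/CBCT/transform paths feed the later stages unless paths
#' were supplied explicitly. Every stage writes a JSON manifest (tool version,
#' effective config, input checksums, seed) next to its outputs, sufficient to
#' re-run it.
#'
#' @param config `NULL`, a YAML file path, or a named override list (see
#'   [load_run_config()]).
#' @return A list with the effective `config`, per-stage output `paths`, and
#'   the `evaluation` metrics when the evaluate stage ran.
#' @export
run_pipeline <- function(config = NULL) {
  config <- load_run_config(config)
  out <- list(config = config, paths = list())
  for (stage in config$stages) {
    res <- switch(stage,
      simulate = {
        p <- stage_simulate(config)
        if (is.null(config$paths$ct)) config$paths$ct <- p[["ct"]]
        if (is.null(config$paths$cbct)) config$paths$cbct <- p[["cbct"]]
        if (is.null(config$paths$transform))
          config$paths$transform <- p[["transform"]]
        p
      },
      register = {
        p <- stage_register(config)
        config$paths$transform <- p[["transform"]]
        p
      },
      correct = stage_correct(config),
      evaluate = stage_evaluate(config),
      cbct_stop("cbct_configuration_error", paste("unknown stage:", stage)))
    out$paths[[stage]] <- res
    if (stage == "evaluate") out$evaluation <- res
  }
  out
}
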