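pipeline_known_keys <- c("seed", "outdir", "height", "phantom", "cohort",
                         "thresholds", "models", "slice_mode",
                         "refit_density_model")

#' Validate a pipeline configuration
#'
#' Checks the configuration before any stage runs: unknown keys are
#' rejected, sub-specs are built through their own validating
#' constructors, and scalar fields are range-checked.
#'
#' @param config Named list (or path to a JSON/YAML-free JSON file) with
#'   any of: `seed` (integer, threaded to all samplers), `outdir`,
#'   `height` (m, used for phantom indices), `phantom` (argument list for
#'   [phantom_spec()]), `cohort` (argument list for [cohort_spec()]),
#'   `thresholds` (argument list for [threshold_set()]), `models`
#'   (character subset of m1/m2/focusedon), `slice_mode` (`"mean"` or
#'   `"single"`), `refit_density_model` (logical).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    outdir = if (is.null(config$outdir)) tempfile("bodycomp_run_") else config$outdir,
    height = if (is.null(config$height)) 1.70 else config$height,
    models = if (is.null(config$models)) c("m1", "m2", "focusedon") else config$models,
    slice_mode = if (is.null(config$slice_mode)) "mean" else config$slice_mode,
    refit_density_model = isTRUE(config$refit_density_model)
  )
  check_positive(cfg$height, "height", 1L)
  if (!all(cfg$models %in% c("m1", "m2", "focusedon"))) {
    stop_field("models", "must be a subset of m1, m2, focusedon")
  }
  if (!cfg$slice_mode %in% c("mean", "single")) {
    stop_field("slice_mode", "must be 'mean' or 'single'")
  }
  cfg$phantom <- do.call(phantom_spec, c(as.list(config$phantom),
                                         list(seed = cfg$seed)))
  cfg$cohort <- do.call(cohort_spec, c(as.list(config$cohort),
                                       list(seed = cfg$seed + 1L)))
  cfg$thresholds <- do.call(threshold_set, as.list(config$thresholds))
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic body-composition pipeline
#'
#' Stages, in order: phantom simulation (NIfTI volume + ground-truth
#' labels), compartment derivation and segmentation, per-slice and
#' aggregated metrics, cohort simulation, mass estimation with each
#' requested model, and the agreement grid against the cohort's DXA-style
#' references in both 1-slice and all-slice modes. Every output is
#' written under `outdir` and recorded with an MD5 checksum in the run
#' manifest, so identical config + seed reproduces identical files.
#'
#' @param config A [pipeline_config()] (or a raw list passed through it).
#' @return The manifest list (also written as `manifest.json`):
#'   package version, seed, configuration, per-stage outputs with
#'   checksums.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  failed_stage <- "simulate-phantom"
  result <- tryCatch({
    ph <- generate_phantom(config$phantom)
    write_ct_nifti(ph$slices, out("phantom.nii"))
    write_labels_nifti(ph$masks, out("phantom_truth.nii"),
                       pixel_spacing = config$phantom$pixel_spacing)

    failed_stage <- "segment-metrics"
    ana <- analyze_stack(ph$slices, height = config$height,
                         thresholds = config$thresholds,
                         mode = config$slice_mode)
    write_labels_nifti(ana$masks, out("phantom_labels.nii"),
                       pixel_spacing = config$phantom$pixel_spacing)
    per_slice <- do.call(rbind, lapply(ana$per_slice, as.data.frame))
    per_slice$slice <- seq_len(nrow(per_slice))
    utils::write.csv(rbind(per_slice,
                           cbind(as.data.frame(ana$aggregate),
                                 slice = NA_integer_)),
                     out("phantom_metrics.csv"), row.names = FALSE)

    failed_stage <- "simulate-cohort"
    co <- generate_cohort(config$cohort)
    write_cohort(co$subjects, out("cohort.csv"))
    utils::write.csv(co$metrics, out("cohort_ct_metrics.csv"),
                     row.names = FALSE)

    failed_stage <- "estimate"
    ests <- do.call(rbind, lapply(config$models, function(m) {
      estimate_masses(co$metrics, co$subjects, m)
    }))
    utils::write.csv(ests, out("estimates.csv"), row.names = FALSE)

    fitted <- NULL
    if (config$refit_density_model) {
      x <- density_weighted_predictor(co$subjects$weight,
                                      co$metrics$roi_mean_hu,
                                      co$metrics$fat_pct,
                                      co$metrics$fat_mean_hu)
      fitted <- fit_linear(x, co$subjects$dxa_fm, "density_weighted_fat")
      jsonlite::write_json(list(slope = fitted$slope,
                                intercept = fitted$intercept,
                                predictor_kind = fitted$predictor_kind,
                                n = fitted$fit$n, sigma = fitted$fit$sigma,
                                r_squared = fitted$fit$r_squared),
                           out("fitted_model.json"), auto_unbox = TRUE,
                           digits = NA)
    }

    failed_stage <- "agree"
    tab2 <- summarize_table2(co$subjects,
                             list(cohort = co$metrics),
                             models = config$models)
    utils::write.csv(tab2, out("table2.csv"), row.names = FALSE)
    list(ana = ana, tab2 = tab2, fitted = fitted)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", failed_stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- list.files(config$outdir, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(checksums) <- files
  manifest <- list(
    package = "ctbodycomp",
    version = as.character(utils::packageVersion("ctbodycomp")),
    seed = config$seed,
    slice_mode = config$slice_mode,
    models = config$models,
    n_slices = config$phantom$n_slices,
    n_subjects = config$cohort$n_subjects,
    outputs = checksums
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
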