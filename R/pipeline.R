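## Orchestration: simulate -> calibrate -> quantify -> threshold ->
## classify -> evaluate as one reproducible run that persists every
## intermediate artifact (CSV/TIFF/JSON) under an output directory.

## Sub-seed offsets: one global seed is fanned out per stage so that
## enabling or disabling a stage never perturbs another stage's draws.
SEED_OFFSETS <- c(spectra = 101L, titration = 202L, image = 303L, cohort = 404L)

#' Pipeline configuration
#'
#' Assembles the stage toggles, generator configurations, threshold
#' source and output location for one reproducible run. The global
#' `seed` is fanned out to per-stage sub-seeds by fixed offsets.
#'
#' @param out_dir directory for run artifacts (created if absent).
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "calibrate", "quantify", "threshold", "classify",
#'   "evaluate")`.
#' @param spectra a [spectra_config()] (its seed is overridden).
#' @param image an [image_config()] or `NULL` to skip image synthesis.
#' @param cohort a [cohort_config()].
#' @param threshold_source `"derive_from_training"`, or a numeric pair
#'   `c(t_ntr, t_vis)` for a fixed threshold.
#' @param training_csv,test_csv optional paths to externally supplied
#'   intensity tables (columns `sample_id,i_ntr,i_vis[,he_label]`);
#'   when given they replace the simulated tables, so the same run
#'   works on real per-specimen measurements.
#' @param seed global integer seed.
#' @param verbose print per-stage progress.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("marginscreen_run_"),
                            stages = c("simulate", "calibrate", "threshold",
                                       "classify", "evaluate"),
                            spectra = spectra_config(),
                            image = NULL,
                            cohort = cohort_config(),
                            threshold_source = "derive_from_training",
                            training_csv = NULL, test_csv = NULL,
                            seed = 1L, verbose = FALSE) {
  all_stages <- c("simulate", "calibrate", "quantify", "threshold",
                  "classify", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.numeric(threshold_source)) {
    if (length(threshold_source) != 2L ||
        any(threshold_source < 0 | threshold_source > 255))
      stopf("a fixed threshold must be a pair within [0, 255]")
  } else if (!identical(threshold_source, "derive_from_training")) {
    stopf("`threshold_source` must be \"derive_from_training\" or c(t_ntr, t_vis)")
  }
  for (p in c(training_csv, test_csv))
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  structure(list(out_dir = out_dir, stages = stages, spectra = spectra,
                 image = image, cohort = cohort,
                 threshold_source = threshold_source,
                 training_csv = training_csv, test_csv = test_csv,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Flat, human-editable key-value file; round-trips everything needed to
#' reproduce a run (re-running from the persisted config reproduces the
#' report byte for byte).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$spectra <- unclass(x$spectra)
  x$cohort <- unclass(x$cohort)
  if (!is.null(x$image)) x$image <- unclass(x$image)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    out_dir = x$out_dir, stages = unlist(x$stages),
    spectra = do.call(spectra_config, x$spectra),
    image = if (!is.null(x$image)) do.call(image_config, x$image),
    cohort = do.call(cohort_config, x$cohort),
    threshold_source = if (is.numeric(unlist(x$threshold_source)))
      unlist(x$threshold_source) else x$threshold_source,
    training_csv = x$training_csv, test_csv = x$test_csv,
    seed = x$seed, verbose = isTRUE(x$verbose))
}

read_sample_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("i_ntr", "i_vis") %in% names(df)))
    stopf("%s must have columns i_ntr and i_vis", path)
  df
}

#' Run the pre-screening pipeline
#'
#' Executes the enabled stages in order, writing every intermediate
#' artifact under `config$out_dir`:
#' \describe{
#'   \item{simulate}{viscosity/titration spectra CSVs, training/test
#'     cohort CSVs, and (if an image config is given) the paired
#'     `_ntr.tif` / `_vis.tif` channel images plus truth CSV.}
#'   \item{calibrate}{Forster-Hoffmann and titration fits and the
#'     3-sigma/k LOD, written to `calibration.json`.}
#'   \item{quantify}{segments the channel images and measures each
#'     specimen's per-channel maximum (`quantified_samples.csv`).}
#'   \item{threshold}{derives the K-means-centroid threshold from the
#'     training table, or adopts the configured fixed pair.}
#'   \item{classify}{fills the `call` column of the test table.}
#'   \item{evaluate}{confusion summary and crosstab versus H&E labels.}
#' }
#' The run report carries the triage verdict: if every specimen is
#' called `-` the cohort is flagged tumor-free at pre-screen level
#' (`cohort_negative`); any `++`/`+` specimen is flagged for priority
#' pathology review.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `"run_report"`: per-stage status, output file
#'   inventory, threshold, confusion summary, triage verdict, config
#'   echo, seed and package version. Also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...)
    if (config$verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                        sprintf(fmt, ...)))
  art <- function(name) file.path(config$out_dir, name)
  report <- list(stages = list(), files = character(),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("marginscreen")))
  record <- function(name, files = character()) {
    report$stages[[name]] <<- "ok"
    report$files <<- c(report$files, files)
  }
  on_stage <- function(name) name %in% config$stages

  training <- test <- NULL
  calib <- NULL

  tryCatch({
    if (on_stage("simulate")) {
      say("simulate: spectra + cohort")
      sp <- config$spectra; sp$seed <- config$seed + SEED_OFFSETS[["spectra"]]
      visc <- gen_viscosity_series(sp)
      sp$seed <- config$seed + SEED_OFFSETS[["titration"]]
      titr <- gen_ntr_titration(sp)
      write_emission_series(visc, art("viscosity_series.csv"))
      write_emission_series(titr$series, art("ntr_titration.csv"))
      utils::write.csv(data.frame(blank = titr$blanks), art("blanks.csv"),
                       row.names = FALSE)
      co <- config$cohort; co$seed <- config$seed + SEED_OFFSETS[["cohort"]]
      cohort <- gen_margin_cohort(co)
      training <- cohort$training; test <- cohort$test
      utils::write.csv(training, art("training_samples.csv"), row.names = FALSE)
      utils::write.csv(test, art("test_samples.csv"), row.names = FALSE)
      files <- c("viscosity_series.csv", "ntr_titration.csv", "blanks.csv",
                 "training_samples.csv", "test_samples.csv")
      if (!is.null(config$image)) {
        im <- config$image; im$seed <- config$seed + SEED_OFFSETS[["image"]]
        timg <- gen_tissue_image(im)
        write_channel_tiff(timg$ntr, art("field_ntr.tif"))
        write_channel_tiff(timg$vis, art("field_vis.tif"))
        utils::write.csv(timg$truth, art("field_truth.csv"), row.names = FALSE)
        files <- c(files, "field_ntr.tif", "field_vis.tif", "field_truth.csv")
      }
      record("simulate", files)
    }

    if (on_stage("calibrate")) {
      say("calibrate: Forster-Hoffmann + titration + LOD")
      fh <- fit_forster_hoffmann(read_emission_series(art("viscosity_series.csv")))
      titr <- fit_titration(read_emission_series(art("ntr_titration.csv")))
      blanks <- utils::read.csv(art("blanks.csv"))$blank
      lod <- compute_lod(titr$slope_k, blank_sigma(blanks))
      calib <- list(forster_hoffmann = unclass(fh), titration = unclass(titr),
                    lod = unclass(lod), lod_display_ng_per_ml = format_lod(lod))
      jsonlite::write_json(calib, art("calibration.json"), auto_unbox = TRUE,
                           digits = NA)
      record("calibrate", "calibration.json")
    }

    if (on_stage("quantify")) {
      say("quantify: segment + measure channel images")
      ntr <- read_channel_tiff(art("field_ntr.tif"))
      vis <- read_channel_tiff(art("field_vis.tif"))
      regions <- segment_samples(ntr, vis)
      quant <- measure_samples(regions, ntr, vis)
      utils::write.csv(quant, art("quantified_samples.csv"), row.names = FALSE)
      record("quantify", "quantified_samples.csv")
    }

    if (!is.null(config$training_csv)) training <- read_sample_csv(config$training_csv)
    if (!is.null(config$test_csv)) test <- read_sample_csv(config$test_csv)
    if (is.null(training) && file.exists(art("training_samples.csv")))
      training <- read_sample_csv(art("training_samples.csv"))
    if (is.null(test) && file.exists(art("test_samples.csv")))
      test <- read_sample_csv(art("test_samples.csv"))

    thr <- NULL
    if (on_stage("threshold")) {
      if (is.numeric(config$threshold_source)) {
        thr <- threshold(config$threshold_source[1], config$threshold_source[2])
      } else {
        if (is.null(training))
          stopf("threshold stage needs a training table (simulate or training_csv)")
        thr <- derive_threshold(training, seed = config$seed)
      }
      say("threshold: (%.1f, %.1f)", thr$t_ntr, thr$t_vis)
      jsonlite::write_json(unclass(thr), art("threshold.json"),
                           auto_unbox = TRUE, digits = NA)
      record("threshold", "threshold.json")
      report$threshold <- unclass(thr)
    }

    called <- NULL
    if (on_stage("classify")) {
      if (is.null(test) || nrow(test) == 0L)
        stopf("classify stage received an empty test cohort")
      if (is.null(thr)) stopf("classify stage needs a threshold stage")
      called <- classify_cohort(test, thr)
      utils::write.csv(called, art("classified_samples.csv"), row.names = FALSE)
      record("classify", "classified_samples.csv")
      report$verdict <- if (all(called$call == "-")) "cohort_negative"
                        else "priority_review"
      report$n_flagged <- sum(called$call != "-")
    }

    if (on_stage("evaluate")) {
      if (is.null(called)) stopf("evaluate stage needs classified records")
      if (!"he_label" %in% names(called))
        stopf("evaluate stage needs H&E labels on the test table")
      cs <- confusion_summary(called)
      ct <- group_crosstab(called)
      write_crosstab_csv(ct, art("crosstab.csv"))
      record("evaluate", "crosstab.csv")
      report$confusion <- unclass(cs)
    }
  }, error = function(e) {
    report$error <<- conditionMessage(e)
    jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    stopf("pipeline failed: %s", conditionMessage(e))
  })

  report$calibration <- calib
  report$config <- list(stages = config$stages,
                        threshold_source = config$threshold_source,
                        out_dir = config$out_dir)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), art("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("marginscreen run report\n")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$threshold))
    cat(sprintf("  threshold (ntr, vis) = (%.1f, %.1f)\n",
                x$threshold$t_ntr, x$threshold$t_vis))
  if (!is.null(x$verdict)) cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$confusion)) {
    cs <- x$confusion
    cat(sprintf("  specificity %s, sensitivity %s (TP=%d FP=%d TN=%d FN=%d)\n",
                ifelse(is.na(cs$specificity), "undefined",
                       sprintf("%.1f%%", 100 * cs$specificity)),
                ifelse(is.na(cs$sensitivity), "undefined",
                       sprintf("%.1f%%", 100 * cs$sensitivity)),
                cs$tp, cs$fp, cs$tn, cs$fn))
  }
  invisible(x)
}
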