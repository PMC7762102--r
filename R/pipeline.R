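#' Pipeline configuration
#'
#' Bundles the synthetic-cohort, feature-extraction and inference
#' settings, round-trips losslessly through YAML, and is written in
#' resolved form next to every run's outputs.
#'
#' @param synthetic a [synthetic_config()].
#' @param entropy an [entropy_params()].
#' @param hrf an [hrf_params()].
#' @param bins conditional-entropy quantile bins.
#' @param envelope_rate_hz EEG envelope decimation target (Hz).
#' @param n_boot bootstrap resamples for CI filtering.
#' @param alpha significance level (stationarity gate and FDR).
#' @param families classifier feature families to run.
#' @param phases phases to analyze.
#' @param thresholds optional named list `family -> phase -> threshold`
#'   of operating points.
#' @param seed global seed for the inference stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            entropy = entropy_params(),
                            hrf = hrf_params(),
                            bins = 8, envelope_rate_hz = 25,
                            n_boot = 1000, alpha = 0.05,
                            families = c("EEG", "fNIRS", "NC"),
                            phases = NULL, thresholds = NULL,
                            seed = 1L) {
  if (is.null(phases)) phases <- names(synthetic$phase_durations)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # named atomic vectors become YAML maps so names survive the trip
  to_plain <- function(x) {
    if (is.list(x)) lapply(x, to_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_plain(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, lapply(raw$synthetic, function(x)
    if (is.list(x)) unlist(x) else x))
  pipeline_config(
    synthetic = syn,
    entropy = do.call(entropy_params, raw$entropy),
    hrf = do.call(hrf_params, raw$hrf),
    bins = raw$bins, envelope_rate_hz = raw$envelope_rate_hz,
    n_boot = raw$n_boot, alpha = raw$alpha,
    families = unlist(raw$families), phases = unlist(raw$phases),
    thresholds = raw$thresholds, seed = raw$seed)
}

feature_config_from <- function(config) {
  feature_config(entropy = config$entropy, bins = config$bins,
                 hrf = config$hrf,
                 envelope_rate_hz = config$envelope_rate_hz,
                 stationarity_alpha = config$alpha)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort and writes, per subject, an EDF file
#' with the EEG and a CSV + JSON pair with the optical intensities,
#' plus a cohort `manifest.json` (ids, labels, ages, phase markers,
#' per-subject seeds) and the resolved configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output directory is not writable")
  cohort <- generate_cohort(config$synthetic)
  n <- length(cohort)
  seeds <- (as.numeric(config$synthetic$seed) + 7919 * seq_len(n)) %%
    2147483647
  manifest <- list(package_version =
                     as.character(utils::packageVersion("nvcomplexity")),
                   subjects = list())
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    write_edf(s$eeg, file.path(out_dir, paste0(s$subject_id, ".edf")),
              patient_id = s$subject_id)
    write_optical(s$optical,
                  file.path(out_dir, paste0(s$subject_id, "_optical")))
    manifest$subjects[[i]] <- list(
      subject_id = s$subject_id, group = s$group, age = s$age,
      seed = seeds[i],
      phase_markers = s$phase_markers)
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  message(sprintf("simulate: wrote %d subjects to %s", n, out_dir))
  invisible(mpath)
}

# Load a subject written by run_simulate back into memory.
load_subject <- function(dir, entry) {
  eeg <- read_edf(file.path(dir, paste0(entry$subject_id, ".edf")))
  optical <- read_optical(file.path(dir,
                                    paste0(entry$subject_id, "_optical")))
  pm <- as.data.frame(entry$phase_markers)
  structure(list(subject_id = entry$subject_id, group = entry$group,
                 age = entry$age, eeg = eeg, optical = optical,
                 phase_markers = pm),
            class = "subject_recording")
}

#' Compute the feature table from simulated files
#'
#' Reads every subject of a simulated cohort directory and writes
#' `features.csv` (one row per subject x phase: the 17 features plus
#' validity flags) next to the resolved configuration.
#'
#' @param config a [pipeline_config()].
#' @param cohort_dir directory written by [run_simulate()].
#' @param out_dir output directory.
#' @return path of the feature CSV, invisibly.
#' @export
run_features <- function(config, cohort_dir, out_dir = cohort_dir) {
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- list()
  for (entry in manifest$subjects) {
    s <- tryCatch(load_subject(cohort_dir, entry), error = function(e) {
      warning(sprintf("subject %s skipped: %s", entry$subject_id,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(s)) cohort[[length(cohort) + 1L]] <- s
  }
  if (length(cohort) == 0L) stop("no subject could be loaded")
  tab <- cohort_features(cohort, phases = config$phases,
                         config = feature_config_from(config))
  fpath <- file.path(out_dir, "features.csv")
  utils::write.csv(tab, fpath, row.names = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  message(sprintf("features: wrote %d rows to %s", nrow(tab), fpath))
  invisible(fpath)
}

#' Group inference and classification from a feature table
#'
#' Per phase: CI-filtered FDR-corrected t-tests (CSV), per-family
#' leave-one-out GLM classification with ROC (JSON), paired AUC
#' comparisons of the NC family against EEG and fNIRS, and ROC plots
#' (SVG, best effort).
#'
#' @param config a [pipeline_config()].
#' @param features_csv path to `features.csv` from [run_features()].
#' @param out_dir output directory.
#' @return list of per-phase result bundles, invisibly.
#' @export
run_inference <- function(config, features_csv, out_dir) {
  tab <- utils::read.csv(features_csv, stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  if (length(unique(tab$group)) < 2)
    stop("feature table contains a single class")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  results <- list()
  for (ph in config$phases) {
    tests <- ttests_fdr(tab, ph, n_boot = config$n_boot)
    utils::write.csv(tests,
                     file.path(out_dir, sprintf("ttests_%s.csv", ph)),
                     row.names = FALSE)
    rocs <- list()
    for (fam in config$families) {
      th <- config$thresholds[[fam]][[ph]]
      res <- glm_loocv_classify(tab, fam, ph)
      if (!is.null(th)) res <- roc_analysis(res$scores, res$labels, th)
      rocs[[fam]] <- res
      jsonlite::write_json(
        list(family = fam, phase = ph, auc = res$auc,
             threshold = res$threshold, sensitivity = res$sensitivity,
             specificity = res$specificity,
             beta = as.list(res$beta), scores = res$scores,
             labels = res$labels, roc = res$roc),
        file.path(out_dir, sprintf("roc_%s_%s.json", fam, ph)),
        auto_unbox = TRUE, digits = NA)
    }
    comparisons <- list()
    if (all(c("NC", "EEG") %in% names(rocs)))
      comparisons$NC_vs_EEG <- compare_auc(rocs$NC, rocs$EEG)
    if (all(c("NC", "fNIRS") %in% names(rocs)))
      comparisons$NC_vs_fNIRS <- compare_auc(rocs$NC, rocs$fNIRS)
    jsonlite::write_json(comparisons,
                         file.path(out_dir,
                                   sprintf("auc_comparisons_%s.json", ph)),
                         auto_unbox = TRUE, digits = NA)
    try(plot_roc_bundle(rocs, ph, out_dir), silent = TRUE)
    results[[ph]] <- list(tests = tests, rocs = rocs,
                          comparisons = comparisons)
  }
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(results)
}

# ROC curves of the three families for one phase, SVG.
plot_roc_bundle <- function(rocs, phase, out_dir) {
  path <- file.path(out_dir, sprintf("roc_%s.svg", phase))
  grDevices::svg(path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC, %s", phase))
  cols <- c(EEG = "steelblue", fNIRS = "darkorange", NC = "forestgreen")
  for (fam in names(rocs)) {
    r <- rocs[[fam]]$roc
    graphics::lines(r$fpr, r$tpr, type = "s", col = cols[[fam]], lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", names(rocs),
                                    vapply(rocs, `[[`, 0, "auc")),
                   col = cols[names(rocs)], lwd = 2, bty = "n")
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> features -> inference, each stage writing its outputs
#' (and the resolved configuration) under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the inference results, invisibly.
#' @export
run_all <- function(config, out_dir) {
  run_simulate(config, file.path(out_dir, "cohort"))
  fpath <- run_features(config, file.path(out_dir, "cohort"),
                        file.path(out_dir, "features"))
  run_inference(config, fpath, file.path(out_dir, "inference"))
}
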