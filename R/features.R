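#' The 17 complexity feature names, in canonical order
#'
#' Five EEG sample entropies (band GFP envelopes), two fNIRS sample
#' entropies (averaged hemoglobin), ten neurovascular-coupling
#' conditional entropies (each hemoglobin form x each EEG band). The
#' order is fixed so classifier beta-weights are attributable.
#'
#' @return character vector of length 17.
#' @export
feature_names <- function() {
  bands <- eeg_band_table()$name
  c(paste0("sampen_eeg_", bands),
    "sampen_o2hb", "sampen_hhb",
    paste0("conden_o2hb_", bands),
    paste0("conden_hhb_", bands))
}

#' Analysis configuration for feature extraction
#'
#' @param entropy an [entropy_params()].
#' @param bins quantile bins for conditional entropy.
#' @param hrf an [hrf_params()].
#' @param envelope_rate_hz rate (Hz) to which EEG envelopes are
#'   decimated (anti-aliased) before sample entropy; keeps the O(N^2)
#'   template search tractable without touching the sub-Hz dynamics the
#'   entropy summarizes. Set `NULL` to disable.
#' @param despike,despike_alpha OD despiking switch and tail
#'   probability.
#' @param stationarity_alpha level of the Phillips-Perron gate.
#' @param stationarity_test_rate_hz effective rate (Hz) at which the
#'   unit-root statistic is evaluated for the slow hemodynamic-scale
#'   series (see [check_stationarity()]'s `subsample`); a few times the
#'   0.4 Hz band edge.
#' @param edge_trim_s seconds dropped at each epoch edge after the
#'   Hilbert transform (analytic-signal edge transients).
#' @param constants a [chromophore_constants()].
#' @param analysis_duration_s optional common analyzed duration in
#'   seconds (epochs are cut to this length); `NULL` = full phase.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(entropy = entropy_params(), bins = 8,
                           hrf = hrf_params(), envelope_rate_hz = 25,
                           despike = TRUE, despike_alpha = 0.1,
                           stationarity_alpha = 0.05,
                           stationarity_test_rate_hz = 1.5,
                           edge_trim_s = 1,
                           constants = chromophore_constants(),
                           analysis_duration_s = NULL) {
  structure(as.list(environment()), class = "feature_config")
}

# Slice an optical recording to [start, end) seconds.
slice_optical <- function(optical, markers, phase, max_duration = NULL) {
  row <- markers[markers$phase == phase, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("phase '%s' not found in markers", phase))
  end <- row$end
  if (!is.null(max_duration)) end <- min(end, row$start + max_duration)
  t <- (seq_len(dim(optical$intensities)[3]) - 1) / optical$rate
  keep <- which(t >= row$start & t < end)
  optical_recording(optical$intensities[, , keep, drop = FALSE],
                    optical$rate, optical$wavelengths, optical$geometry)
}

# Gate a series through the stationarity check; returns list(series,
# valid). Errors (constant series etc.) invalidate the feature instead
# of aborting the subject.
gate_series <- function(x, alpha, subsample = 1) {
  out <- tryCatch(check_stationarity(x, alpha = alpha,
                                     subsample = subsample),
                  error = function(e) NULL)
  if (is.null(out))
    return(list(series = x, valid = FALSE, detrended = FALSE))
  list(series = out$series, valid = out$stationary,
       detrended = out$detrended)
}

#' Per-subject, per-phase complexity feature vector
#'
#' Runs the EEG and fNIRS preprocessing chains on one task phase and
#' computes the 17 complexity features: sample entropy of the five
#' band-limited EEG GFP envelopes, sample entropy of the averaged
#' oxy-/deoxy-hemoglobin traces, and the conditional entropy of each
#' hemoglobin trace given each HRF-convolved band envelope (the
#' neurovascular-coupling index). Series failing the stationarity gate
#' yield `NA` features flagged invalid rather than being silently
#' zeroed.
#'
#' @param subject a `subject_recording` (see [generate_subject()]).
#' @param phase phase name present in the subject's markers.
#' @param config a [feature_config()].
#' @return object of class `feature_vector`: list with `features`
#'   (named numeric, length 17), `valid` (named logical), `subject_id`,
#'   `group`, `age`, `phase`.
#' @export
compute_feature_vector <- function(subject, phase,
                                   config = feature_config()) {
  markers <- subject$phase_markers
  if (!phase %in% markers$phase)
    stop(sprintf("phase '%s' absent from subject markers", phase))
  dur <- config$analysis_duration_s

  # --- EEG chain ---------------------------------------------------
  row <- markers[markers$phase == phase, ]
  eeg_markers <- markers
  if (!is.null(dur))
    eeg_markers$end <- pmin(eeg_markers$end, eeg_markers$start + dur)
  eeg_phase <- slice_phase(subject$eeg, eeg_markers, phase)
  eeg_f <- broadband_filter(eeg_phase)
  bands <- eeg_band_table()$name
  gfp_bands <- lapply(bands, function(b) {
    env <- band_envelope(eeg_f, band_definition(b))
    env <- trim_edges(env, config$edge_trim_s)
    global_field_power(env)
  })
  names(gfp_bands) <- bands

  # --- fNIRS chain -------------------------------------------------
  optical_phase <- slice_optical(subject$optical, markers, phase, dur)
  fn <- fnirs_preprocess(optical_phase, subject$age,
                         constants = config$constants,
                         despike = config$despike,
                         alpha = config$despike_alpha)
  hb <- fn$hb_mean

  feats <- stats::setNames(rep(NA_real_, 17L), feature_names())
  valid <- stats::setNames(rep(FALSE, 17L), feature_names())

  # --- EEG SampEn on decimated band GFP envelopes ------------------
  # The stationarity of the EEG side is a property of the envelope
  # itself; its verdict also gates the HRF-convolved copy used for the
  # coupling features (convolution is deterministic smoothing).
  env_rate <- subject$eeg$rate
  env_gate <- list()
  for (b in bands) {
    g <- gfp_bands[[b]]$values
    r_out <- env_rate
    if (!is.null(config$envelope_rate_hz) &&
        config$envelope_rate_hz < env_rate) {
      fac <- max(1L, round(env_rate / config$envelope_rate_hz))
      g <- decimate_series(g, fac)
      r_out <- env_rate / fac
    }
    gated <- gate_series(g, config$stationarity_alpha)
    env_gate[[b]] <- gated
    if (gated$detrended) {
      # mirror the detrend on the full-rate envelope feeding the
      # coupling features
      t_idx <- seq_along(gfp_bands[[b]]$values)
      gfp_bands[[b]]$values <-
        stats::residuals(stats::lm(gfp_bands[[b]]$values ~ t_idx))
    }
    nm <- paste0("sampen_eeg_", b)
    if (gated$valid) {
      v <- tryCatch(sample_entropy(gated$series, config$entropy),
                    error = function(e) NA_real_)
      feats[nm] <- v
      valid[nm] <- is.finite(v)
    }
  }

  # --- fNIRS SampEn on averaged hemoglobin -------------------------
  hb_traces <- list(o2hb = drop(hb$o2hb), hhb = drop(hb$hhb))
  hemo_sub <- max(1L, round(hb$rate / config$stationarity_test_rate_hz))
  gated_hb <- list()
  for (chrom in names(hb_traces)) {
    gated <- gate_series(hb_traces[[chrom]], config$stationarity_alpha,
                         subsample = hemo_sub)
    gated_hb[[chrom]] <- gated
    nm <- paste0("sampen_", chrom)
    if (gated$valid) {
      v <- tryCatch(sample_entropy(gated$series, config$entropy),
                    error = function(e) NA_real_)
      feats[nm] <- v
      valid[nm] <- is.finite(v)
    }
  }

  # --- NC CondEn: hemoglobin given HRF-convolved band envelope -----
  hrf_k <- canonical_hrf(config$hrf, rate = env_rate)
  fr <- hb$rate
  for (b in bands) {
    conv <- eeg_to_hemo_timescale(gfp_bands[[b]], hrf_k, fr)
    # align hemoglobin to the convolved series' start (envelope edge
    # trim + kernel start-up)
    offset_s <- config$edge_trim_s + conv$start_s
    j0 <- floor(offset_s * fr) + 1L
    for (chrom in names(hb_traces)) {
      nm <- paste0("conden_", chrom, "_", b)
      y_full <- gated_hb[[chrom]]$series
      if (j0 > length(y_full)) next
      y <- y_full[j0:length(y_full)]
      nn <- min(length(conv$values), length(y))
      if (nn < config$bins^2 / 5) next
      if (env_gate[[b]]$valid && gated_hb[[chrom]]$valid) {
        v <- tryCatch(
          conditional_entropy(conv$values[seq_len(nn)], y[seq_len(nn)],
                              bins = config$bins),
          error = function(e) NA_real_)
        feats[nm] <- v
        valid[nm] <- is.finite(v)
      }
    }
  }

  if (!any(valid)) stop("subject-phase unusable: all features invalid")
  structure(list(features = feats, valid = valid,
                 subject_id = subject$subject_id, group = subject$group,
                 age = subject$age, phase = phase),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> subject %s, phase %s, group %d (%d/17 valid)\n",
              x$subject_id, x$phase, x$group, sum(x$valid)))
  print(round(x$features, 4))
  invisible(x)
}

#' Cohort-level feature table
#'
#' Computes the 17-feature vector for every subject and phase, after
#' equalizing the analyzed duration across all subject-phases (epochs
#' are cut to the shortest one, as complexity estimates are
#' length-sensitive).
#'
#' @param cohort list of `subject_recording`s.
#' @param phases phase names to analyze; default all phases of the
#'   first subject.
#' @param config a [feature_config()]; its `analysis_duration_s` is
#'   filled in with the common minimum duration when `NULL`.
#' @param verbose print per-subject progress.
#' @return `cohort_table`: data.frame with one row per subject x phase,
#'   columns `subject_id`, `group`, `age`, `phase`, the 17 features and
#'   17 `valid_*` flags.
#' @export
cohort_features <- function(cohort, phases = NULL,
                            config = feature_config(), verbose = FALSE) {
  stopifnot(length(cohort) >= 1L)
  if (is.null(phases)) phases <- cohort[[1]]$phase_markers$phase
  if (is.null(config$analysis_duration_s)) {
    durs <- unlist(lapply(cohort, function(s) {
      m <- s$phase_markers
      m$end[m$phase %in% phases] - m$start[m$phase %in% phases]
    }))
    config$analysis_duration_s <- min(durs)
  }
  rows <- list()
  for (s in cohort) {
    for (ph in phases) {
      fv <- tryCatch(compute_feature_vector(s, ph, config),
                     error = function(e) {
                       warning(sprintf("subject %s phase %s skipped: %s",
                                       s$subject_id, ph, conditionMessage(e)))
                       NULL
                     })
      if (is.null(fv)) next
      row <- data.frame(subject_id = fv$subject_id, group = fv$group,
                        age = fv$age, phase = fv$phase,
                        stringsAsFactors = FALSE)
      row <- cbind(row, as.data.frame(as.list(fv$features)),
                   stats::setNames(as.data.frame(as.list(fv$valid)),
                                   paste0("valid_", names(fv$valid))))
      rows[[length(rows) + 1L]] <- row
      if (verbose)
        message(sprintf("features: subject %s phase %s (%d/17 valid)",
                        fv$subject_id, ph, sum(fv$valid)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
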