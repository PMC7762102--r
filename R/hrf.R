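#' Canonical hemodynamic response parameters
#'
#' Double-gamma kernel: a positive gamma peaking at `peak_delay` seconds
#' minus a later, smaller undershoot gamma. Delays are times-to-peak
#' (the gamma modes), dispersions are the gamma scales in seconds.
#'
#' @param peak_delay,undershoot_delay times to peak (s).
#' @param peak_dispersion,undershoot_dispersion gamma scales (s).
#' @param peak_undershoot_ratio peak/undershoot amplitude ratio.
#' @param kernel_length kernel support (s).
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay,
            peak_dispersion > 0, undershoot_dispersion > 0,
            peak_undershoot_ratio > 0, kernel_length > undershoot_delay)
  structure(as.list(environment()), class = "hrf_params")
}

#' Sampled canonical hemodynamic response
#'
#' @param params an [hrf_params()].
#' @param rate sampling rate in Hz.
#' @return numeric kernel sampled on `[0, kernel_length]`, peak-normalized
#'   to 1, with attribute `"rate"`.
#' @export
canonical_hrf <- function(params = hrf_params(), rate) {
  stopifnot(inherits(params, "hrf_params"), rate > 0)
  t <- seq(0, params$kernel_length, by = 1 / rate)
  if (length(t) < 10) stop("kernel too short: fewer than 10 samples")
  # shape = 1 + delay/dispersion puts the gamma mode exactly at `delay`
  shape1 <- 1 + params$peak_delay / params$peak_dispersion
  shape2 <- 1 + params$undershoot_delay / params$undershoot_dispersion
  k <- stats::dgamma(t, shape = shape1, scale = params$peak_dispersion) -
    stats::dgamma(t, shape = shape2, scale = params$undershoot_dispersion) /
      params$peak_undershoot_ratio
  k <- k / max(k)
  attr(k, "rate") <- rate
  k
}

#' Bring an EEG envelope onto the hemodynamic timescale
#'
#' Convolves a (GFP) envelope with the canonical HRF (causal linear
#' convolution, same-length output), applies an anti-alias zero-phase
#' low-pass at `0.4 * target_rate`, resamples onto the fNIRS time grid,
#' and (by default) discards the first `kernel_length` seconds of
#' convolution start-up transient.
#'
#' @param gfp_env a `gfp_series` (see [global_field_power()]) or a list
#'   with `values` and `rate`.
#' @param hrf kernel from [canonical_hrf()] (carries its own rate, which
#'   must match `gfp_env$rate`).
#' @param target_rate output rate in Hz (must not exceed the input rate).
#' @param trim_startup discard the initial `kernel_length` seconds.
#' @return list with `values`, `rate = target_rate`, and `start_s`, the
#'   time of the first output sample relative to the input's first
#'   sample.
#' @export
eeg_to_hemo_timescale <- function(gfp_env, hrf, target_rate,
                                  trim_startup = TRUE) {
  x <- gfp_env$values
  rate <- gfp_env$rate
  if (target_rate > rate) stop("target rate exceeds the source rate")
  if (!isTRUE(all.equal(attr(hrf, "rate"), rate)))
    stop("HRF kernel rate must match the envelope rate")
  n <- length(x)
  # causal linear convolution, first n samples
  y <- stats::convolve(x, rev(as.numeric(hrf)), type = "open")[seq_len(n)]
  # anti-alias before resampling
  nyq <- rate / 2
  bf <- signal::butter(4, (0.4 * target_rate) / nyq, type = "low")
  y <- filtfilt_zp(bf, y)
  t_src <- (seq_len(n) - 1) / rate
  kernel_s <- (length(hrf) - 1) / rate
  start_s <- if (trim_startup) kernel_s else 0
  t_out <- seq(start_s, t_src[n], by = 1 / target_rate)
  vals <- stats::approx(t_src, y, xout = t_out)$y
  list(values = vals, rate = target_rate, start_s = start_s)
}
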