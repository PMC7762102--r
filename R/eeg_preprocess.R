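#' EEG frequency bands of interest
#'
#' The five canonical bands used throughout the analysis. Note that the
#' theta (3.5-8.2 Hz) and alpha (7.4-13 Hz) bands overlap by design; each
#' band is filtered independently so the overlap is harmless.
#'
#' @param name band name, one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`.
#' @param low_hz,high_hz optional cutoffs overriding the defaults.
#' @return list with `name`, `low_hz`, `high_hz` (class `band_definition`).
#' @export
band_definition <- function(name, low_hz = NULL, high_hz = NULL) {
  defaults <- eeg_band_table()
  if (is.null(low_hz) || is.null(high_hz)) {
    row <- defaults[defaults$name == name, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("unknown band '%s'", name))
    if (is.null(low_hz)) low_hz <- row$low_hz
    if (is.null(high_hz)) high_hz <- row$high_hz
  }
  if (!(low_hz > 0 && high_hz > low_hz))
    stop("band cutoffs must satisfy 0 < low < high")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Default EEG band table
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`, in the
#'   fixed feature order delta, theta, alpha, beta, gamma.
#' @export
eeg_band_table <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1,       3.5,     7.4,     13,     26),
    high_hz = c(4,       8.2,     13,      30,     40),
    stringsAsFactors = FALSE
  )
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection edge
# padding (three filter lengths) to suppress start-up transients.
filtfilt_zp <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- length(x)
  pad <- min(3L * 10L * (max(length(a), length(b)) - 1L), n - 1L)
  idx_f <- (pad + 1L):2L
  idx_b <- (n - 1L):(n - pad)
  ext <- c(2 * x[1L] - x[idx_f], x, 2 * x[n] - x[idx_b])
  y <- .iir_filter(b, a, ext)
  y <- rev(.iir_filter(b, a, rev(y)))
  y[pad + seq_len(n)]
}

# Zero-phase (forward-backward) Butterworth filter applied row-wise.
# W is in normalized frequency (fraction of Nyquist), type as in
# signal::butter.
zerophase_butter <- function(mat, rate, n, w_hz, type) {
  nyq <- rate / 2
  bf <- signal::butter(n, w_hz / nyq, type = type)
  out <- mat
  for (i in seq_len(nrow(mat))) out[i, ] <- filtfilt_zp(bf, mat[i, ])
  out
}

# Anti-aliased integer-factor decimation: 8th-order zero-phase
# Butterworth at 80% of the output Nyquist, then subsampling.
decimate_series <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(x)
  bf <- signal::butter(8, 0.8 / factor, type = "low")
  filtfilt_zp(bf, x)[seq(1L, length(x), by = factor)]
}

#' Broadband EEG filtering
#'
#' Band-pass 1-80 Hz plus 50 Hz notch, both 2nd-order Butterworth applied
#' forward-backward (zero phase lag).
#'
#' @param eeg an [mc_series()] with `rate > 160` Hz.
#' @param low_hz,high_hz band-pass cutoffs (Hz).
#' @param notch_hz mains frequency to suppress; `notch_halfwidth_hz` sets
#'   the stop-band half width.
#' @param order Butterworth order of both stages.
#' @return filtered `mc_series`.
#' @export
broadband_filter <- function(eeg, low_hz = 1, high_hz = 80,
                             notch_hz = 50, notch_halfwidth_hz = 2,
                             order = 2) {
  stopifnot(inherits(eeg, "mc_series"))
  if (eeg$rate <= 2 * high_hz)
    stop("sampling rate must exceed twice the upper cutoff")
  out <- zerophase_butter(eeg$data, eeg$rate, order,
                          c(low_hz, high_hz), "pass")
  out <- zerophase_butter(out, eeg$rate, order,
                          c(notch_hz - notch_halfwidth_hz,
                            notch_hz + notch_halfwidth_hz), "stop")
  mc_series(out, eeg$rate, eeg$labels, eeg$unit)
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones, keep DC and (for even n) Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited power envelope
#'
#' Zero-phase band-pass to the requested band (4th-order Butterworth),
#' then the modulus of the analytic (Hilbert) representation per channel.
#'
#' @param eeg a broadband-filtered [mc_series()].
#' @param band a [band_definition()].
#' @param order Butterworth order of the band filter.
#' @return `mc_series` of non-negative envelopes.
#' @export
band_envelope <- function(eeg, band, order = 4) {
  stopifnot(inherits(eeg, "mc_series"), inherits(band, "band_definition"))
  if (band$high_hz >= eeg$rate / 2)
    stop("band upper cutoff must be below the Nyquist frequency")
  filtered <- zerophase_butter(eeg$data, eeg$rate, order,
                               c(band$low_hz, band$high_hz), "pass")
  env <- filtered
  for (i in seq_len(nrow(env)))
    env[i, ] <- Mod(analytic_signal(filtered[i, ]))
  mc_series(env, eeg$rate, eeg$labels, paste0(eeg$unit, " envelope"))
}

#' Global field power
#'
#' At each sample, the root-mean-square deviation of the channel values
#' from their instantaneous across-channel mean (population standard
#' deviation across channels): a one-dimensional whole-head summary.
#'
#' @param envelopes an [mc_series()] with at least two channels.
#' @return list with `values` (numeric vector, >= 0), `rate`, and the
#'   attributes carried over (class `gfp_series`).
#' @export
global_field_power <- function(envelopes) {
  stopifnot(inherits(envelopes, "mc_series"))
  m <- envelopes$data
  if (nrow(m) < 2L) stop("GFP requires at least two channels")
  mu <- colMeans(m)
  gfp <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  structure(list(values = gfp, rate = envelopes$rate),
            class = "gfp_series")
}
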