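#' Uniformly sampled multichannel time series
#'
#' The basic carrier for EEG, optical-density and hemoglobin signals:
#' a channels-by-samples matrix with a sampling rate, channel labels and a
#' physical unit. Time of sample `k` is `(k - 1) / rate` seconds.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as a
#'   single channel).
#' @param rate sampling rate in Hz.
#' @param labels optional character vector of channel labels.
#' @param unit physical unit of the samples (informational).
#' @return An object of class `mc_series`.
#' @export
mc_series <- function(data, rate, labels = NULL, unit = "a.u.") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("labels length must equal the number of channels")
  structure(
    list(data = data, rate = rate, labels = labels, unit = unit),
    class = "mc_series"
  )
}

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("<mc_series> %d channel(s) x %d samples @ %.4g Hz (%.1f s), unit: %s\n",
              nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate, x$unit))
  invisible(x)
}

#' @export
dim.mc_series <- function(x) dim(x$data)

n_samples <- function(x) ncol(x$data)
n_channels <- function(x) nrow(x$data)

#' Sample times of a multichannel series
#' @param x an `mc_series`.
#' @return numeric vector of times in seconds, starting at 0.
#' @export
series_times <- function(x) (seq_len(ncol(x$data)) - 1) / x$rate

#' Phase markers
#'
#' Task phases are named, disjoint, ordered time intervals
#' (`[start, end)` in seconds from the start of the recording).
#'
#' @param phase character vector of phase names.
#' @param start,end numeric vectors, interval bounds in seconds.
#' @return data.frame with columns `phase`, `start`, `end`.
#' @export
phase_markers <- function(phase, start, end) {
  stopifnot(length(phase) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("phase intervals must have end > start")
  o <- order(start)
  phase <- phase[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)]))
    stop("phase intervals must be disjoint")
  data.frame(phase = phase, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Extract one task phase from a series
#'
#' Returns the samples whose time falls in `[start, end)` of the named
#' phase (half-open in time, so abutting phases do not share samples).
#'
#' @param x an `mc_series`.
#' @param markers a `phase_markers()` data.frame.
#' @param phase name of the phase to extract.
#' @return An `mc_series` restricted to the phase.
#' @export
slice_phase <- function(x, markers, phase) {
  stopifnot(inherits(x, "mc_series"))
  row <- markers[markers$phase == phase, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("phase '%s' not found (or duplicated) in markers", phase))
  t <- series_times(x)
  keep <- which(t >= row$start & t < row$end)
  if (length(keep) == 0L) stop("phase interval contains no samples")
  mc_series(x$data[, keep, drop = FALSE], x$rate, x$labels, x$unit)
}

# Trim n_sec seconds from both ends (edge-transient removal after
# zero-phase filtering / Hilbert transforms). Never trims below 2 samples.
trim_edges <- function(x, n_sec) {
  stopifnot(inherits(x, "mc_series"))
  k <- floor(n_sec * x$rate)
  n <- ncol(x$data)
  if (2L * k >= n - 2L) return(x)
  mc_series(x$data[, (k + 1L):(n - k), drop = FALSE], x$rate, x$labels, x$unit)
}
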