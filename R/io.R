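# File I/O: a minimal EDF (European Data Format) writer/reader for EEG
# and a plain-text (CSV + JSON sidecar) container for two-wavelength
# optical recordings.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

num_field <- function(x, width) pad_field(signif(x, width - 2), width)

#' Write a multichannel series to EDF
#'
#' Minimal EDF: 1-second data records, 16-bit samples, per-channel
#' physical scaling from the data range. The sampling rate must be a
#' whole number per second; trailing samples beyond the last full
#' second are zero-padded.
#'
#' @param series an [mc_series()].
#' @param path output file.
#' @param patient_id,recording_id header strings.
#' @return `path`, invisibly.
#' @export
write_edf <- function(series, path, patient_id = "X",
                      recording_id = "synthetic") {
  stopifnot(inherits(series, "mc_series"))
  rate <- series$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- nrow(series$data)
  n <- ncol(series$data)
  n_rec <- as.integer(ceiling(n / rate))
  data <- series$data
  if (n < n_rec * rate)
    data <- cbind(data, matrix(0, ns, n_rec * rate - n))
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L + 256L * ns
  wr(pad_field("0", 8))
  wr(pad_field(patient_id, 80))
  wr(pad_field(recording_id, 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(header_bytes, 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field(1, 8))
  wr(pad_field(ns, 4))
  for (f in list(function(i) pad_field(series$labels[i], 16),
                 function(i) pad_field("", 80),
                 function(i) pad_field(series$unit, 8),
                 function(i) num_field(pmin_[i], 8),
                 function(i) num_field(pmax_[i], 8),
                 function(i) pad_field(dmin, 8),
                 function(i) pad_field(dmax, 8),
                 function(i) pad_field("", 80),
                 function(i) pad_field(rate, 8),
                 function(i) pad_field("", 32)))
    for (i in seq_len(ns)) wr(f(i))
  # re-read the printed physical bounds so scaling is exactly invertible
  pmin_r <- as.numeric(vapply(seq_len(ns),
                              function(i) num_field(pmin_[i], 8), ""))
  pmax_r <- as.numeric(vapply(seq_len(ns),
                              function(i) num_field(pmax_[i], 8), ""))
  scale <- (pmax_r - pmin_r) / (dmax - dmin)
  for (rec in seq_len(n_rec)) {
    cols <- ((rec - 1L) * rate + 1L):(rec * rate)
    for (i in seq_len(ns)) {
      dig <- round((data[i, cols] - pmin_r[i]) / scale[i]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads EDF files with a uniform per-record duration of 1 s (as
#' written by [write_edf()]).
#'
#' @param path EDF file.
#' @return an [mc_series()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) readChar(con, nchars, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  unit <- trimws(rd(8)); if (ns > 1) for (i in seq_len(ns - 1)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("reader supports a single common sampling rate only")
  rate <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little")
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) /
        (dmax[i] - dmin[i])
      out[i, ((rec - 1L) * spr[i] + 1L):(rec * spr[i])] <- phys
    }
  }
  mc_series(out, rate, labels, unit)
}

#' Write an optical recording as CSV + JSON sidecar
#'
#' Intensities go to `<prefix>.csv` (one row per sample, one column per
#' channel x wavelength, named `ch<c>_wl<w>`); rate, wavelengths and
#' channel geometry go to `<prefix>.json`.
#'
#' @param optical an [optical_recording()].
#' @param prefix output path prefix (without extension).
#' @return the two paths, invisibly.
#' @export
write_optical <- function(optical, prefix) {
  stopifnot(inherits(optical, "optical_recording"))
  d <- dim(optical$intensities)
  cols <- list()
  for (ch in seq_len(d[1])) for (wl in seq_len(d[2]))
    cols[[sprintf("ch%d_wl%d", ch, wl)]] <- optical$intensities[ch, wl, ]
  df <- as.data.frame(cols)
  csv <- paste0(prefix, ".csv")
  jsn <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(rate = optical$rate, wavelengths = optical$wavelengths,
               geometry = optical$geometry, n_samples = d[3])
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, jsn))
}

#' Read an optical recording written by [write_optical()]
#'
#' @param prefix path prefix used at write time.
#' @return an [optical_recording()].
#' @export
read_optical <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  geometry <- as.data.frame(meta$geometry)
  nch <- nrow(geometry)
  nwl <- length(meta$wavelengths)
  I <- array(0, c(nch, nwl, nrow(df)))
  for (ch in seq_len(nch)) for (wl in seq_len(nwl))
    I[ch, wl, ] <- df[[sprintf("ch%d_wl%d", ch, wl)]]
  optical_recording(I, meta$rate, meta$wavelengths, geometry)
}
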