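#' Two-wavelength optical recording
#'
#' Continuous-wave intensities per channel and wavelength, with channel
#' geometry. Long separation channels (35 mm source-detector distance)
#' sense scalp plus cortex; short channels (15 mm) sense scalp only and
#' serve as nuisance regressors.
#'
#' @param intensities numeric array, channels x wavelengths x samples,
#'   strictly positive (a logarithm is taken downstream).
#' @param rate sampling rate in Hz.
#' @param wavelengths wavelengths in nm (default 690, 830).
#' @param geometry data.frame with columns `channel`, `distance_mm`,
#'   `role` (`"long"` or `"short"`).
#' @return object of class `optical_recording`.
#' @export
optical_recording <- function(intensities, rate,
                              wavelengths = c(690, 830),
                              geometry) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (dim(intensities)[2] != length(wavelengths))
    stop("second array dimension must match the number of wavelengths")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and strictly positive")
  stopifnot(all(c("channel", "distance_mm", "role") %in% names(geometry)),
            nrow(geometry) == dim(intensities)[1],
            all(geometry$role %in% c("long", "short")))
  structure(list(intensities = intensities, rate = rate,
                 wavelengths = wavelengths, geometry = geometry),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<optical_recording> %d channels (%d long, %d short) x %d wavelengths x %d samples @ %.4g Hz\n",
              d[1], sum(x$geometry$role == "long"),
              sum(x$geometry$role == "short"), d[2], d[3], x$rate))
  invisible(x)
}

#' Default optical channel geometry
#'
#' @param n_long,n_short numbers of long (35 mm) and short (15 mm)
#'   separation channels.
#' @return geometry data.frame for [optical_recording()].
#' @export
default_geometry <- function(n_long = 16, n_short = 4) {
  data.frame(
    channel = seq_len(n_long + n_short),
    distance_mm = c(rep(35, n_long), rep(15, n_short)),
    role = c(rep("long", n_long), rep("short", n_short)),
    stringsAsFactors = FALSE
  )
}

#' Optical density series
#'
#' @param od array channels x wavelengths x samples (dimensionless).
#' @param rate Hz.
#' @param wavelengths nm.
#' @param geometry as in [optical_recording()].
#' @return object of class `od_series`.
#' @export
od_series <- function(od, rate, wavelengths, geometry) {
  stopifnot(is.array(od), length(dim(od)) == 3L, all(is.finite(od)))
  structure(list(od = od, rate = rate, wavelengths = wavelengths,
                 geometry = geometry),
            class = "od_series")
}

#' Convert intensities to optical densities
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength. The ratio
#' makes the result invariant to any static per-channel gain.
#'
#' @param optical an [optical_recording()].
#' @return an [od_series()].
#' @export
intensity_to_od <- function(optical) {
  stopifnot(inherits(optical, "optical_recording"))
  I <- optical$intensities
  od <- I
  for (ch in seq_len(dim(I)[1])) {
    for (wl in seq_len(dim(I)[2])) {
      tr <- I[ch, wl, ]
      od[ch, wl, ] <- -log(tr / mean(tr))
    }
  }
  od_series(od, optical$rate, optical$wavelengths, optical$geometry)
}

#' Band-pass filter optical densities
#'
#' Zero-phase 4th-order Butterworth band-pass, default 0.01-0.4 Hz:
#' removes drift and attenuates cardiac pulsation while keeping the
#' functional hemodynamic band. The band-pass is realized as cascaded
#' high-pass and low-pass sections: with a 0.01 Hz edge at a ~10 Hz
#' rate the pole radii approach 1 and a single direct-form band-pass
#' recursion loses accuracy, while the cascade stays well-conditioned
#' (the widely separated edges make the responses equivalent).
#'
#' @param od an [od_series()].
#' @param low_hz,high_hz cutoffs in Hz.
#' @param order Butterworth order of each section.
#' @return filtered [od_series()].
#' @export
od_bandpass <- function(od, low_hz = 0.01, high_hz = 0.4, order = 4) {
  stopifnot(inherits(od, "od_series"))
  if (od$rate <= 2 * high_hz)
    stop("sampling rate too low for the requested band")
  dur <- dim(od$od)[3] / od$rate
  if (dur < 3 / (2 * pi * low_hz))
    stop("record shorter than three time constants of the high-pass stage")
  nyq <- od$rate / 2
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  out <- od$od
  for (ch in seq_len(dim(out)[1])) {
    for (wl in seq_len(dim(out)[2])) {
      tr <- od$od[ch, wl, ]
      tr <- tr - mean(tr)  # exact DC removal; in the stop-band anyway
      out[ch, wl, ] <- filtfilt_zp(lp, filtfilt_zp(hp, tr))
    }
  }
  od_series(out, od$rate, od$wavelengths, od$geometry)
}

#' Chromophore constants for the modified Beer-Lambert law
#'
#' Bundles the hemoglobin extinction coefficients and the coefficients of
#' the general age/wavelength differential-pathlength-factor (DPF)
#' equation. Extinction values ship as a plain-text table (base-10 molar
#' extinction, M^-1 cm^-1) and are converted here to natural-log basis
#' uM^-1 mm^-1, matching optical densities defined through `-ln`.
#'
#' @param wavelengths the two wavelengths (nm) used.
#' @param extinction_file optional path to an alternative extinction
#'   table (same columns as the shipped one).
#' @param dpf_coefficients named numeric vector `(alpha, beta, gamma,
#'   delta, epsilon, zeta)` of the DPF equation
#'   `DPF = alpha + beta*age^gamma + delta*lambda^3 + epsilon*lambda^2 +
#'   zeta*lambda`.
#' @return object of class `chromophore_constants`.
#' @export
chromophore_constants <- function(wavelengths = c(690, 830),
                                  extinction_file = NULL,
                                  dpf_coefficients = c(
                                    alpha = 223.3, beta = 0.05624,
                                    gamma = 0.8493, delta = -5.723e-7,
                                    epsilon = 0.001245, zeta = -0.9025)) {
  if (is.null(extinction_file))
    extinction_file <- system.file("extdata", "extinction_coefficients.csv",
                                   package = "nvcomplexity")
  tab <- utils::read.csv(extinction_file, comment.char = "#")
  eps <- matrix(NA_real_, 2L, 2L,
                dimnames = list(paste0("wl", wavelengths), c("o2hb", "hhb")))
  for (i in 1:2) for (chrom in c("o2hb", "hhb")) {
    row <- tab[tab$wavelength_nm == wavelengths[i] & tab$chromophore == chrom, ]
    if (nrow(row) != 1L)
      stop(sprintf("no extinction value for %g nm / %s", wavelengths[i], chrom))
    # base-10 M^-1 cm^-1  ->  ln-basis uM^-1 mm^-1
    eps[i, chrom] <- row$epsilon_molar_log10 * log(10) / 1e6 / 10
  }
  if (abs(det(eps)) < 1e-16) stop("extinction matrix is singular")
  structure(list(wavelengths = wavelengths, epsilon = eps,
                 dpf_coefficients = dpf_coefficients),
            class = "chromophore_constants")
}

#' Differential pathlength factor
#'
#' General age/wavelength DPF equation; corrects the geometric
#' source-detector distance for the scattering-lengthened photon path.
#'
#' @param constants a [chromophore_constants()].
#' @param wavelength_nm wavelength in nm.
#' @param age subject age in years.
#' @return dimensionless DPF (> 0).
#' @export
dpf <- function(constants, wavelength_nm, age) {
  k <- constants$dpf_coefficients
  val <- k[["alpha"]] + k[["beta"]] * age^k[["gamma"]] +
    k[["delta"]] * wavelength_nm^3 + k[["epsilon"]] * wavelength_nm^2 +
    k[["zeta"]] * wavelength_nm
  if (val <= 0) stop("DPF evaluated non-positive; check coefficients")
  val
}

# The 2x2 system matrix of the modified Beer-Lambert law:
# M[i, j] = epsilon_j(lambda_i) * DPF(lambda_i, age).
mbll_matrix <- function(constants, age) {
  d1 <- dpf(constants, constants$wavelengths[1], age)
  d2 <- dpf(constants, constants$wavelengths[2], age)
  constants$epsilon * c(d1, d2)
}

#' Hemoglobin concentration series
#'
#' @param o2hb,hhb numeric matrices channels x samples, in uM.
#' @param rate Hz.
#' @param geometry as in [optical_recording()] (may be `NULL` after
#'   averaging).
#' @return object of class `hb_series`.
#' @export
hb_series <- function(o2hb, hhb, rate, geometry = NULL) {
  if (is.vector(o2hb)) o2hb <- matrix(o2hb, nrow = 1L)
  if (is.vector(hhb)) hhb <- matrix(hhb, nrow = 1L)
  stopifnot(all(dim(o2hb) == dim(hhb)), all(is.finite(o2hb)),
            all(is.finite(hhb)))
  structure(list(o2hb = o2hb, hhb = hhb, rate = rate, geometry = geometry),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %d channel(s) x %d samples @ %.4g Hz (uM)\n",
              nrow(x$o2hb), ncol(x$o2hb), x$rate))
  invisible(x)
}

#' Modified Beer-Lambert law
#'
#' Converts optical-density changes at two wavelengths into oxy- and
#' deoxy-hemoglobin concentration changes per channel:
#' `(dO2Hb, dHHb)' = (1/d) * M^-1 * (dOD(l1), dOD(l2))'` with
#' `M[i][j] = eps_j(l_i) * DPF(l_i, age)` and `d` the geometric
#' interoptode distance in mm. Concentrations come out in uM; their
#' absolute baseline is arbitrary (only oscillations are meaningful).
#'
#' @param od an [od_series()] with two wavelengths.
#' @param constants a [chromophore_constants()].
#' @param age subject age in years (the DPF depends on it).
#' @return an [hb_series()] with one row per channel.
#' @export
mbll <- function(od, constants, age) {
  stopifnot(inherits(od, "od_series"),
            inherits(constants, "chromophore_constants"))
  if (length(od$wavelengths) != 2L)
    stop("mbll requires exactly two wavelengths")
  M <- mbll_matrix(constants, age)
  if (abs(det(M)) < 1e-20) stop("singular Beer-Lambert system matrix")
  Minv <- solve(M)
  nch <- dim(od$od)[1]
  ns <- dim(od$od)[3]
  o2hb <- matrix(0, nch, ns)
  hhb <- matrix(0, nch, ns)
  for (ch in seq_len(nch)) {
    dd <- od$geometry$distance_mm[ch]
    conc <- (Minv %*% rbind(od$od[ch, 1, ], od$od[ch, 2, ])) / dd
    o2hb[ch, ] <- conc[1, ]
    hhb[ch, ] <- conc[2, ]
  }
  hb_series(o2hb, hhb, od$rate, od$geometry)
}

# Forward counterpart of mbll(): concentrations (uM) -> OD changes.
# Used by the synthetic generator; mbll() inverts it exactly.
hb_to_od <- function(o2hb, hhb, rate, geometry, constants, age) {
  M <- mbll_matrix(constants, age)
  nch <- nrow(o2hb)
  od <- array(0, c(nch, 2L, ncol(o2hb)))
  for (ch in seq_len(nch)) {
    dd <- geometry$distance_mm[ch]
    od[ch, , ] <- dd * (M %*% rbind(o2hb[ch, ], hhb[ch, ]))
  }
  od_series(od, rate, constants$wavelengths, geometry)
}

# Split an hb_series by channel role.
split_by_role <- function(hb) {
  if (is.null(hb$geometry)) stop("hb_series carries no geometry")
  long_idx <- which(hb$geometry$role == "long")
  short_idx <- which(hb$geometry$role == "short")
  list(
    long = hb_series(hb$o2hb[long_idx, , drop = FALSE],
                     hb$hhb[long_idx, , drop = FALSE], hb$rate,
                     hb$geometry[long_idx, , drop = FALSE]),
    short = hb_series(hb$o2hb[short_idx, , drop = FALSE],
                      hb$hhb[short_idx, , drop = FALSE], hb$rate,
                      hb$geometry[short_idx, , drop = FALSE])
  )
}

#' Short-channel scalp regression
#'
#' The first principal component of the short-channel traces defines a
#' global scalp-hemodynamic model; each long channel's least-squares
#' loading on that component is estimated and the fitted scalp
#' contribution subtracted. Applied independently per chromophore.
#'
#' @param hb_long,hb_short [hb_series()] objects of equal length; at
#'   least one short channel is required.
#' @return the corrected long-channel [hb_series()]; the scalp component
#'   used is attached as attribute `"scalp_pc"` (list with `o2hb`,
#'   `hhb` time courses).
#' @export
short_channel_regress <- function(hb_long, hb_short) {
  stopifnot(inherits(hb_long, "hb_series"), inherits(hb_short, "hb_series"))
  if (nrow(hb_short$o2hb) < 1L) stop("at least one short channel required")
  if (ncol(hb_long$o2hb) != ncol(hb_short$o2hb))
    stop("long and short series must have equal length")
  regress_one <- function(long_m, short_m) {
    S <- t(short_m)                       # time x channels
    if (all(apply(S, 2L, stats::sd) < 1e-300))
      stop("short channels have zero variance")
    pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)$x[, 1L]
    pc_c <- pc - mean(pc)
    denom <- sum(pc_c^2)
    out <- long_m
    for (ch in seq_len(nrow(long_m))) {
      y <- long_m[ch, ]
      beta <- sum((y - mean(y)) * pc_c) / denom
      out[ch, ] <- y - beta * pc_c
    }
    list(corrected = out, pc = pc_c)
  }
  a <- regress_one(hb_long$o2hb, hb_short$o2hb)
  b <- regress_one(hb_long$hhb, hb_short$hhb)
  res <- hb_series(a$corrected, b$corrected, hb_long$rate, hb_long$geometry)
  attr(res, "scalp_pc") <- list(o2hb = a$pc, hhb = b$pc)
  res
}

#' Average long-separation channels
#'
#' Unweighted mean across long channels per chromophore, yielding one
#' O2Hb and one HHb trace.
#'
#' @param hb an [hb_series()] (if geometry is present, only `"long"`
#'   channels are averaged; otherwise all rows).
#' @return single-channel [hb_series()].
#' @export
average_long_channels <- function(hb) {
  stopifnot(inherits(hb, "hb_series"))
  idx <- if (is.null(hb$geometry)) seq_len(nrow(hb$o2hb))
         else which(hb$geometry$role == "long")
  if (length(idx) < 1L) stop("no long channels to average")
  hb_series(colMeans(hb$o2hb[idx, , drop = FALSE]),
            colMeans(hb$hhb[idx, , drop = FALSE]), hb$rate, NULL)
}

#' Full fNIRS preprocessing chain
#'
#' Intensities -> optical densities -> wavelet despiking -> 0.01-0.4 Hz
#' band-pass -> modified Beer-Lambert law -> short-channel scalp
#' regression -> long-channel average.
#'
#' @param optical an [optical_recording()].
#' @param age subject age in years.
#' @param constants a [chromophore_constants()].
#' @param despike logical, run the wavelet despiking stage.
#' @param alpha despiking tail probability (see [wavelet_despike()]).
#' @param low_hz,high_hz OD band-pass cutoffs.
#' @return list with `hb_long` (corrected long channels), `hb_mean`
#'   (averaged single-channel [hb_series()]) and `scalp_pc`.
#' @export
fnirs_preprocess <- function(optical, age,
                             constants = chromophore_constants(),
                             despike = TRUE, alpha = 0.1,
                             low_hz = 0.01, high_hz = 0.4) {
  od <- intensity_to_od(optical)
  if (despike) od <- wavelet_despike(od, alpha = alpha)
  od <- od_bandpass(od, low_hz = low_hz, high_hz = high_hz)
  hb <- mbll(od, constants, age)
  parts <- split_by_role(hb)
  if (nrow(parts$short$o2hb) >= 1L) {
    corrected <- short_channel_regress(parts$long, parts$short)
  } else {
    corrected <- parts$long
  }
  list(hb_long = corrected,
       hb_mean = average_long_channels(corrected),
       scalp_pc = attr(corrected, "scalp_pc"))
}
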