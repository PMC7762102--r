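#' Configuration of the synthetic multimodal cohort
#'
#' The generator emulates the statistical structure the analysis
#' assumes: band-limited EEG oscillations shared across channels, a
#' latent neural drive whose HRF convolution feeds the long-channel
#' hemodynamics with a group-dependent coupling gain, a global scalp
#' component shared by short and long optical channels, and a
#' two-wavelength photon-attenuation forward model that is the exact
#' inverse of the preprocessing chain.
#'
#' @param n_ad,n_hc group sizes (AD patients / healthy controls).
#' @param eeg_rate,fnirs_rate sampling rates in Hz.
#' @param n_eeg_channels EEG montage size.
#' @param n_long_channels,n_short_channels optical channel counts
#'   (35 mm / 15 mm source-detector separation).
#' @param phase_durations named numeric vector, seconds per task phase.
#' @param band_powers named per-band source amplitudes (uV).
#' @param comodulation depth of the slow (0.02-0.2 Hz) amplitude
#'   modulation shared by all band sources: task engagement modulates
#'   broadband power coherently, and this shared modulation is what the
#'   hemodynamic drive tracks. 0 disables it.
#' @param eeg_noise_sd broadband 1/f EEG noise amplitude (uV).
#' @param channel_noise_frac per-channel narrowband noise relative to
#'   the shared band source.
#' @param coupling_gain_ad,coupling_gain_hc dimensionless
#'   neurovascular-coupling gains (AD impaired by default).
#' @param hemo_amplitude peak-scale of the coupled O2Hb oscillation at
#'   unit gain (uM).
#' @param hhb_ratio `dHHb = -hhb_ratio * dO2Hb` for the neural part
#'   (functional hyperemia polarity).
#' @param scalp_amplitudes named amplitudes (uM) of the Mayer (~0.1 Hz),
#'   respiratory (~0.3 Hz) and cardiac (~1 Hz) scalp oscillations.
#' @param vasomotion_amplitude amplitude (uM) of cortical vasomotion
#'   (narrowband ~0.05-0.15 Hz; half-global, half-local per long
#'   channel); the stationary in-band variability real cortical
#'   hemodynamics always carry on top of the task-coupled response.
#' @param vasomotion_band frequency band (Hz) of the vasomotion.
#' @param noise_sd hemodynamic measurement noise (uM).
#' @param spike_rate motion spikes per minute added to the optical
#'   densities.
#' @param seed integer master seed; the same configuration generates a
#'   bit-identical cohort.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_ad = 17, n_hc = 18,
    eeg_rate = 250, fnirs_rate = 10.42,
    n_eeg_channels = 16,
    n_long_channels = 16, n_short_channels = 4,
    phase_durations = c(ROCF_copying = 240, RPM = 240, ROCF_recall = 240),
    band_powers = c(delta = 8, theta = 6, alpha = 10, beta = 4, gamma = 2),
    comodulation = 0.5,
    eeg_noise_sd = 3,
    channel_noise_frac = 0.3,
    coupling_gain_ad = 0.3, coupling_gain_hc = 1.0,
    hemo_amplitude = 0.4,
    hhb_ratio = 0.3,
    scalp_amplitudes = c(mayer = 0.25, respiratory = 0.12, cardiac = 0.2),
    vasomotion_amplitude = 0.5,
    vasomotion_band = c(0.05, 0.15),
    noise_sd = 0.05,
    spike_rate = 0,
    seed = 1L) {
  stopifnot(n_ad >= 1, n_hc >= 1, eeg_rate > 0, fnirs_rate > 0,
            n_eeg_channels >= 2, n_long_channels >= 1,
            n_short_channels >= 0, all(phase_durations > 0),
            coupling_gain_ad >= 0, coupling_gain_hc >= 0,
            noise_sd >= 0, spike_rate >= 0)
  if (is.null(names(phase_durations)))
    names(phase_durations) <- paste0("phase", seq_along(phase_durations))
  structure(as.list(environment()), class = "synthetic_config")
}

# White complex spectrum: shaping it and taking the real part of one
# inverse FFT yields a real Gaussian process with the window's power
# spectrum (cheaper than transforming time-domain white noise first).
white_spectrum <- function(n) {
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}

# 1/f ("pink") noise of unit SD via spectral shaping.
pink_noise <- function(n) {
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  x <- Re(stats::fft(white_spectrum(n) / sqrt(f), inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

# Band-limited Gaussian source of unit SD, synthesized spectrally
# (white spectrum windowed to the band with raised-cosine edges).
narrowband_noise <- function(n, rate, low_hz, high_hz) {
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)                 # two-sided frequency axis
  roll <- 0.15 * (high_hz - low_hz)
  w <- numeric(n)
  inside <- f >= low_hz & f <= high_hz
  w[inside] <- 1
  lo_edge <- f >= low_hz - roll & f < low_hz
  w[lo_edge] <- 0.5 * (1 + cos(pi * (low_hz - f[lo_edge]) / roll))
  hi_edge <- f > high_hz & f <= high_hz + roll
  w[hi_edge] <- 0.5 * (1 + cos(pi * (f[hi_edge] - high_hz) / roll))
  x <- Re(stats::fft(white_spectrum(n) * w, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

# Truncated normal by rejection (small n, fine for ages).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate one synthetic subject recording
#'
#' EEG channels are sums over the five bands of amplitude-shared
#' narrowband sources (with per-channel gains and per-channel narrowband
#' noise) plus broadband 1/f noise. The latent neural drive -- the
#' low-passed Hilbert envelope of the summed band sources -- is
#' convolved with the canonical HRF, scaled by the group's coupling
#' gain, and injected as dO2Hb (positive) and dHHb (negative, ratio
#' `hhb_ratio`) into long optical channels only. A global scalp
#' component (Mayer, respiratory, cardiac oscillations) enters short
#' and long channels with per-channel gains. Hemoglobin time courses
#' map to two-wavelength intensities through the exact forward
#' Beer-Lambert model inverted by [fnirs_preprocess()].
#'
#' @param config a [synthetic_config()].
#' @param group `1` (AD) or `0` (HC).
#' @param subject_seed integer seed; identical arguments give an
#'   identical recording.
#' @param subject_id identifier string.
#' @param constants a [chromophore_constants()].
#' @return `subject_recording`: list with `subject_id`, `group`, `age`,
#'   `eeg` ([mc_series()], uV), `optical` ([optical_recording()]),
#'   `phase_markers`, and `truth` (the injected coupled hemoglobin and
#'   scalp component, for validation).
#' @export
generate_subject <- function(config, group, subject_seed,
                             subject_id = sprintf("S%04d", subject_seed),
                             constants = chromophore_constants()) {
  stopifnot(inherits(config, "synthetic_config"), group %in% c(0, 1))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(subject_seed %% 2147483647))

  age_mean <- if (group == 1) 67.6 else 69.2
  age_sd <- if (group == 1) 9.3 else 9.1
  age <- rtruncnorm(1, age_mean, age_sd, 50, 90)

  durs <- config$phase_durations
  starts <- cumsum(c(0, utils::head(durs, -1)))
  markers <- phase_markers(names(durs), starts, starts + durs)
  total_s <- sum(durs)
  ne <- round(total_s * config$eeg_rate)
  nf <- floor(total_s * config$fnirs_rate)

  # --- EEG ----------------------------------------------------------
  bands <- eeg_band_table()
  amps <- config$band_powers[bands$name]
  shared <- matrix(0, nrow(bands), ne)
  comod <- if (config$comodulation > 0) {
    pmax(1 + config$comodulation *
           narrowband_noise(ne, config$eeg_rate, 0.02, 0.2), 0.05)
  } else rep(1, ne)
  for (b in seq_len(nrow(bands)))
    shared[b, ] <- comod * narrowband_noise(ne, config$eeg_rate,
                                            bands$low_hz[b], bands$high_hz[b])
  nch <- config$n_eeg_channels
  gains <- matrix(stats::runif(nch * nrow(bands), 0.5, 1.5),
                  nch, nrow(bands))
  eeg <- matrix(0, nch, ne)
  for (ch in seq_len(nch)) {
    acc <- numeric(ne)
    for (b in seq_len(nrow(bands))) {
      own <- narrowband_noise(ne, config$eeg_rate,
                              bands$low_hz[b], bands$high_hz[b])
      acc <- acc + amps[b] * (gains[ch, b] * shared[b, ] +
                                config$channel_noise_frac * own)
    }
    eeg[ch, ] <- acc + config$eeg_noise_sd * pink_noise(ne)
  }
  eeg_series <- mc_series(eeg, config$eeg_rate,
                          sprintf("EEG%03d", seq_len(nch)), "uV")

  # --- latent neural drive -> coupled hemodynamics ------------------
  summed <- drop(amps %*% shared)
  envelope <- Mod(analytic_signal(summed))
  nyq <- config$eeg_rate / 2
  lp <- signal::butter(4, 0.5 / nyq, type = "low")
  drive <- filtfilt_zp(lp, envelope)
  hrf_k <- canonical_hrf(hrf_params(), rate = config$eeg_rate)
  coupled <- stats::convolve(drive, rev(as.numeric(hrf_k)),
                             type = "open")[seq_len(ne)]
  coupled <- (coupled - mean(coupled)) / stats::sd(coupled)
  gain <- if (group == 1) config$coupling_gain_ad else config$coupling_gain_hc
  t_eeg <- (seq_len(ne) - 1) / config$eeg_rate
  t_f <- (seq_len(nf) - 1) / config$fnirs_rate
  coupled_f <- stats::approx(t_eeg, coupled, xout = t_f, rule = 2)$y
  o2hb_neural <- gain * config$hemo_amplitude * coupled_f

  # --- scalp component ---------------------------------------------
  scalp_freqs <- c(mayer = 0.1, respiratory = 0.3, cardiac = 1.0)
  scalp <- numeric(nf)
  for (k in names(scalp_freqs)) {
    f <- scalp_freqs[[k]] * stats::runif(1, 0.9, 1.1)
    scalp <- scalp + config$scalp_amplitudes[[k]] *
      sin(2 * pi * f * t_f + stats::runif(1, 0, 2 * pi))
  }

  # --- per-channel hemoglobin --------------------------------------
  geometry <- default_geometry(config$n_long_channels,
                               config$n_short_channels)
  ntot <- nrow(geometry)
  vaso_shared <- if (config$vasomotion_amplitude > 0)
    narrowband_noise(nf, config$fnirs_rate, config$vasomotion_band[1],
                     config$vasomotion_band[2])
  else numeric(nf)
  o2hb <- matrix(0, ntot, nf)
  hhb <- matrix(0, ntot, nf)
  scalp_gain <- stats::runif(ntot, 0.5, 1.5)
  for (ch in seq_len(ntot)) {
    sc <- scalp_gain[ch] * scalp
    if (geometry$role[ch] == "long") {
      w <- stats::runif(1, 0.8, 1.2)
      vaso <- if (config$vasomotion_amplitude > 0)
        config$vasomotion_amplitude * sqrt(0.5) *
          (vaso_shared + narrowband_noise(nf, config$fnirs_rate,
                                          config$vasomotion_band[1],
                                          config$vasomotion_band[2]))
      else 0
      o2hb[ch, ] <- w * o2hb_neural + sc + vaso
      hhb[ch, ] <- -config$hhb_ratio * (w * o2hb_neural + vaso) +
        config$hhb_ratio * sc
    } else {
      o2hb[ch, ] <- sc
      hhb[ch, ] <- config$hhb_ratio * sc
    }
    if (config$noise_sd > 0) {
      o2hb[ch, ] <- o2hb[ch, ] + stats::rnorm(nf, 0, config$noise_sd)
      hhb[ch, ] <- hhb[ch, ] + stats::rnorm(nf, 0, config$noise_sd)
    }
    o2hb[ch, ] <- o2hb[ch, ] - mean(o2hb[ch, ])
    hhb[ch, ] <- hhb[ch, ] - mean(hhb[ch, ])
  }

  # --- forward Beer-Lambert: concentrations -> intensities ----------
  od <- hb_to_od(o2hb, hhb, config$fnirs_rate, geometry, constants, age)
  if (config$spike_rate > 0) {
    n_spikes <- stats::rpois(ntot, config$spike_rate * total_s / 60)
    for (ch in seq_len(ntot)) {
      if (n_spikes[ch] == 0) next
      pos <- sample.int(nf, n_spikes[ch])
      amp <- stats::runif(n_spikes[ch], 5, 10) *
        max(stats::sd(od$od[ch, 1, ]), 1e-4) *
        sample(c(-1, 1), n_spikes[ch], replace = TRUE)
      for (wl in 1:2) od$od[ch, wl, pos] <- od$od[ch, wl, pos] + amp
    }
  }
  baseline <- matrix(1e6 * stats::runif(ntot * 2, 0.5, 2), ntot, 2)
  I <- array(0, dim(od$od))
  for (ch in seq_len(ntot)) for (wl in 1:2)
    I[ch, wl, ] <- baseline[ch, wl] * exp(-od$od[ch, wl, ])
  if (any(!is.finite(I)) || any(I <= 0))
    stop("non-positive generated intensity: amplitudes too large")
  optical <- optical_recording(I, config$fnirs_rate,
                               constants$wavelengths, geometry)

  structure(list(subject_id = subject_id, group = group, age = age,
                 eeg = eeg_series, optical = optical,
                 phase_markers = markers,
                 truth = list(o2hb = o2hb, hhb = hhb, scalp = scalp,
                              scalp_gain = scalp_gain,
                              coupled = o2hb_neural, drive = drive,
                              coupling_gain = gain)),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> %s (group %d, age %.1f)\n",
              x$subject_id, x$group, x$age))
  print(x$eeg); print(x$optical)
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' `n_ad + n_hc` subjects with per-subject seeds derived
#' deterministically from `config$seed`; ages follow the study-group
#' moments (AD 67.6 +/- 9.3, HC 69.2 +/- 9.1 years, truncated to
#' 50-90).
#'
#' @param config a [synthetic_config()].
#' @param constants a [chromophore_constants()].
#' @return list of `subject_recording`s, AD subjects first.
#' @export
generate_cohort <- function(config, constants = chromophore_constants()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_ad + config$n_hc
  groups <- rep(c(1, 0), c(config$n_ad, config$n_hc))
  ids <- c(sprintf("AD%02d", seq_len(config$n_ad)),
           sprintf("HC%02d", seq_len(config$n_hc)))
  seeds <- (as.numeric(config$seed) + 7919 * seq_len(n)) %% 2147483647
  lapply(seq_len(n), function(i)
    generate_subject(config, groups[i], seeds[i], ids[i], constants))
}
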