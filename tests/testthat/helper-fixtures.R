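# Small synthetic fixtures shared across test files. Generation is
# cheap; helpers memoize nothing so each test stays independent.

tiny_config <- function(...) {
  synthetic_config(n_ad = 1, n_hc = 1,
                   phase_durations = c(ROCF_copying = 60, RPM = 60,
                                       ROCF_recall = 60),
                   n_eeg_channels = 3, n_long_channels = 3,
                   n_short_channels = 2, seed = 7, ...)
}

# The scaled-down single-phase design used for end-to-end checks:
# study-sized groups, 240 s epochs (matching the analyzed epoch
# length), reduced channel counts for tractability.
e2e_config <- function(seed, ...) {
  synthetic_config(n_ad = 17, n_hc = 18,
                   phase_durations = c(task = 240),
                   n_eeg_channels = 2, n_long_channels = 3,
                   n_short_channels = 2, seed = seed, ...)
}

e2e_feature_config <- function() feature_config(envelope_rate_hz = 12.5)

# A deterministic multichannel sinusoid series.
sine_series <- function(freqs, rate = 250, dur = 10, amp = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  mc_series(t(sapply(freqs, function(f) amp * sin(2 * pi * f * t))), rate)
}
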