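test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_subject(cfg, 1, 555)
  b <- generate_subject(cfg, 1, 555)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$optical$intensities, b$optical$intensities)
  expect_identical(a$age, b$age)
  # different seed, different data
  c_ <- generate_subject(cfg, 1, 556)
  expect_false(identical(a$eeg$data, c_$eeg$data))
})

test_that("cohorts have the configured sizes, labels and ages", {
  cfg <- tiny_config()
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2L)
  expect_identical(vapply(cohort, `[[`, 0, "group"), c(1, 0))

  cfg35 <- synthetic_config()
  expect_identical(cfg35$n_ad + cfg35$n_hc, 35)
  expect_identical(cfg35$n_ad, 17)
  expect_identical(cfg35$n_hc, 18)
  expect_identical(cfg35$eeg_rate, 250)
  expect_identical(cfg35$fnirs_rate, 10.42)
  expect_identical(cfg35$n_long_channels, 16)
  expect_identical(cfg35$n_short_channels, 4)

  ages <- vapply(cohort, `[[`, 0, "age")
  expect_true(all(ages >= 50 & ages <= 90))

  # study-sized cohort: 35 subjects, 17 AD then 18 HC (miniature
  # recordings keep this cheap; cardinality is what matters)
  cfg_study <- synthetic_config(phase_durations = c(t = 8),
                                n_eeg_channels = 2, n_long_channels = 2,
                                n_short_channels = 1, seed = 2)
  study <- generate_cohort(cfg_study)
  expect_length(study, 35L)
  expect_identical(sum(vapply(study, `[[`, 0, "group") == 1), 17L)
  expect_identical(sum(vapply(study, `[[`, 0, "group") == 0), 18L)
})

test_that("phase markers are disjoint, ordered and span both modalities", {
  cfg <- tiny_config()
  s <- generate_subject(cfg, 0, 42)
  m <- s$phase_markers
  expect_identical(m$phase, c("ROCF_copying", "RPM", "ROCF_recall"))
  expect_true(all(m$end > m$start))
  expect_true(all(diff(m$start) > 0))
  expect_true(all(m$start[-1] >= m$end[-3]))
  total <- sum(cfg$phase_durations)
  expect_equal(ncol(s$eeg$data) / s$eeg$rate, total)
  expect_equal(dim(s$optical$intensities)[3] / s$optical$rate, total,
               tolerance = 1 / s$optical$rate)
})

test_that("the forward optical model is inverted exactly by preprocessing", {
  # all nuisance terms off: recovered oscillations match the injected
  # ones (baselines are arbitrary, so compare mean-centered series)
  cfg <- tiny_config(noise_sd = 0, spike_rate = 0,
                     scalp_amplitudes = c(mayer = 0, respiratory = 0,
                                          cardiac = 0),
                     vasomotion_amplitude = 0)
  s <- generate_subject(cfg, 0, 77)
  od <- intensity_to_od(s$optical)
  hb <- mbll(od, chromophore_constants(), s$age)
  center <- function(m) m - rowMeans(m)
  rel_err <- function(got, want)
    max(abs(center(got) - center(want))) / max(abs(center(want)))
  expect_lt(rel_err(hb$o2hb, s$truth$o2hb), 1e-10)
  expect_lt(rel_err(hb$hhb, s$truth$hhb), 1e-10)
})

test_that("zero coupling removes group information from the long channels", {
  cfg <- tiny_config(coupling_gain_ad = 0, coupling_gain_hc = 0,
                     noise_sd = 0, vasomotion_amplitude = 0)
  s <- generate_subject(cfg, 1, 31)
  # long-channel hemoglobin = scalp only (up to gains): correlation of
  # every long channel with the scalp waveform is +/-1
  od <- intensity_to_od(s$optical)
  hb <- mbll(od, chromophore_constants(), s$age)
  long_idx <- which(hb$geometry$role == "long")
  cors <- vapply(long_idx, function(ch)
    abs(cor(hb$o2hb[ch, ], s$truth$scalp)), 0)
  expect_true(all(cors > 0.999))
})

test_that("motion spikes appear at the configured rate and are removable", {
  cfg <- tiny_config(spike_rate = 6, noise_sd = 0)
  s <- generate_subject(cfg, 0, 91)
  od <- intensity_to_od(s$optical)
  despiked <- wavelet_despike(od)
  # despiking reduces the largest OD excursions
  expect_lt(max(abs(despiked$od)), max(abs(od$od)))
})

test_that("overdriven amplitudes are rejected rather than silently clipped", {
  cfg <- tiny_config(hemo_amplitude = 1e8)
  expect_error(generate_subject(cfg, 0, 1), "amplitudes too large|positive")
})

test_that("coupling gain difference produces a NC feature contrast", {
  # group-mean CondEn differs when gains differ (small cohort, fixed
  # seed; the full-scale effect-size check lives in the acceptance
  # suite)
  cfg <- synthetic_config(n_ad = 3, n_hc = 3,
                          phase_durations = c(task = 240),
                          n_eeg_channels = 4, n_long_channels = 4,
                          n_short_channels = 2,
                          coupling_gain_ad = 0, coupling_gain_hc = 1.5,
                          seed = 8)
  cohort <- generate_cohort(cfg)
  tab <- suppressWarnings(cohort_features(
    cohort, config = feature_config(envelope_rate_hz = 12.5)))
  nc_cols <- grep("^conden_", names(tab), value = TRUE)
  m <- as.matrix(tab[, nc_cols])
  diffs <- colMeans(m[tab$group == 1, ], na.rm = TRUE) -
    colMeans(m[tab$group == 0, ], na.rm = TRUE)
  # impaired coupling leaves more residual entropy on average
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})
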