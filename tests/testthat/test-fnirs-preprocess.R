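make_optical <- function(od_fun, n = 1024, rate = 10.42, n_long = 2,
                         n_short = 1, baseline = 1e5) {
  geom <- default_geometry(n_long, n_short)
  I <- array(0, c(nrow(geom), 2, n))
  for (ch in seq_len(nrow(geom))) for (wl in 1:2)
    I[ch, wl, ] <- baseline * exp(-od_fun(ch, wl, n))
  optical_recording(I, rate, geometry = geom)
}

test_that("optical densities follow -ln(I / mean I)", {
  geom <- default_geometry(1, 0)
  # constant intensity: OD identically zero
  I <- array(5e4, c(1, 2, 100))
  od <- intensity_to_od(optical_recording(I, 10, geometry = geom))
  expect_equal(max(abs(od$od)), 0, tolerance = 1e-12)
  # one sample at I_avg * exp(-1) gives OD 1 there (a compensating
  # sample keeps the mean exactly at 1)
  x <- rep(1, 200)
  x[77] <- exp(-1)
  x[100] <- 2 - exp(-1)
  I2 <- array(0, c(1, 2, 200))
  I2[1, 1, ] <- 3e4 * x; I2[1, 2, ] <- 3e4 * x
  od2 <- intensity_to_od(optical_recording(I2, 10, geometry = geom))
  expect_equal(od2$od[1, 1, 77], 1, tolerance = 1e-9)
  # global gain invariance
  od3 <- intensity_to_od(optical_recording(2 * I2, 10, geometry = geom))
  expect_equal(od3$od, od2$od, tolerance = 1e-12)
  I_bad <- I; I_bad[1, 1, 5] <- 0
  expect_error(optical_recording(I_bad, 10, geometry = geom), "positive")
})

test_that("OD band-pass keeps the hemodynamic band and kills drift", {
  rate <- 10.42
  n <- 2500
  t <- (seq_len(n) - 1) / rate
  mk <- function(sig) {
    geom <- default_geometry(1, 0)
    od_series(array(rep(sig, each = 2), c(1, 2, n)), rate,
              c(690, 830), geom)
  }
  mid <- 500:2000
  in_band <- od_bandpass(mk(sin(2 * pi * 0.1 * t)))
  expect_equal(max(abs(in_band$od[1, 1, mid])), 1, tolerance = 0.05)
  cardiac <- od_bandpass(mk(sin(2 * pi * 1.0 * t)))
  expect_lt(max(abs(cardiac$od[1, 1, mid])), 0.1)  # >= 20 dB
  dc <- od_bandpass(mk(rep(4, n)))
  expect_lt(abs(mean(dc$od[1, 1, ])), 4e-6)
  short <- mk(sin(2 * pi * 0.1 * t))
  short$od <- short$od[, , 1:100, drop = FALSE]
  expect_error(od_bandpass(short), "three time constants")
})

test_that("wavelet despiking is transparent to smooth signals and kills spikes", {
  t <- seq(0, 99.9, by = 0.1)
  s <- sin(2 * pi * 0.1 * t)
  expect_lt(max(abs(wavelet_despike(s) - s)), 0.01)
  s2 <- s
  s2[500] <- s2[500] + 10
  despiked <- wavelet_despike(s2)
  expect_lt(abs(despiked[500] - s[500]), 1)  # >= 90% of the spike removed
  expect_identical(max(abs(wavelet_despike(numeric(64)))), 0)
  expect_error(wavelet_despike(s, alpha = 1.5), "alpha")
  expect_error(wavelet_despike(rnorm(8)), "too short")
})

test_that("the Beer-Lambert inversion is exact against its forward model", {
  cc <- chromophore_constants()
  geom <- default_geometry(3, 0)
  set.seed(20)
  o2 <- matrix(rnorm(3 * 256, 0, 0.8), 3)
  hh <- matrix(rnorm(3 * 256, 0, 0.3), 3)
  od <- nvcomplexity:::hb_to_od(o2, hh, 10.42, geom, cc, 68)
  hb <- mbll(od, cc, 68)
  expect_lt(max(abs(hb$o2hb - o2)) / max(abs(o2)), 1e-10)
  expect_lt(max(abs(hb$hhb - hh)) / max(abs(hh)), 1e-10)
  # zero OD maps to zero concentration
  od0 <- od_series(array(0, c(1, 2, 10)), 10, c(690, 830),
                   default_geometry(1, 0))
  hb0 <- mbll(od0, cc, 68)
  expect_identical(max(abs(hb0$o2hb)), 0)
})

test_that("DPF is positive, wavelength- and age-dependent", {
  cc <- chromophore_constants()
  d690 <- dpf(cc, 690, 65)
  d830 <- dpf(cc, 830, 65)
  expect_gt(d690, d830)  # shorter wavelength, longer path
  expect_gt(dpf(cc, 690, 85), dpf(cc, 690, 55))  # DPF grows with age
  expect_gt(d830, 1)
})

test_that("short-channel regression removes the scalp component", {
  set.seed(21)
  n <- 2000
  scalp <- sin(2 * pi * 0.1 * seq_len(n) / 10) +
    0.5 * sin(2 * pi * 0.3 * seq_len(n) / 10 + 1)
  neural <- as.numeric(arima.sim(list(ar = 0.9), n))
  # orthogonalized against scalp: the sample projection onto scalp is
  # removed by any regression and would otherwise count as leakage
  sc_c <- scalp - mean(scalp)
  neural <- neural - mean(neural) - sum(neural * sc_c) / sum(sc_c^2) * sc_c
  long <- hb_series(rbind(neural + 0.8 * scalp, 0.5 * scalp),
                    rbind(-0.3 * neural + 0.2 * scalp, 0.1 * scalp),
                    10.42, default_geometry(2, 0))
  short <- hb_series(rbind(1.3 * scalp, 0.7 * scalp),
                     rbind(0.4 * scalp, 0.2 * scalp),
                     10.42, default_geometry(0, 2))
  out <- short_channel_regress(long, short)
  # residual correlation with the scalp waveform ~ 0
  expect_lt(abs(cor(out$o2hb[1, ], scalp)), 1e-6)
  # channel that was pure scalp is annihilated
  expect_lt(sd(out$o2hb[2, ]), 1e-6 * sd(scalp))
  # variance of the scalp contribution reduced >= 95%
  v_before <- stats::var(long$o2hb[1, ] - neural)
  v_after <- stats::var(out$o2hb[1, ] - neural)
  expect_lt(v_after / v_before, 0.05)
  # a long channel orthogonal to scalp passes through
  indep <- sin(2 * pi * 0.05 * seq_len(n) / 10 + 0.4)
  indep <- indep - mean(indep)
  scalp_c <- scalp - mean(scalp)
  indep <- indep - sum(indep * scalp_c) / sum(scalp_c^2) * scalp_c
  long2 <- hb_series(rbind(indep), rbind(indep), 10.42,
                     default_geometry(1, 0))
  out2 <- short_channel_regress(long2, short)
  expect_equal(out2$o2hb[1, ], indep, tolerance = 1e-8)
  zero_short <- hb_series(matrix(0, 1, n), matrix(0, 1, n), 10.42,
                          default_geometry(0, 1))
  expect_error(short_channel_regress(long, zero_short), "zero variance")
})

test_that("long-channel averaging is the unweighted mean", {
  hb <- hb_series(rbind(rep(1, 5), rep(3, 5)), rbind(rep(2, 5), rep(-2, 5)),
                  10, default_geometry(2, 0))
  avg <- average_long_channels(hb)
  expect_identical(drop(avg$o2hb), rep(2, 5))
  expect_identical(drop(avg$hhb), rep(0, 5))
  one <- hb_series(matrix(rnorm(5), 1), matrix(rnorm(5), 1), 10,
                   default_geometry(1, 0))
  expect_equal(drop(average_long_channels(one)$o2hb), drop(one$o2hb))
})

test_that("intensity scaling cancels through the whole optical chain", {
  set.seed(22)
  cfg <- tiny_config()
  s <- generate_subject(cfg, 0, 123)
  out1 <- fnirs_preprocess(s$optical, s$age, despike = FALSE)
  scaled <- s$optical
  scaled$intensities <- scaled$intensities * 7.7
  out2 <- fnirs_preprocess(scaled, s$age, despike = FALSE)
  # ODs agree to machine epsilon; the narrow high-pass amplifies
  # roundoff, so the hemoglobin agreement tolerance is looser
  expect_equal(out1$hb_mean$o2hb, out2$hb_mean$o2hb, tolerance = 1e-6)
})
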