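test_that("sample entropy matches hand-enumerated template counts", {
  # alternating series: every length-2 match extends to length 3
  expect_identical(sample_entropy(c(0, 1, 0, 1, 0, 1, 0, 1), r = 0.5), 0)
  # B = 8 ordered pairs, A = 2 => -ln(2/8) = ln 4
  expect_equal(sample_entropy(c(0, 1, 0, 0, 1, 0, 1, 1), r = 0.5),
               log(4), tolerance = 1e-12)
})

test_that("sample entropy agrees with the brute-force oracle", {
  set.seed(42)
  n_checked <- 0
  for (rep in 1:170) {
    n <- sample(30:200, 1)
    m <- sample(1:3, 1)
    tau <- sample(1:2, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expected <- sampen_oracle(x, m, r, tau)
    if (is.na(expected)) next
    got <- sample_entropy(x, entropy_params(m = m, tau = tau), r = r)
    expect_equal(got, expected, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("sample entropy is invariant under affine rescaling", {
  set.seed(1)
  x <- rnorm(150)
  base <- sample_entropy(x)
  expect_equal(sample_entropy(3.7 * x - 11), base, tolerance = 1e-12)
  expect_equal(sample_entropy(-0.2 * x + 5), base, tolerance = 1e-12)
})

test_that("sample entropy rejects degenerate inputs", {
  expect_error(sample_entropy(rep(1, 50)), "degenerate")
  expect_error(sample_entropy(c(0, 1)), "too short")
  # smooth ramp: every m-match extends, but tolerance too small for any
  # match at all
  expect_error(sample_entropy(seq_len(30), r = 1e-9), "no length-m")
})

test_that("white noise is less predictable than a sinusoid", {
  set.seed(99)
  wins <- 0
  for (i in 1:50) {
    n <- 300
    noise <- rnorm(n)
    tone <- sin(2 * pi * 5 * seq_len(n) / n + runif(1, 0, 2 * pi))
    tone <- tone / sd(tone)
    if (sample_entropy(noise) > sample_entropy(tone)) wins <- wins + 1
  }
  expect_gte(wins, 48)
})

test_that("conditional entropy reproduces analytic cases", {
  # y == x: knowing x fixes y
  set.seed(2)
  x <- rnorm(200)
  expect_equal(conditional_entropy(x, x, bins = 4), 0, tolerance = 1e-12)
  # independent 2-bin uniform: H(Y|X) = H(Y) = ln 2
  expect_equal(conditional_entropy(c(0, 0, 1, 1), c(0, 1, 0, 1), bins = 2),
               log(2), tolerance = 1e-12)
  # direct evaluation on a printed joint table
  expect_equal(conditional_entropy_table(matrix(c(2, 0, 1, 1), 2, 2)),
               0.75 * (log(3) - (2 / 3) * log(2)), tolerance = 1e-6)
})

test_that("conditional entropy is bounded and matches the chain rule", {
  set.seed(3)
  for (i in 1:300) {
    counts <- matrix(rpois(16, 3), 4, 4)
    if (sum(counts) == 0) next
    h <- conditional_entropy_table(counts)
    expect_equal(h, conden_oracle(counts), tolerance = 1e-12)
    py <- colSums(counts) / sum(counts)
    hy <- -sum(ifelse(py > 0, py * log(py), 0))
    expect_gte(h, -1e-12)
    expect_lte(h, hy + 1e-12)
  }
})

test_that("conditional entropy respects its estimator invariances", {
  set.seed(4)
  x <- rnorm(400)
  y <- rnorm(400)
  base <- conditional_entropy(x, y)
  # strictly monotone transforms leave quantile bins unchanged
  expect_equal(conditional_entropy(exp(x), y^3 + 2 * y), base,
               tolerance = 1e-12)
  # a constant predictor carries no information: H(Y|X) = H(Y)
  expect_equal(conditional_entropy(rep(1, 400), y),
               marginal_entropy(y), tolerance = 1e-12)
  expect_error(conditional_entropy(x, y[1:100]), "equal length")
  expect_warning(conditional_entropy(x[1:10], y[1:10], bins = 8), "sparse")
})

test_that("stationarity gate passes noise, detrends ramps, flags walks", {
  set.seed(5)
  pass <- mean(replicate(100, check_stationarity(rnorm(1000))$stationary))
  expect_gte(pass, 0.95)

  ramp <- 0.05 * seq_len(500) + rnorm(500, sd = 0.5)
  v <- check_stationarity(ramp)
  expect_true(v$detrended)
  expect_true(v$stationary)

  flagged <- mean(replicate(40, {
    !check_stationarity(cumsum(rnorm(1000)))$stationary
  }))
  expect_gte(flagged, 0.6)

  expect_error(check_stationarity(rep(2, 100)), "constant")
})

test_that("epochs are truncated to the shortest duration", {
  out <- truncate_common(list(rnorm(100), rnorm(80), rnorm(120)))
  expect_identical(lengths(out), c(80L, 80L, 80L))
  same <- list(1:5, 6:10)
  expect_identical(truncate_common(same), same)
  single <- list(rnorm(7))
  expect_identical(truncate_common(single), single)
  expect_error(truncate_common(list()), "non-empty")
})
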