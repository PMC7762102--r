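#' Entropy estimation parameters
#'
#' @param m embedding (pattern) dimension, >= 1.
#' @param r_factor tolerance as a multiple of the series SD (the
#'   similarity factor `r = r_factor * SD`).
#' @param tau delay between template points, in samples.
#' @return list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, tau = 1) {
  stopifnot(m >= 1, r_factor > 0, tau >= 1)
  structure(list(m = as.integer(m), r_factor = r_factor,
                 tau = as.integer(tau)),
            class = "entropy_params")
}

#' Sample entropy
#'
#' The negative natural logarithm of the conditional probability that
#' subseries of length `m` matching within tolerance `r` (Chebyshev
#' distance) also match at the `m + 1`-th point:
#' `SampEn = -ln(A / B)`, with `B` the count of ordered template pairs
#' (`i != j`) of length `m` within `r` and `A` the analogous count at
#' length `m + 1`, both over the same template index range. Lower values
#' indicate a more regular, predictable signal.
#'
#' @param x numeric series.
#' @param params an [entropy_params()]; default `m = 2`,
#'   `r_factor = 0.2`, `tau = 1`.
#' @param r absolute tolerance; if `NULL` (default), `r = r_factor *
#'   SD(x)` (making the estimate invariant to affine rescaling of `x`).
#' @return non-negative scalar, in nats.
#' @export
sample_entropy <- function(x, params = entropy_params(), r = NULL) {
  stopifnot(is.numeric(x))
  m <- params$m; tau <- params$tau
  if (length(x) < m * tau + 2)
    stop("series too short: need N >= m*tau + 2")
  if (is.null(r)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate series: zero variance with relative tolerance")
    r <- params$r_factor * s
  }
  counts <- .sampen_counts(as.numeric(x), m, r, tau)
  A <- counts[1]; B <- counts[2]
  if (B == 0) stop("no length-m template matches; tolerance too small")
  if (A == 0) stop("no m+1 matches: sample entropy undefined (A = 0)")
  -log(A / B)
}

#' Conditional entropy from a joint count table
#'
#' `H(Y|X) = -sum_xy p(x,y) log p(y|x)` in nats, evaluated directly on a
#' (possibly unnormalized) joint contingency table with X in rows.
#'
#' @param counts non-negative matrix of joint counts or probabilities.
#' @return non-negative scalar (nats).
#' @export
conditional_entropy_table <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  tot <- sum(counts)
  if (tot <= 0) stop("empty joint table")
  p <- counts / tot
  px <- rowSums(p)
  h <- 0
  for (i in seq_len(nrow(p))) {
    if (px[i] == 0) next
    for (j in seq_len(ncol(p))) {
      if (p[i, j] == 0) next
      h <- h - p[i, j] * log(p[i, j] / px[i])
    }
  }
  max(h, 0)
}

#' Conditional entropy between two series
#'
#' Each series is discretized by its own quantile (equal-mass) bins,
#' which makes the estimate invariant under strictly monotone transforms
#' of either series; the joint histogram then yields
#' `H(Y|X) = -sum p(x,y) log p(y|x)` in nats. Convention: `x` is the
#' predictor (the HRF-convolved EEG envelope) and `y` the target
#' (hemoglobin), so the result is the residual entropy of the
#' hemodynamic signal once the electrical signal is known — the
#' neurovascular-coupling index.
#'
#' @param x,y numeric series of equal length.
#' @param bins number of quantile bins per variable (>= 2).
#' @return non-negative scalar (nats), at most `H(Y)`.
#' @export
conditional_entropy <- function(x, y, bins = 8) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  stopifnot(bins >= 2)
  if (length(x) < bins^2 / 5)
    warning("sparse joint histogram: series shorter than bins^2 / 5")
  xb <- quantile_bin(x, bins)
  yb <- quantile_bin(y, bins)
  counts <- table(factor(xb, levels = seq_len(bins)),
                  factor(yb, levels = seq_len(bins)))
  conditional_entropy_table(unclass(counts))
}

# Equal-mass binning by empirical quantiles; duplicate quantiles (ties,
# constant stretches) collapse bins, which is the desired degenerate
# behavior (a constant series occupies a single bin).
quantile_bin <- function(x, bins) {
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) return(rep(1L, length(x)))
  cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
}

#' Marginal entropy of a quantile-binned series
#'
#' `H(Y)` in nats under the same discretization as
#' [conditional_entropy()]; useful as its upper bound.
#'
#' @param y numeric series.
#' @param bins number of quantile bins.
#' @return non-negative scalar (nats).
#' @export
marginal_entropy <- function(y, bins = 8) {
  yb <- quantile_bin(y, bins)
  p <- tabulate(yb, nbins = max(yb)) / length(yb)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Stationarity gate with optional detrending
#'
#' Phillips-Perron unit-root test at level `alpha`. If the unit root is
#' not rejected, the series is linearly detrended and retested; series
#' still non-stationary after detrending are flagged for exclusion from
#' further analysis.
#'
#' @param x numeric series, length >= 20.
#' @param alpha significance level of the test.
#' @param subsample integer; the test statistic is evaluated on every
#'   `subsample`-th sample. Strongly oversampled band-limited series
#'   (e.g. a 0.01-0.4 Hz hemoglobin signal at 10 Hz) are locally almost
#'   perfectly autocorrelated and mimic a unit root; testing at a rate
#'   a few times the actual signal bandwidth restores the test's power
#'   without aliasing. Detrending is applied to the full-rate series.
#' @return list with `series` (possibly detrended, full rate),
#'   `statistic`, `p_value` (of the final test), `stationary`,
#'   `detrended`.
#' @export
check_stationarity <- function(x, alpha = 0.05, subsample = 1) {
  stopifnot(is.numeric(x), subsample >= 1)
  if (length(x) < 20) stop("series too short for a stationarity test")
  if (stats::sd(x) == 0) stop("constant series: stationarity undefined")
  sub <- function(v) v[seq(1L, length(v), by = as.integer(subsample))]
  if (length(sub(x)) < 20) stop("too few samples at the test subsampling")
  pp <- stats::PP.test(stats::ts(sub(x)))
  # the PP regression includes a linear trend, so a trending series can
  # be judged trend-stationary; downstream entropy needs the level
  # series, so a clearly significant linear trend also triggers
  # detrending (strict level: OLS slope p-values are anti-conservative
  # under autocorrelation)
  t_idx <- seq_along(x)
  fit <- stats::lm(x ~ t_idx)
  slope_p <- stats::coef(summary(fit))[2, 4]
  detrended <- FALSE
  if (pp$p.value > alpha || slope_p < alpha / 5) {
    x <- stats::residuals(fit)
    detrended <- TRUE
    pp <- stats::PP.test(stats::ts(sub(x)))
  }
  list(series = as.numeric(x),
       statistic = unname(pp$statistic),
       p_value = pp$p.value,
       stationary = pp$p.value <= alpha,
       detrended = detrended)
}

#' Truncate epochs to a common duration
#'
#' Complexity estimates depend on series length, so epochs from
#' different task phases are cut to the length of the shortest one,
#' keeping the initial samples.
#'
#' @param epochs non-empty list of numeric vectors.
#' @return list of vectors, all of the minimum input length.
#' @export
truncate_common <- function(epochs) {
  if (!is.list(epochs) || length(epochs) == 0L)
    stop("epochs must be a non-empty list")
  n <- min(vapply(epochs, length, integer(1)))
  lapply(epochs, function(e) e[seq_len(n)])
}
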