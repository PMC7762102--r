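# Periodized orthonormal discrete wavelet transform used for motion
# despiking of optical densities. Self-contained: only the Daubechies-5
# filter pair and the standard pyramid algorithm.

# Orthonormal Daubechies-5 scaling (low-pass) filter, 10 taps; sums to
# sqrt(2).
.db5_h <- c(
   0.1601023979741929, 0.6038292697971895, 0.7243085284377726,
   0.1384281459013203, -0.2422948870663823, -0.0322448695846381,
   0.0775714938400459, -0.0062414902127983, -0.0125807519990820,
   0.0033357252854738)

# Quadrature mirror high-pass: g[n] = (-1)^n h[L-1-n].
.db5_g <- rev(.db5_h) * (-1)^(seq_along(.db5_h) - 1)

# One periodized analysis step: x (length even) -> list(a, d).
dwt_step <- function(x) {
  N <- length(x)
  L <- length(.db5_h)
  k <- seq.int(0L, N / 2 - 1L)
  a <- numeric(N / 2)
  d <- numeric(N / 2)
  for (n in seq_len(L)) {
    idx <- (2L * k + (n - 1L)) %% N + 1L
    a <- a + .db5_h[n] * x[idx]
    d <- d + .db5_g[n] * x[idx]
  }
  list(a = a, d = d)
}

# Inverse of dwt_step (transpose of the orthogonal analysis matrix).
# For fixed filter tap n the target indices (2k + n) mod N are all
# distinct (stride-2 shifts are distinct modulo an even N), so plain
# vectorized accumulation is exact.
idwt_step <- function(a, d) {
  N <- 2L * length(a)
  x <- numeric(N)
  k <- seq.int(0L, length(a) - 1L)
  for (n in seq_along(.db5_h)) {
    idx <- (2L * k + (n - 1L)) %% N + 1L
    x[idx] <- x[idx] + .db5_h[n] * a + .db5_g[n] * d
  }
  x
}

# Multi-level periodized DWT; x length must be divisible by 2^levels.
dwt_pyramid <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    a <- s$a
    details[[j]] <- s$d
  }
  list(a = a, d = details)
}

idwt_pyramid <- function(decomp) {
  a <- decomp$a
  for (j in rev(seq_along(decomp$d))) a <- idwt_step(a, decomp$d[[j]])
  a
}

# Despike a single trace: decompose, zero detail coefficients whose
# magnitude lies outside the central (1 - alpha) mass of a Gaussian fit
# to that level's coefficients, reconstruct. The trace is
# reflection-padded on both sides by the coarsest-level filter
# footprint so that boundary-join artifacts (which the thresholding
# rightly flags) fall outside the retained region, and to a length
# divisible by 2^levels.
despike_trace <- function(x, alpha, levels) {
  n <- length(x)
  block <- 2L^levels
  margin <- 2L * (length(.db5_h) - 1L) * block
  margin <- min(margin, n - 2L)
  # antisymmetric (point-symmetric) extension: continuous value and
  # first derivative at both joins
  left <- 2 * x[1L] - x[(margin + 1L):2L]
  pad <- (block - (n + 2L * margin) %% block) %% block
  mr <- margin + pad
  mr_core <- min(mr, n - 1L)
  right <- 2 * x[n] - x[(n - 1L):(n - mr_core)]
  if (mr > mr_core) right <- c(right, rep(right[mr_core], mr - mr_core))
  x <- c(left, x, right)
  dec <- dwt_pyramid(x, levels)
  z <- stats::qnorm(1 - alpha / 2)
  for (j in seq_along(dec$d)) {
    d <- dec$d[[j]]
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) next
    flag <- abs(d - mean(d)) > z * s
    d[flag] <- 0
    dec$d[[j]] <- d
  }
  idwt_pyramid(dec)[margin + seq_len(n)]
}

#' Wavelet-based motion-artifact removal
#'
#' Each optical-density trace is decomposed with a 4-level periodized
#' Daubechies-5 wavelet transform; detail coefficients whose magnitude
#' falls outside the central `1 - alpha` probability mass of a Gaussian
#' fit to that level are zeroed, and the trace is reconstructed. Sharp
#' motion spikes concentrate in flagged detail coefficients while smooth
#' physiological oscillations pass essentially unchanged.
#'
#' @param od an [od_series()] or a numeric vector (length >= 16).
#' @param alpha tail probability in (0, 1); default 0.1.
#' @param levels decomposition depth.
#' @return despiked object of the same type as the input.
#' @export
wavelet_despike <- function(od, alpha = 0.1, levels = 4) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("alpha must lie strictly between 0 and 1")
  if (is.numeric(od) && is.null(dim(od))) {
    if (length(od) < 2^4) stop("series too short for wavelet despiking")
    return(despike_trace(od, alpha, levels))
  }
  stopifnot(inherits(od, "od_series"))
  if (dim(od$od)[3] < 2^4) stop("series too short for wavelet despiking")
  out <- od$od
  for (ch in seq_len(dim(out)[1]))
    for (wl in seq_len(dim(out)[2]))
      out[ch, wl, ] <- despike_trace(od$od[ch, wl, ], alpha, levels)
  od_series(out, od$rate, od$wavelengths, od$geometry)
}
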