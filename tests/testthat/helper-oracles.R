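# Independent brute-force oracles used to validate the fast
# implementations. Deliberately written as plain nested loops over the
# defining formulas, sharing no code with the package internals.

# Sample entropy by exhaustive template enumeration: ordered pairs
# i != j over the common index range 1 .. N - m*tau, Chebyshev distance.
sampen_oracle <- function(x, m, r, tau = 1) {
  n <- length(x)
  nt <- n - m * tau
  stopifnot(nt >= 2)
  tmpl <- function(i, len) x[i + (0:(len - 1)) * tau]
  B <- 0; A <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(tmpl(i, m) - tmpl(j, m))) <= r) {
        B <- B + 1
        if (max(abs(tmpl(i, m + 1) - tmpl(j, m + 1))) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Conditional entropy H(Y|X) from a joint count matrix via the chain
# rule H(Y|X) = H(X,Y) - H(X).
conden_oracle <- function(counts) {
  p <- counts / sum(counts)
  hxy <- -sum(ifelse(p > 0, p * log(p), 0))
  px <- rowSums(p)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hxy - hx
}

# Benjamini-Hochberg step-up adjusted p-values, literal definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# AUC as the fraction of concordant (positive, negative) score pairs,
# ties counted half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
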