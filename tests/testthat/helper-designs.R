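# shared generators and independent oracles

# random valid (n, N0, r, alpha) designs
random_designs <- function(n_designs, seed = 42L) {
  set.seed(seed)
  N0 <- sample(20:400, n_designs, replace = TRUE)
  n <- vapply(N0, function(m) sample(seq_len(m - 1L), 1L), integer(1))
  data.frame(
    n = n, N0 = N0,
    r = stats::runif(n_designs, 0.5, 3) * N0,
    alpha = stats::runif(n_designs, 0.005, 0.2)
  )
}

# independent oracle for the promising-zone bound: the z at which the
# conditional error change vanishes, found by root-finding on the two normal
# CDF terms of G directly (no call to bound_b)
bound_b_oracle <- function(n, N0, r, alpha = 0.025) {
  za <- qnorm(1 - alpha)
  g <- function(z) {
    a1 <- (sqrt(n / (N0 + r)) * z - za) / sqrt(1 - n / (N0 + r))
    a2 <- (sqrt(n / N0) * z - za) / sqrt(1 - n / N0)
    pnorm(a1) - pnorm(a2)
  }
  uniroot(g, c(1e-6, za * sqrt(n / N0) - 1e-9), tol = 1e-12)$root / za
}

# enumeration oracle for the exact binomial conditional error change:
# percentile by brute-force CDF scan, tails by summing pmf terms
g_binomial_oracle <- function(k, n, N0, r, p0, alpha) {
  pct <- function(m) {
    cdf <- cumsum(dbinom(0:m, m, p0))
    min(which(cdf >= 1 - alpha)) - 1L
  }
  tail_gt <- function(bar, m) {
    lo <- floor(bar) + 1L
    if (lo > m) return(0)
    sum(dbinom(max(lo, 0L):m, m, p0))
  }
  tail_gt(pct(N0 + r) - k, N0 + r - n) - tail_gt(pct(N0) - k, N0 - n)
}
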