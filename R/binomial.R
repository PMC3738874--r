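#' SSA design for a one-sample binomial proportion
#'
#' One-sided test of `H0: p = p0` against `p > p0` with a pre-planned interim
#' after `n` of `N0` observations and a candidate raise `r`. Derived
#' quantities: `sigma0 = sqrt(p0 (1 - p0))`, the standardized third cumulant
#' `gamma0 = (1 - 2 p0) / sigma0`, and the rule-of-thumb flag for normal
#' approximation validity, `min(n p0, n (1 - p0)) > 5`.
#'
#' @param p0 Null proportion, in (0, 1).
#' @param n Interim sample size.
#' @param N0 Planned final sample size (`n < N0`).
#' @param r Raise of the final sample size (positive).
#' @param alpha One-sided level.
#' @return An object of class `binom_ssa_design`.
#' @export
binomial_design <- function(p0, n, N0, r, alpha = 0.025) {
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly in (0, 1)", call. = FALSE)
  check_design(n, N0, r, alpha)
  sigma0 <- sqrt(p0 * (1 - p0))
  structure(
    list(
      p0 = p0, n = n, N0 = N0, r = r, alpha = alpha,
      z_alpha = stats::qnorm(1 - alpha),
      sigma0 = sigma0,
      gamma0 = (1 - 2 * p0) / sigma0,
      normal_ok = min(n * p0, n * (1 - p0)) > 5
    ),
    class = "binom_ssa_design"
  )
}

#' @export
print.binom_ssa_design <- function(x, ...) {
  cat(sprintf("Binomial SSA design: p0 = %g, n = %d, N0 = %d, r = %d, alpha = %g\n",
              x$p0, as.integer(x$n), as.integer(x$N0), as.integer(x$r), x$alpha))
  if (!x$normal_ok)
    cat("  note: min(n*p0, n*(1-p0)) <= 5; normal approximations unreliable\n")
  invisible(x)
}

#' Exact upper percentile of a binomial distribution
#'
#' The 100(1 - alpha) percentile of `Bin(m, p0)`: the smallest integer `t`
#' with `P(X <= t) >= 1 - alpha`. The associated exact test rejects when the
#' count strictly exceeds `t`, the only convention under which the fixed-size
#' test has level at most `alpha`.
#'
#' @param m Number of trials (vectorized).
#' @param p0 Success probability (vectorized).
#' @param alpha One-sided level.
#' @return Integer percentile(s).
#' @export
binomial_percentile <- function(m, p0, alpha = 0.025) {
  if (any(m < 1)) stop("'m' must be at least 1", call. = FALSE)
  stats::qbinom(1 - alpha, m, p0)
}

#' Cornish-Fisher approximation to a binomial upper percentile
#'
#' Skewness-corrected quantile approximation
#' \deqn{q_{\alpha,m} \approx m p_0 + \sqrt{m}\,\sigma_0
#'   \left(z_\alpha + \frac{\gamma_0 (z_\alpha^2 - 1)}{6\sqrt{m}}\right),}
#' with \eqn{\sigma_0 = \sqrt{p_0(1-p_0)}} and
#' \eqn{\gamma_0 = (1-2p_0)/\sigma_0}. At `p0 = 0.5` the skewness term
#' vanishes and the plain normal approximation remains. Within the
#' rule-of-thumb regime `min(m p0, m (1-p0)) > 5` (and `m` between about 20
#' and 200) the approximation stays within one count of the exact percentile.
#'
#' @inheritParams binomial_percentile
#' @return Real-valued percentile approximation(s). A warning is emitted when
#'   the rule of thumb `min(m p0, m (1-p0)) > 5` fails.
#' @export
cornish_fisher_percentile <- function(m, p0, alpha = 0.025) {
  if (any(m < 1)) stop("'m' must be at least 1", call. = FALSE)
  if (any(pmin(m * p0, m * (1 - p0)) <= 5))
    warning("min(m*p0, m*(1-p0)) <= 5 for some inputs; ",
            "Cornish-Fisher percentile may be inaccurate", call. = FALSE)
  za <- stats::qnorm(1 - alpha)
  sigma0 <- sqrt(p0 * (1 - p0))
  gamma0 <- (1 - 2 * p0) / sigma0
  m * p0 + sqrt(m) * sigma0 * (za + gamma0 * (za^2 - 1) / (6 * sqrt(m)))
}

# vectorized core of the exact conditional error change; all arguments may be
# vectors of equal length (or scalars). Given the interim count k, the final
# count is k plus an independent Bin(N - n, p0) remainder, so the conditional
# tail P(X_N > q | X_n = k) = P(Bin(N - n, p0) > q - k). pbinom() handles
# q - k < 0 (tail 1) and q - k >= N - n (tail 0) by saturation.
g_binom_exact_core <- function(k, n, N0, r, p0, alpha) {
  q_raised <- stats::qbinom(1 - alpha, N0 + r, p0)
  q_orig <- stats::qbinom(1 - alpha, N0, p0)
  stats::pbinom(q_orig - k, N0 - n, p0) -
    stats::pbinom(q_raised - k, N0 + r - n, p0)
}

#' Exact conditional type I error change for a binomial raise
#'
#' Given the interim count `k`, the change in conditional type I error when
#' the final sample size is raised from `N0` to `N0 + r`:
#' \deqn{G(r) = P_{p_0}(X_{N_0+r-n} > q_{\alpha,N_0+r} - k)
#'            - P_{p_0}(X_{N_0-n} > q_{\alpha,N_0} - k),}
#' with exact binomial percentiles ([binomial_percentile()]) and exact
#' binomial tails. Values are in \eqn{[-1, 1]}; sufficiently large interim
#' counts make the change non-positive.
#'
#' @param k Observed interim success count(s), in `0..n` (vectorized).
#' @param design A [binomial_design()] object.
#' @return Exact conditional error change(s).
#' @export
g_binomial_exact <- function(k, design) {
  stopifnot(inherits(design, "binom_ssa_design"))
  if (any(k < 0 | k > design$n)) stop("'k' must lie in 0..n", call. = FALSE)
  g_binom_exact_core(k, design$n, design$N0, design$r, design$p0, design$alpha)
}

#' Cornish-Fisher / normal approximation to the conditional error change
#'
#' Approximates [g_binomial_exact()] by replacing the exact percentiles with
#' their Cornish-Fisher approximations and the exact binomial tails with
#' normal tails of the pivotal quantities
#' \deqn{U_N = \frac{q_{\alpha,N} - k - (N-n) p_0}{\sqrt{N-n}\,\sigma_0},
#'   \qquad G(r) \approx \Phi(U_{N_0}) - \Phi(U_{N_0+r}).}
#' Accurate from interim sizes of about 20 onwards in the rule-of-thumb
#' regime.
#'
#' @inheritParams g_binomial_exact
#' @return Approximate conditional error change(s). Warns when the design
#'   falls outside the rule-of-thumb regime.
#' @export
g_binomial_cf_approx <- function(k, design) {
  stopifnot(inherits(design, "binom_ssa_design"))
  if (any(k < 0 | k > design$n)) stop("'k' must lie in 0..n", call. = FALSE)
  if (!design$normal_ok)
    warning("min(n*p0, n*(1-p0)) <= 5; normal approximation unreliable",
            call. = FALSE)
  n <- design$n; p0 <- design$p0; s0 <- design$sigma0
  n1 <- design$N0 + design$r
  n2 <- design$N0
  qcf <- function(m)
    m * p0 + sqrt(m) * s0 *
      (design$z_alpha + design$gamma0 * (design$z_alpha^2 - 1) / (6 * sqrt(m)))
  u1 <- (qcf(n1) - k - (n1 - n) * p0) / (sqrt(n1 - n) * s0)
  u2 <- (qcf(n2) - k - (n2 - n) * p0) / (sqrt(n2 - n) * s0)
  stats::pnorm(u2) - stats::pnorm(u1)
}

#' Interim count threshold permitting a raise (Cornish-Fisher criterion)
#'
#' The smallest interim count scale above which the Cornish-Fisher-normal
#' approximation to the conditional error change is non-positive:
#' \deqn{k > n p_0 + \frac{\gamma_0 \sigma_0 (z_\alpha^2 - 1)}{6}
#'   + \frac{(\sqrt{n_2-n}\sqrt{n_1} - \sqrt{n_1-n}\sqrt{n_2})\,
#'           z_\alpha \sigma_0}{\sqrt{n_2-n} - \sqrt{n_1-n}},}
#' with `n1 = N0 + r` (the larger final size) and `n2 = N0`. The first term is
#' the null expectation; the second (skewness) term is negative exactly when
#' `p0 > 0.5`; the third term is always positive here -- it equals
#' `sqrt(n) * b(q, V) * z_alpha * sigma0`, the count-scale image of the
#' normal-endpoint promising-zone threshold, slightly below the
#' simple-criterion spread (see [simple_k_threshold()]).
#'
#' @param design A [binomial_design()] object.
#' @param terms If `TRUE`, also return the three additive terms.
#' @return The real-valued threshold, or (with `terms = TRUE`) a list with
#'   `threshold`, `term_null`, `term_skew`, `term_bound`.
#' @export
k_threshold <- function(design, terms = FALSE) {
  stopifnot(inherits(design, "binom_ssa_design"))
  n <- design$n; p0 <- design$p0; s0 <- design$sigma0
  n1 <- design$N0 + design$r
  n2 <- design$N0
  za <- design$z_alpha
  term_null <- n * p0
  term_skew <- design$gamma0 * s0 * (za^2 - 1) / 6
  term_bound <- (sqrt(n2 - n) * sqrt(n1) - sqrt(n1 - n) * sqrt(n2)) * za * s0 /
    (sqrt(n2 - n) - sqrt(n1 - n))
  thr <- term_null + term_skew + term_bound
  if (terms)
    list(threshold = thr, term_null = term_null,
         term_skew = term_skew, term_bound = term_bound)
  else thr
}

#' Interim count threshold under the simple (50% conditional power) criterion
#'
#' The count-scale form of the simple criterion
#' `z > z_alpha * sqrt(n / N0)` applied to the score statistic:
#' `k > n p0 + n sigma0 z_alpha / sqrt(N0)`. Stricter than [k_threshold()] in
#' the regimes simulated here, hence conservative.
#'
#' @param design A [binomial_design()] object.
#' @return The real-valued threshold.
#' @export
simple_k_threshold <- function(design) {
  stopifnot(inherits(design, "binom_ssa_design"))
  design$n * design$p0 +
    design$n * design$sigma0 * design$z_alpha / sqrt(design$N0)
}

#' Interim test statistics for a binomial proportion
#'
#' Two asymptotically standard normal statistics for `H0: p = p0` at interim
#' count `k` out of `n`:
#' the score statistic `sqrt(n) (phat - p0) / sqrt(p0 (1 - p0))` and the
#' log-odds statistic
#' `sqrt(n phat (1 - phat)) * (logit(phat) - logit(p0))`. The log-odds
#' statistic is undefined at `phat` of 0 or 1.
#'
#' @param k Interim success count.
#' @param n Interim sample size.
#' @param p0 Null proportion.
#' @param statistic Which statistic(s) to compute.
#' @return A list with elements `score` and/or `log_odds`.
#' @export
interim_score_statistics <- function(k, n, p0,
                                     statistic = c("both", "score", "log_odds")) {
  statistic <- match.arg(statistic)
  if (k < 0 || k > n) stop("'k' must lie in 0..n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie in (0, 1)", call. = FALSE)
  phat <- k / n
  out <- list()
  if (statistic %in% c("both", "score"))
    out$score <- sqrt(n) * (phat - p0) / sqrt(p0 * (1 - p0))
  if (statistic %in% c("both", "log_odds")) {
    if (k == 0 || k == n)
      stop("log-odds statistic is undefined at k = 0 or k = n ",
           "(observed proportion on the boundary)", call. = FALSE)
    out$log_odds <- sqrt(n * phat * (1 - phat)) *
      (log(phat / (1 - phat)) - log(p0 / (1 - p0)))
  }
  out
}

#' Simulation study of the conditional error change under a raising criterion
#'
#' Replicates the large randomized-design study of the binomial raise: each
#' iteration draws an interim size `n` uniformly on the integers 20..100, sets
#' `N0 = 2n` and `r = n`, draws `p0` uniformly on `[5/n, 1 - 5/n]` and the
#' interim count `k` from `Bin(n, p0)`; iterations whose `k` strictly exceeds
#' the chosen criterion's threshold are retained and the exact conditional
#' error change [g_binomial_exact()] is recorded for them. With a common
#' `seed`, the two criteria see identical draws, so their summaries differ
#' only through retention.
#'
#' @param n_sims Number of iterations (at least 1000).
#' @param criterion `"derived"` for [k_threshold()], `"simple"` for
#'   [simple_k_threshold()].
#' @param alpha One-sided level.
#' @param seed Integer seed for the draw stream.
#' @return An object of class `binom_ssr_study`: list with `median`, `mean`,
#'   `n_retained`, `retention_rate`, `n_sims`, `criterion`, `alpha`, `seed`,
#'   and the retained `G` values.
#' @export
binom_ssr_study <- function(n_sims, criterion = c("derived", "simple"),
                            alpha = 0.025, seed = 1L) {
  criterion <- match.arg(criterion)
  if (n_sims < 1000) stop("'n_sims' must be at least 1000", call. = FALSE)
  set.seed(seed)
  n <- sample(20:100, n_sims, replace = TRUE)
  p0 <- stats::runif(n_sims, 5 / n, 1 - 5 / n)
  k <- stats::rbinom(n_sims, n, p0)
  N0 <- 2L * n
  r <- n
  s0 <- sqrt(p0 * (1 - p0))
  g0 <- (1 - 2 * p0) / s0
  za <- stats::qnorm(1 - alpha)
  n1 <- N0 + r
  n2 <- N0
  thr <- if (criterion == "derived") {
    n * p0 + g0 * s0 * (za^2 - 1) / 6 +
      (sqrt(n2 - n) * sqrt(n1) - sqrt(n1 - n) * sqrt(n2)) * za * s0 /
        (sqrt(n2 - n) - sqrt(n1 - n))
  } else {
    n * p0 + n * s0 * za / sqrt(N0)
  }
  keep <- k > thr
  if (!any(keep))
    stop("no iteration passed the raising criterion; increase 'n_sims'",
         call. = FALSE)
  G <- g_binom_exact_core(k[keep], n[keep], N0[keep], r[keep], p0[keep], alpha)
  structure(
    list(median = stats::median(G), mean = mean(G),
         n_retained = sum(keep), retention_rate = mean(keep),
         n_sims = n_sims, criterion = criterion, alpha = alpha, seed = seed,
         G = G),
    class = "binom_ssr_study"
  )
}

#' @export
print.binom_ssr_study <- function(x, ...) {
  cat(sprintf(
    "Binomial SSA study: %d sims, criterion = %s, alpha = %g, seed = %d\n",
    x$n_sims, x$criterion, x$alpha, x$seed))
  cat(sprintf("  retained %d (%.1f%%); G(r): median = %.7g, mean = %.7g\n",
              x$n_retained, 100 * x$retention_rate, x$median, x$mean))
  invisible(x)
}
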