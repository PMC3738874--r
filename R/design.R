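#' Frozen design of a sample-size-adjustable (SSA) trial
#'
#' Bundles the quantities fixed in the protocol of a one-look SSA design: the
#' interim sample size `n`, the originally planned final size `N0`, the
#' candidate raise `r` under consideration at the interim, and the one-sided
#' significance level `alpha`. Derived quantities are attached: the critical
#' value `z_alpha`, the information fraction against the raised design
#' `q = n / (N0 + r)`, the inflation factor `V = (N0 + r) / N0`, and their
#' product `qV = n / N0` (which does not depend on `r`).
#'
#' `r` is accepted as any positive real, not only an integer: the limiting
#' behaviour of the bound as `r` shrinks is of interest in itself, and the
#' algebra nowhere requires integrality. Practical raises are integers.
#'
#' @param n Interim sample size (positive, less than `N0`).
#' @param N0 Planned final sample size.
#' @param r Proposed raise of the final sample size (positive).
#' @param alpha One-sided significance level, in (0, 0.5).
#' @return An object of class `ssa_design`: a list with elements `n`, `N0`,
#'   `r`, `alpha`, `z_alpha`, `q`, `V`, `qV`.
#' @examples
#' d <- ssa_design(n = 55, N0 = 110, r = 40)
#' d$qV            # information fraction of the original design, 0.5
#' @export
ssa_design <- function(n, N0, r, alpha = 0.025) {
  check_design(n, N0, r, alpha)
  structure(
    list(
      n = n, N0 = N0, r = r, alpha = alpha,
      z_alpha = stats::qnorm(1 - alpha),
      q = n / (N0 + r),
      V = (N0 + r) / N0,
      qV = n / N0
    ),
    class = "ssa_design"
  )
}

#' @export
print.ssa_design <- function(x, ...) {
  cat("SSA design: interim n =", x$n, ", planned N0 =", x$N0,
      ", candidate raise r =", x$r, "\n")
  cat(sprintf("  one-sided alpha = %g (z_alpha = %.7g)\n", x$alpha, x$z_alpha))
  cat(sprintf("  q = n/(N0+r) = %.7g, V = (N0+r)/N0 = %.7g, n/N0 = %.7g\n",
              x$q, x$V, x$qV))
  invisible(x)
}

# shared domain checks; r = 0 is rejected here because the bound formula is
# 0/0 there -- the limit is exposed separately via bound_b_limit()
check_design <- function(n, N0, r = 1, alpha = 0.025) {
  if (!is.numeric(n) || !is.numeric(N0) || n <= 0 || N0 <= 0)
    stop("sample sizes 'n' and 'N0' must be positive numbers", call. = FALSE)
  if (n >= N0)
    stop("interim size 'n' must be strictly less than the planned size 'N0'",
         call. = FALSE)
  if (!is.numeric(r) || any(r <= 0))
    stop("raise 'r' must be strictly positive (use bound_b_limit() for r = 0)",
         call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("one-sided level 'alpha' must lie in (0, 0.5)", call. = FALSE)
  invisible(TRUE)
}

#' Interim result of an SSA trial
#'
#' Records the standardized interim test statistic and the sample size it is
#' based on. The contract is that `z` has been standardized by the caller so
#' that it is (approximately) standard normal under the null hypothesis; see
#' [standardize_mean_difference()] for the known-variance normal case.
#'
#' @param z Standardized interim statistic (finite).
#' @param n Interim sample size the statistic is based on.
#' @return An object of class `ssa_interim` with elements `z`, `n`, and
#'   `theta_hat = z / sqrt(n)`, the interim drift estimate.
#' @export
ssa_interim <- function(z, n) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("interim statistic 'z' must be a single finite number", call. = FALSE)
  if (!is.numeric(n) || n <= 0)
    stop("interim sample size 'n' must be positive", call. = FALSE)
  structure(list(z = z, n = n, theta_hat = z / sqrt(n)), class = "ssa_interim")
}

#' Standardize a mean difference with known variance
#'
#' Turns an observed mean of `n` unit-information observations into the
#' standardized statistic `sqrt(n) * (xbar - theta0) / sigma` consumed by the
#' interim machinery. With unknown variance a t-statistic may be substituted;
#' it is only approximately standard normal and no adjustment is applied.
#'
#' @param xbar Observed mean.
#' @param n Number of observations behind `xbar`.
#' @param sigma Known standard deviation of a single observation.
#' @param theta0 Null value of the mean (default 0).
#' @return The standardized z statistic.
#' @export
standardize_mean_difference <- function(xbar, n, sigma = 1, theta0 = 0) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  sqrt(n) * (xbar - theta0) / sigma
}
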