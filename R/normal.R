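#' Promising-zone bound b(q, V) for a raised sample size
#'
#' The interim z-statistic threshold above which raising the final sample size
#' from `N0` to `N0 + r` cannot increase the conditional (and hence the
#' unconditional) type I error rate is `z_alpha * b(q, V)`, with
#' `q = n / (N0 + r)`, `V = (N0 + r) / N0` and
#'
#' \deqn{b(q,V) = \frac{\sqrt{1-q} - \sqrt{1-qV}}
#'   {\sqrt{qV}\sqrt{1-q} - \sqrt{q}\sqrt{1-qV}}.}
#'
#' `b` lies strictly between its two limits,
#' \eqn{(1-\sqrt{1-qV})/\sqrt{qV} < b(q,V) < \sqrt{qV}}, is strictly
#' decreasing in `r`, tends to \eqn{\sqrt{n/N_0}} as `r` shrinks to 0 (the
#' classical 50%-conditional-power rule) and to the lower limit as `r` grows
#' (see [bound_b_limit()]).
#'
#' @param n Interim sample size.
#' @param N0 Planned final sample size (`n < N0`).
#' @param r Proposed raise (strictly positive; may be vectorized).
#' @return The dimensionless bound value(s) `b(q, V)`.
#' @examples
#' bound_b(55, 110, 0.01)   # 0.7070907, essentially sqrt(55/110)
#' bound_b(55, 110, 40)     # a visibly smaller threshold multiplier
#' @export
bound_b <- function(n, N0, r) {
  check_design(n, N0, r)
  q <- n / (N0 + r)
  qV <- n / N0
  (sqrt(1 - q) - sqrt(1 - qV)) /
    (sqrt(qV) * sqrt(1 - q) - sqrt(q) * sqrt(1 - qV))
}

#' Infimum of the promising-zone bound as the raise grows without limit
#'
#' As `r` increases, `b(n, N0, r)` decreases monotonically towards
#' \eqn{(1 - \sqrt{1 - n/N_0}) / \sqrt{n/N_0}}. No finite raise reaches this
#' value; it caps how far the permitted zone can extend below the simple
#' criterion `sqrt(n/N0)`.
#'
#' @inheritParams bound_b
#' @return The infimum of `bound_b(n, N0, r)` over `r > 0`.
#' @examples
#' bound_b_limit(55, 110)   # (1 - sqrt(0.5)) / sqrt(0.5) = 0.4142136
#' @export
bound_b_limit <- function(n, N0) {
  check_design(n, N0)
  qV <- n / N0
  (1 - sqrt(1 - qV)) / sqrt(qV)
}

#' Conditional type I error of the final test given the interim statistic
#'
#' Under the null, the final standardized statistic given the interim one is
#' normal with mean `rho * z` and variance `1 - rho^2`, `rho = sqrt(n/N_final)`
#' being the correlation induced by the shared observations. The conditional
#' error is therefore
#' \deqn{A(z) = 1 - \Phi\!\left(\frac{z_\alpha - \sqrt{n/N}\,z}
#'   {\sqrt{1 - n/N}}\right).}
#' Its integral against the standard normal density of `z` recovers `alpha`
#' exactly: this is what makes it a proper conditional error function.
#'
#' @param z Interim standardized statistic (vectorized).
#' @param n Interim sample size.
#' @param N_final Final sample size the test will be run at (`n < N_final`).
#' @param alpha One-sided level.
#' @return Conditional rejection probability/ies under the null, in (0, 1).
#' @export
conditional_error <- function(z, n, N_final, alpha = 0.025) {
  check_design(n, N_final, alpha = alpha)
  rho <- sqrt(n / N_final)
  1 - stats::pnorm((stats::qnorm(1 - alpha) - rho * z) / sqrt(1 - rho^2))
}

#' Conditional power at the interim drift estimate
#'
#' The probability of final rejection given the interim statistic, evaluated
#' under the drift equal to its interim estimate `theta_hat = z / sqrt(n)`:
#' \deqn{CP(z) = 1 - \Phi\!\left(\frac{z_\alpha - z/\sqrt{n/N}}
#'   {\sqrt{1 - n/N}}\right).}
#' At the simple criterion `z = z_alpha * sqrt(n/N)` the argument vanishes
#' and the conditional power is exactly 50%.
#'
#' @inheritParams conditional_error
#' @return Conditional power value(s) in (0, 1).
#' @export
conditional_power <- function(z, n, N_final, alpha = 0.025) {
  check_design(n, N_final, alpha = alpha)
  f <- n / N_final
  1 - stats::pnorm((stats::qnorm(1 - alpha) - z / sqrt(f)) / sqrt(1 - f))
}

#' Change in conditional type I error caused by raising the sample size
#'
#' `G(r)` is the conditional error of the raised design minus that of the
#' original design, both given the interim statistic `z` under the null:
#' \deqn{G(r) = A_{N_0+r}(z) - A_{N_0}(z).}
#' It is non-positive exactly when `z >= z_alpha * bound_b(n, N0, r)`; at the
#' threshold it vanishes, which is why the bound cannot be improved.
#'
#' @param z Interim standardized statistic (vectorized).
#' @param n Interim sample size.
#' @param N0 Planned final sample size.
#' @param r Proposed raise (positive).
#' @param alpha One-sided level.
#' @return The conditional error change(s); negative values mean the raise is
#'   conservative at this `z`.
#' @export
g_normal <- function(z, n, N0, r, alpha = 0.025) {
  check_design(n, N0, r, alpha)
  conditional_error(z, n, N0 + r, alpha) - conditional_error(z, n, N0, alpha)
}

#' Minimum conditional power over the permitted raising zone
#'
#' Conditional power is increasing in `z`, so its minimum over the zone where
#' a raise of `r` is permitted (`z >= z_alpha * b`) is attained at the
#' threshold:
#' \deqn{\Phi\!\left(z_\alpha\,\frac{b(q,V)/\sqrt{qV} - 1}
#'   {\sqrt{1-qV}}\right).}
#' This is the least promising interim, expressed on the conditional power
#' scale, at which the raise still cannot inflate the type I error rate. It
#' equals 50% in the limit of a vanishing raise and decreases as `r` grows.
#'
#' @inheritParams g_normal
#' @return A probability in (0, 0.5].
#' @examples
#' min_conditional_power(55, 110, 40)    # 0.43 at two decimals
#' min_conditional_power(55, 110, 110)   # 0.3575873
#' @export
min_conditional_power <- function(n, N0, r, alpha = 0.025) {
  check_design(n, N0, r, alpha)
  qV <- n / N0
  b <- bound_b(n, N0, r)
  stats::pnorm(stats::qnorm(1 - alpha) * (b / sqrt(qV) - 1) / sqrt(1 - qV))
}

#' All interim thresholds of an SSA design
#'
#' Convenience wrapper computing, for one design, the bound `b`, the z-scale
#' threshold `z_alpha * b`, the stricter simple-criterion threshold
#' `z_alpha * sqrt(n/N0)` (conditional power 50%), and the minimum conditional
#' power over the permitted zone.
#'
#' @param design An [ssa_design()] object.
#' @return An object of class `ssa_bound`: list with `b`, `z_threshold`,
#'   `simple_threshold`, `min_conditional_power`.
#' @examples
#' ssa_thresholds(ssa_design(55, 110, 40, 0.025))
#' @export
ssa_thresholds <- function(design) {
  stopifnot(inherits(design, "ssa_design"))
  b <- bound_b(design$n, design$N0, design$r)
  structure(
    list(
      b = b,
      z_threshold = design$z_alpha * b,
      simple_threshold = design$z_alpha * sqrt(design$qV),
      min_conditional_power =
        min_conditional_power(design$n, design$N0, design$r, design$alpha)
    ),
    class = "ssa_bound"
  )
}

#' @export
print.ssa_bound <- function(x, ...) {
  cat(sprintf("b(q,V)              = %.7g\n", x$b))
  cat(sprintf("z threshold (raise) = %.7g\n", x$z_threshold))
  cat(sprintf("simple threshold    = %.7g\n", x$simple_threshold))
  cat(sprintf("min cond. power     = %.7g\n", x$min_conditional_power))
  invisible(x)
}

#' Three-way interim decision: futility, continue, or raise
#'
#' Compares the observed interim statistic with a user-supplied futility
#' threshold and with the promising-zone threshold `z_alpha * b(q, V)` for the
#' design's candidate raise. A tie with the raising threshold permits the
#' raise: the conditional error change is exactly zero there. No futility rule
#' is imposed by default (`futility_threshold = -Inf`); stopping for futility
#' can only lower the type I error rate, so its placement is left to the
#' analyst.
#'
#' @param interim An [ssa_interim()] object (or a single numeric z).
#' @param design An [ssa_design()] object; `interim$n` must match `design$n`.
#' @param futility_threshold Stop for futility when `z` falls strictly below
#'   this value; must be below the raising threshold.
#' @return An object of class `ssa_decision`: list with `verdict` (one of
#'   `"futility"`, `"continue"`, `"raise_permitted"`), `g_value` (the
#'   conditional error change at this `z` and `r`), `z_threshold`,
#'   `simple_threshold`, and a human-readable `rationale`.
#' @examples
#' d <- ssa_design(55, 110, 40, 0.025)
#' ssa_decide(ssa_interim(z = 1.5, n = 55), d)
#' @export
ssa_decide <- function(interim, design, futility_threshold = -Inf) {
  stopifnot(inherits(design, "ssa_design"))
  if (is.numeric(interim) && length(interim) == 1L)
    interim <- ssa_interim(interim, design$n)
  stopifnot(inherits(interim, "ssa_interim"))
  if (interim$n != design$n)
    stop("interim sample size does not match the design's 'n'", call. = FALSE)

  thr <- ssa_thresholds(design)
  if (futility_threshold >= thr$z_threshold)
    stop("futility threshold must lie strictly below the raising threshold ",
         sprintf("z_alpha * b = %.7g", thr$z_threshold), call. = FALSE)

  z <- interim$z
  g <- g_normal(z, design$n, design$N0, design$r, design$alpha)
  if (z < futility_threshold) {
    verdict <- "futility"
    rationale <- sprintf(
      "z = %.7g fell below the futility threshold %.7g", z, futility_threshold)
  } else if (z >= thr$z_threshold) {
    verdict <- "raise_permitted"
    rationale <- sprintf(
      "z = %.7g reached the raising threshold z_alpha*b = %.7g (G(r) = %.3g <= 0)",
      z, thr$z_threshold, g)
  } else {
    verdict <- "continue"
    rationale <- sprintf(
      "z = %.7g lies between the futility threshold %.7g and the raising threshold %.7g; raising now would change the conditional error by G(r) = %.3g > 0",
      z, futility_threshold, thr$z_threshold, g)
  }
  structure(
    list(verdict = verdict, g_value = g,
         z_threshold = thr$z_threshold,
         simple_threshold = thr$simple_threshold,
         rationale = rationale),
    class = "ssa_decision"
  )
}

#' @export
print.ssa_decision <- function(x, ...) {
  cat("Interim decision:", x$verdict, "\n")
  cat(" ", x$rationale, "\n")
  invisible(x)
}
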