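#' Sample-size raising rule for the trial-level Monte-Carlo engine
#'
#' Encodes the interim policies whose unconditional type I error the engine
#' compares: raise when the interim z reaches the promising-zone bound
#' (`"derived_bound"`), the stricter 50%-conditional-power bound
#' (`"simple_criterion"`), always, never, at a user-chosen z threshold, or
#' only when z falls inside a user-chosen band (`"custom_band"`,
#' `custom_z = c(lo, hi)`; raise iff `lo <= z < hi`).
#'
#' Any one-sided threshold rule has unconditional level at most `alpha`: the
#' conditional-error surplus accumulated below the promising-zone bound is
#' exactly offset by the deficit above it, with equality only for the
#' degenerate always/never rules. The band rule exists to show the bound is
#' not vacuous: raising only inside the region where the conditional error
#' change is positive (below `z_alpha * b`) strictly inflates the level.
#'
#' @param kind Rule kind.
#' @param custom_z Threshold (length 1) for `"custom_threshold"`, band
#'   endpoints (length 2, increasing) for `"custom_band"`.
#' @return An object of class `ssa_rule`.
#' @export
ssa_rule <- function(kind = c("derived_bound", "simple_criterion",
                              "always_raise", "never_raise",
                              "custom_threshold", "custom_band"),
                     custom_z = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom_threshold" &&
      (!is.numeric(custom_z) || length(custom_z) != 1L))
    stop("'custom_z' must be a single number for a custom threshold rule",
         call. = FALSE)
  if (kind == "custom_band" &&
      (!is.numeric(custom_z) || length(custom_z) != 2L ||
         custom_z[1] >= custom_z[2]))
    stop("'custom_z' must be an increasing pair c(lo, hi) for a band rule",
         call. = FALSE)
  structure(list(kind = kind, custom_z = custom_z), class = "ssa_rule")
}

# the z interval [lo, hi) on which the rule raises (ties at lo raise; the
# conditional error change is exactly zero at the derived bound)
rule_raise_interval <- function(rule, design) {
  stopifnot(inherits(rule, "ssa_rule"), inherits(design, "ssa_design"))
  switch(rule$kind,
    derived_bound =
      c(design$z_alpha * bound_b(design$n, design$N0, design$r), Inf),
    simple_criterion = c(design$z_alpha * sqrt(design$qV), Inf),
    always_raise = c(-Inf, Inf),
    never_raise = c(Inf, Inf),
    custom_threshold = c(rule$custom_z, Inf),
    custom_band = rule$custom_z
  )
}

#' Monte-Carlo rejection rate of an SSA trial under a raising rule
#'
#' Simulates whole trials with unit-variance normal observations of mean
#' `theta`: the interim statistic is observed after `n` observations, the
#' rule decides whether the final analysis uses `N0` or `N0 + r`
#' observations, and the final equally-weighted standardized statistic is
#' compared with `z_alpha`. `theta = 0` estimates the type I error rate;
#' `theta > 0` the power. All draws come from a single documented stream
#' under `set.seed(seed)`: first the `n_sims` interim statistics, then the
#' `n_sims` standardized post-interim increments, so results are independent
#' of how the arithmetic is vectorized.
#'
#' @param design An [ssa_design()] object.
#' @param rule An [ssa_rule()] object.
#' @param theta Common mean of the observations (drift).
#' @param n_sims Number of simulated trials (at least 1e4).
#' @param seed Integer seed.
#' @return An object of class `ssa_sim_report`: list with `rejection_rate`,
#'   `mc_se` (binomial standard error), `raise_fraction`,
#'   `mean_G_over_raised` (average conditional error change over trials that
#'   raised; `NA` if none), `n_sims`, `seed`, `theta`, `rule`.
#' @export
simulate_type1 <- function(design, rule, theta = 0, n_sims = 1e5, seed = 1L) {
  stopifnot(inherits(design, "ssa_design"), inherits(rule, "ssa_rule"))
  if (n_sims < 1e4) stop("'n_sims' must be at least 1e4", call. = FALSE)
  n <- design$n; N0 <- design$N0; r <- design$r
  iv <- rule_raise_interval(rule, design)
  set.seed(seed)
  z_interim <- stats::rnorm(n_sims, mean = theta * sqrt(n), sd = 1)
  raise <- z_interim >= iv[1] & z_interim < iv[2]
  N <- ifelse(raise, N0 + r, N0)
  # sum of the N - n post-interim observations, standardized at the end
  s_rest <- stats::rnorm(n_sims, mean = theta * (N - n), sd = sqrt(N - n))
  z_final <- (sqrt(n) * z_interim + s_rest) / sqrt(N)
  rejected <- z_final > design$z_alpha
  p_hat <- mean(rejected)
  mean_g <- if (any(raise))
    mean(g_normal(z_interim[raise], n, N0, r, design$alpha))
  else NA_real_
  structure(
    list(rejection_rate = p_hat,
         mc_se = sqrt(p_hat * (1 - p_hat) / n_sims),
         raise_fraction = mean(raise),
         mean_G_over_raised = mean_g,
         n_sims = n_sims, seed = seed, theta = theta, rule = rule$kind),
    class = "ssa_sim_report"
  )
}

#' @export
print.ssa_sim_report <- function(x, ...) {
  cat(sprintf(
    "SSA simulation (%s, theta = %g, %d trials, seed %d):\n",
    x$rule, x$theta, x$n_sims, x$seed))
  cat(sprintf("  rejection rate %.7g (MC SE %.3g), raised in %.1f%% of trials\n",
              x$rejection_rate, x$mc_se, 100 * x$raise_fraction))
  invisible(x)
}

#' Exact unconditional type I error of a deterministic raising rule
#'
#' Deterministic twin of [simulate_type1()] at `theta = 0`: integrates the
#' conditional error function of the chosen final size against the standard
#' normal density of the interim statistic over the rule's raise and no-raise
#' regions, by adaptive quadrature. The `never_raise` and `always_raise`
#' rules recover `alpha` exactly (a fixed design either way); every one-sided
#' threshold rule stays at or below `alpha`; a band rule confined to the
#' region below the promising-zone bound exceeds it.
#'
#' @param design An [ssa_design()] object.
#' @param rule An [ssa_rule()] object (deterministic in z).
#' @return The unconditional rejection probability under the null.
#' @export
exact_type1_by_quadrature <- function(design, rule) {
  stopifnot(inherits(design, "ssa_design"), inherits(rule, "ssa_rule"))
  iv <- rule_raise_interval(rule, design)
  n <- design$n; N0 <- design$N0; alpha <- design$alpha
  piece <- function(N_final, lo, hi) {
    if (lo >= hi) return(0)
    stats::integrate(
      function(z) conditional_error(z, n, N_final, alpha) * stats::dnorm(z),
      lo, hi, rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L
    )$value
  }
  piece(N0, -Inf, iv[1]) + piece(N0 + design$r, iv[1], iv[2]) +
    piece(N0, iv[2], Inf)
}

#' Reproducible synthetic trial fixture
#'
#' Draws the full vector of `N0 + r` unit-variance normal observations with
#' mean `theta` and packages the interim statistic after `n` of them together
#' with the final statistics under both the planned and the raised size.
#' Identical seeds give identical fixtures, and every stored statistic can be
#' recomputed from the raw observations.
#'
#' @param design An [ssa_design()] object (integer `n`, `N0`, `r`).
#' @param theta Common observation mean.
#' @param seed Integer seed.
#' @return A list with `observations`, `z_interim`, `z_final_N0`,
#'   `z_final_raised`, `theta`, `seed`.
#' @export
generate_trial_fixture <- function(design, theta = 0, seed = 1L) {
  stopifnot(inherits(design, "ssa_design"))
  n <- as.integer(design$n); N0 <- as.integer(design$N0)
  N <- N0 + as.integer(design$r)
  set.seed(seed)
  x <- stats::rnorm(N, mean = theta, sd = 1)
  list(
    observations = x,
    z_interim = sum(x[seq_len(n)]) / sqrt(n),
    z_final_N0 = sum(x[seq_len(N0)]) / sqrt(N0),
    z_final_raised = sum(x) / sqrt(N),
    theta = theta, seed = seed
  )
}
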