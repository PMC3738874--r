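---
title: "The promising zone for raising a trial's sample size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The promising zone for raising a trial's sample size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrzone)
```

## The design problem

A sample-size-adjustable (SSA) trial plans `N0` subjects, looks at the data
once after `n` of them, and lets a Data Monitoring Committee choose between
stopping for futility, continuing as planned, or recruiting `r` extra
subjects. The worry with the third option is type I error inflation: raising
the sample size exactly when the interim data look *mediocre* gives the null
hypothesis extra chances in the region where it was about to survive.

The classical rule of thumb permits the raise when the conditional power at
the interim estimate reaches 50%, equivalently when the interim statistic
satisfies `z >= z_alpha * sqrt(n / N0)`. This package implements a weaker,
raise-dependent threshold that still cannot inflate the error rate, together
with the machinery needed to use it for normal, binomial and survival
endpoints, and a simulation engine that verifies the claim empirically.

## Model and main result

Observations are i.i.d. `N(theta, 1)` (unit variance is a contract on the
caller: `standardize_mean_difference()` maps a known-variance mean difference
onto this scale). With `Z^(m)` the standardized partial-sum statistic, the
pair `(Z^(n), Z^(N))` is bivariate normal with correlation
`rho = sqrt(n / N)`, so under the null

    Z^(N) | Z^(n) = z  ~  N(rho * z, 1 - rho^2).

The conditional probability of final rejection (`conditional_error()`) is
therefore an explicit normal tail, and the *change* caused by raising the
final size from `N0` to `N0 + r`,

    G(r) = A_{N0+r}(z) - A_{N0}(z),

is non-positive exactly when `z >= z_alpha * b(q, V)` where
`q = n / (N0 + r)`, `V = (N0 + r) / N0`, and

    b(q, V) = (sqrt(1-q) - sqrt(1-qV)) / (sqrt(qV) sqrt(1-q) - sqrt(q) sqrt(1-qV)).

`bound_b()` evaluates this; `min_conditional_power()` re-expresses the
threshold on the conditional power scale,

    Phi( z_alpha * (b / sqrt(qV) - 1) / sqrt(1 - qV) ),

which is exactly 50% in the limit `r -> 0` and decreases as the contemplated
raise grows — a larger raise is *safer*, because the mediocre interim gets
diluted more. The bound is sandwiched,

    (1 - sqrt(1-qV)) / sqrt(qV)  <  b(q, V)  <  sqrt(qV),

so the permitted zone always extends below the simple criterion but never
below the left limit (`bound_b_limit()`).

```{r worked}
d <- ssa_design(n = 55, N0 = 110, r = 40, alpha = 0.025)
ssa_thresholds(d)
min_conditional_power(55, 110, 110)   # doubling the trial: 36% suffices
bound_b(55, 110, 0.01)                # r -> 0 recovers sqrt(n/N0)
```

A conditional power well under 50% can therefore justify a raise, provided
the raise is large enough.

### Decisions and ties

`ssa_decide()` applies the three-way decision. A tie `z == z_alpha * b` is
resolved in favour of raising: `G = 0` there, so the raise is exactly
neutral. The futility threshold defaults to `-Inf` (disabled) because
stopping for futility can only lower the error rate and no principled
placement exists on type-I-error grounds alone; it is the analyst's choice.
`r = 0` is excluded from `bound_b()` — the formula is 0/0 there — and the
limiting value `sqrt(n / N0)` is exposed separately rather than special-cased.

### What "optimal" means, exactly

Two statements must be kept apart.

*Conditionally*, the bound is sharp: for any `z` strictly below
`z_alpha * b`, raising increases the conditional error (`G(z) > 0`), so no
smaller threshold can claim preservation via the conditional-error argument.

*Unconditionally*, however, every one-sided rule "raise iff `z >= t`" has
level at most `alpha`, whatever `t`. Writing the level as
`alpha + integral of G(z) phi(z) over z >= t` shows the level equals `alpha`
at `t = ±Inf` (both degenerate rules are fixed designs), decreases in `t`
while `G(t) > 0`, and increases after; its *minimum* is at the bound. The
surplus below the bound and the deficit above it cancel exactly over the
whole line. Unconditional inflation therefore requires raising *selectively*
inside the positive-`G` region — for instance a "band" policy that raises on
mediocre interims but not on strong ones. The engine's rule set includes
`custom_band` precisely to exhibit this:

```{r band}
z_star <- d$z_alpha * bound_b(55, 110, 40)
exact_type1_by_quadrature(d, ssa_rule("derived_bound"))   # below 0.025
exact_type1_by_quadrature(d, ssa_rule("always_raise"))    # exactly 0.025
exact_type1_by_quadrature(d, ssa_rule("custom_band",
                                      custom_z = c(0.2, 0.9 * z_star)))  # above
```

`simulate_type1()` is the stochastic twin of the quadrature: it draws whole
trials (interim statistic, rule, post-interim increment) and must agree with
the exact level within Monte-Carlo error; the test suite enforces this for
every rule kind. Randomness discipline: all trial variables are drawn as
whole vectors in a fixed, documented order under a single `set.seed(seed)`,
making results reproducible and independent of vectorization details.

## Binomial endpoint

For a one-sample test of `p = p0` against `p > p0` the conditional argument
goes through exactly: given the interim count `k`, the final count is `k`
plus an independent `Bin(N - n, p0)` remainder, so

    G(r) = P(X_{N0+r-n} > q_{a,N0+r} - k) - P(X_{N0-n} > q_{a,N0} - k)

with exact binomial upper percentiles (`binomial_percentile()`; smallest `t`
with CDF at least `1 - alpha`, rejection strictly above — the only convention
keeping the fixed-size test at level `alpha`). Bars that fall outside the
remaining support clamp to tail probabilities 0 or 1 rather than erroring.
`g_binomial_exact()` computes this; `g_binomial_cf_approx()` replaces the
percentiles by their Cornish–Fisher approximations and the tails by normal
pivots, which is accurate from interim sizes of about 20 when
`min(n p0, n (1 - p0)) > 5` (violations warn, not error).

Solving "approximate `G <= 0`" for `k` gives the count-scale threshold of
`k_threshold()`:

    k > n p0 + gamma0 sigma0 (z_alpha^2 - 1) / 6 + third term.

The first term is the null expectation and the second (skewness) term is
negative exactly when `p0 > 0.5`. The third term is *positive*: algebra
reduces it to `sqrt(n) * b(q, V) * z_alpha * sigma0`, i.e. the count-scale
image of the normal-endpoint bound, sitting slightly below the
simple-criterion spread `n sigma0 z_alpha / sqrt(N0)` of
`simple_k_threshold()`. (The test suite verifies this identity to 1e-10.)

Because the threshold is calibrated on the smooth approximation while the
exact `G` moves in discrete jumps, the interim-averaged quantity
`sum_k G(k) P(X_n = k)` over the retained set is *usually* but not always
non-positive: for a minority of designs discreteness pushes it a few
thousandths above zero. The tests assert the defensible form (all averages
within +0.005, the majority non-positive, the across-design mean negative)
rather than a universal sign claim.

`binom_ssr_study()` packages the randomized-design study used to calibrate
expectations about these quantities: each iteration draws an interim size `n`
uniformly on the integers 20..100 (the smallest size where the normal
approximation is trusted, up to a typical phase-II scale), sets `N0 = 2n`
(interim at the halfway point) and `r = n` (raise by one more stage), draws
`p0` uniformly on `[5/n, 1 - 5/n]` (the rule-of-thumb validity region) and
`k ~ Bin(n, p0)`, retains iterations passing the chosen criterion, and
summarizes the exact `G` over the retained set. Both criteria consume the
identical stream under a common seed, so their comparison is a
common-random-numbers comparison: the simple criterion retains a subset
deeper in the promising region and its retained `G` is more negative — it is
the conservative rule. The study emulates *design heterogeneity*, not data
heterogeneity: within an iteration the binomial model is exact, so passing
these checks says nothing about, e.g., overdispersed real count data.

## Survival endpoint

Lifetimes are Weibull with survival `exp(-lam * y^beta)` and censoring is
`Exp(mu)` (set `mu = 0` to disable). Three ingredient functions feed the
Edgeworth expansion of the standardized product-limit estimator:
`surv_atrisk()` is `C(y) = exp(-mu y - lam y^beta)`, `surv_w1()` the
sub-distribution of observed events, and `surv_sigma1()` the accumulated
variance integrand `dW1 / C^2`. All quadratures run at absolute tolerance
1e-10 on the substituted scale `u = x^beta`, which removes the integrable
`x^(beta-1)` singularity at zero for `beta < 1`; the `beta = 1` closed forms
(`W1 = lam/(lam+mu) (1 - e^{-(lam+mu)y})`, `sigma1 = e^{lam z} - 1`) serve as
oracles in the tests. `surv_sigma1()` refuses evaluation where
`C(z) < 1e-8`: the variance ingredient grows like `1/C` and the expansion is
meaningless that deep into follow-up.

The skewness constant is implemented as

    kappa3_tilde(z) = ( -7.5 sigma1(z)^4 + integral_0^z C^{-3} dW1 ) / sigma1(z).

The defining expression is typographically ambiguous in its source — the
`sigma1^{-1}` prefix could plausibly bind only to the first summand, reading
`sigma1^{-1} - 7.5 sigma1^4 + integral`. The grouping adopted here keeps
`kappa3` a ratio of a cumulant-like bracket to the scale factor, which is the
only reading under which the correction term vanishes with the events (both
bracket terms go to zero as `z -> 0`, rather than diverging through the lone
`sigma1^{-1}`); the alternative grouping diverges at small `z` and was
rejected on those grounds. Neither reading is treated as verified original
intent; the choice is documented here and isolated in one function.

`surv_edgeworth_cdf()` carries a second documented discrepancy: the
expansion's polynomial appears in the literature both as
`kappa3 (x^2 - 1)` (`variant = "results"`, the default) and as
`kappa3 (x^2 - 1) + 3 sigma1` (`variant = "methods"`). The two differ by
exactly `phi(x) * 3 sigma1 / (6 sqrt(n))`; the flag makes the choice
explicit, and raw values leaving `[0, 1]` are clipped with a warning.

For decision-making at the interim the package follows the logrank route:
`logrank_z()` computes `T / sqrt(V)` from a risk/event table (CSV format
`time,r_A,r_C,o_A,o_C` via `read_logrank_table()`), with the hypergeometric
variance term handling ties within an event time; rows are keyed by distinct
event times. The resulting `z` feeds `ssa_decide()` unchanged. Subject-level
data aggregate via `build_logrank_table()`, and the test suite cross-checks
the statistic against an independent implementation
(`survival::survdiff()`). `simulate_remainder()` estimates conditional power
by simulating the post-interim cohort; an interim table enters through its
`T` and `V` contributions added to those of the simulated remainder — an
independent-increments treatment, appropriate because a summary table cannot
identify which interim subjects remain at risk. Time units are caller-defined
throughout.

## Numerical choices and problem sizes

* Boundary assertions on `G` use absolute tolerance 1e-9; all quantities are
  compositions of `pnorm` evaluations, well conditioned away from the tails.
* Quadratures: `stats::integrate`, relative/absolute tolerance 1e-10 (level
  integrals), 1e-10 absolute (survival ingredients).
* `r` is accepted as any positive real; the command-line interface validates
  integer raises unless `--allow-fractional-r` semantics are wanted, in which
  case fractional values pass straight through to `bound_b()` (the algebra
  nowhere needs integrality, and the small-`r` limit is of interest).
* Test problem sizes, chosen to make the suite complete in well under a
  minute while keeping Monte-Carlo bands meaningful: 1e4 random designs for
  the sandwich property, 1e3 quadrature designs for level preservation, 2e6
  null trials for the Monte-Carlo level check, 1e5 iterations for the
  randomized binomial study (the acceptance script runs the full 9e5), 3e3-4e3
  replicates for survival calibrations.
* Monte-Carlo acceptance bands are three binomial standard errors.

## Known limitations

* Unknown variance is not adjusted for: a t-statistic fed into the normal
  machinery is only approximately standard normal, and small-sample
  t-inflation is outside scope.
* No repeated interim looks, alpha-spending, combination tests or p-value
  adjustments: the design has exactly one pre-planned look and conventional
  final tests.
* No sample-size decrease rule.
* The binomial count threshold certifies the sign of the *approximate*
  conditional error change; the exact conditional change can be mildly
  positive for individual `(n, p0, k)` near the threshold.
* The survival module estimates conditional power by simulation or via the
  logrank normal approximation; no closed-form Weibull conditional power is
  claimed.
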