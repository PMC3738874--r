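# ssrzone

Promising-zone bounds for sample-size re-estimation in adaptive clinical
trials.

## The problem

A sample-size-adjustable (SSA) trial plans `N0` subjects, takes one
pre-planned interim look after `n` of them, and may then stop for futility,
continue as planned, or recruit `r` extra subjects. Raising the sample size
after an unblinded look is widely feared to inflate the one-sided type I
error rate, and the classical safe harbour — raise only when the conditional
power at the interim estimate is at least 50%, i.e.
`z ≥ z_α √(n/N0)` — is needlessly strict.

`ssrzone` implements the weaker, raise-dependent threshold

    z  ≥  z_α · b(q, V),        q = n/(N0+r),  V = (N0+r)/N0,

    b(q, V) = (√(1−q) − √(1−qV)) / (√(qV)·√(1−q) − √q·√(1−qV)),

below which raising by `r` cannot increase the conditional (hence the
unconditional) type I error rate. On the conditional power scale the
permitted zone reaches down to

    Φ( z_α (b/√(qV) − 1) / √(1−qV) ),

which is 50% only in the limit `r → 0` and drops well below it for sizeable
raises. The package is written for trial statisticians evaluating or
defending an SSA design: it covers normal endpoints exactly, a one-sample
binomial proportion both exactly and through Cornish–Fisher-corrected normal
approximations (including the interim *count* threshold `k*`), Weibull
survival endpoints with exponential censoring (Edgeworth-expansion
ingredients for the product-limit estimator plus the logrank interim
statistic), and a Monte-Carlo trial engine cross-validated against exact
quadrature of the conditional error function.

## Worked example

A trial plans `N0 = 110` subjects with an interim at `n = 55`, one-sided
`α = 0.025`, and contemplates a raise of `r = 40`:

```r
library(ssrzone)
d <- ssa_design(n = 55, N0 = 110, r = 40, alpha = 0.025)
ssa_thresholds(d)
#> b(q,V)              = 0.6593164
#> z threshold (raise) = 1.292236
#> simple threshold    = 1.385904
#> min cond. power     = 0.425699
```

Reading: the classical 50%-conditional-power rule would demand an interim
statistic of at least `1.385904`; for a raise of 40 subjects a statistic of
`1.292236` already suffices, corresponding to a conditional power of only
about 43%. An interim `z = 1.31` therefore permits the raise even though it
misses the classical bar:

```r
ssa_decide(1.31, d)
#> Interim decision: raise_permitted
#>   z = 1.31 reached the raising threshold z_alpha*b = 1.292236 (G(r) = -0.00058 <= 0)
```

The negative `G(r)` is the change in conditional type I error caused by the
raise — the raise is (slightly) conservative at this `z`. The same decision
is available from the shell:

```sh
Rscript inst/cli/ssrzone bound --n 55 --N0 110 --r 40 --alpha 0.025
Rscript inst/cli/ssrzone decide --z 1.31 --n 55 --N0 110 --r 40
```

For a binomial endpoint, `binom_ssr_study()` reruns the randomized-design
study of the exact conditional error change over designs retained by the
derived count threshold:

```r
binom_ssr_study(100000, "derived", seed = 1)
#> Binomial SSA study: 100000 sims, criterion = derived, alpha = 0.025, seed = 1
#>   retained 10392 (10.4%); G(r): median = -0.01331787, mean = -0.02631287
```

Retained medians and means are negative: among promising interims the raise
is conservative, and the `"simple"` criterion is more conservative still.

The methods vignette (`vignettes/promising-zone.Rmd`) derives the bound,
explains why *one-sided* threshold rules can never inflate the unconditional
level (the engine's band rule exists to show what does), and documents the
survival-module conventions.

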