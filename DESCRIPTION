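Package: ssrzone
Title: Promising-Zone Bounds for Sample-Size Re-Estimation in Adaptive Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for sample-size-adjustable (SSA) adaptive clinical
    trials with a single pre-planned interim look. Implements the relaxed
    promising-zone bound on the interim z-statistic below the classical
    50%-conditional-power rule under which raising the sample size still
    preserves the one-sided type I error rate, together with the conditional
    error and conditional power machinery for normal endpoints, exact and
    Cornish-Fisher-approximate conditional error changes for a one-sample
    binomial proportion, Edgeworth-expansion ingredients and the logrank
    interim statistic for Weibull survival endpoints with exponential
    censoring, and a Monte-Carlo engine that verifies unconditional type I
    error control of any deterministic raising rule against exact quadrature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
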