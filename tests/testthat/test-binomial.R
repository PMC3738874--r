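test_that("exact binomial percentile matches a brute-force CDF scan", {
  expect_identical(binomial_percentile(1, 0.5, 0.025), 1)
  # enumerate the full CDF independently
  for (m in c(5, 20, 37)) for (p0 in c(0.2, 0.5, 0.83)) {
    cdf <- cumsum(dbinom(0:m, m, p0))
    expect_identical(binomial_percentile(m, p0, 0.025),
                     as.numeric(min(which(cdf >= 0.975)) - 1L))
  }
  # the induced test "reject if X > t" has level at most alpha
  t <- binomial_percentile(40, 0.3, 0.05)
  expect_lte(1 - pbinom(t, 40, 0.3), 0.05)
  expect_gt(1 - pbinom(t - 1, 40, 0.3), 0.05)
})

test_that("Cornish-Fisher percentile has the stated closed form and accuracy", {
  # skewness term vanishes at p0 = 0.5
  expect_equal(cornish_fisher_percentile(80, 0.5, 0.025),
               80 * 0.5 + sqrt(80) * 0.5 * qnorm(0.975), tolerance = 1e-12)
  # hand-computed closed form
  za <- qnorm(0.975)
  g0 <- (1 - 2 * 0.2) / sqrt(0.16)
  expect_equal(cornish_fisher_percentile(50, 0.2, 0.025),
               50 * 0.2 + sqrt(50) * sqrt(0.16) *
                 (za + g0 * (za^2 - 1) / (6 * sqrt(50))),
               tolerance = 1e-12)
  # within one count of the exact percentile across the rule-of-thumb grid
  grid <- expand.grid(m = seq(20, 200, by = 3),
                      p0 = seq(0.05, 0.95, by = 0.05))
  grid <- grid[pmin(grid$m * grid$p0, grid$m * (1 - grid$p0)) > 5, ]
  dev <- abs(cornish_fisher_percentile(grid$m, grid$p0, 0.025) -
               binomial_percentile(grid$m, grid$p0, 0.025))
  expect_lt(max(dev), 1)
  # rule-of-thumb violation warns rather than errors
  expect_warning(cornish_fisher_percentile(10, 0.1, 0.025), "inaccurate")
})

test_that("exact conditional error change matches full enumeration", {
  # every design with a raised total of at most 40, selected interim counts
  designs <- expand.grid(N = 6:40, N0 = 3:39, n = 1:38)
  designs <- designs[designs$n < designs$N0 & designs$N0 < designs$N, ]
  set.seed(19)
  designs <- designs[sample(nrow(designs), 400), ]
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    p0 <- c(0.25, 0.5, 0.8)[1 + i %% 3]
    bd <- binomial_design(p0, d$n, d$N0, d$N - d$N0)
    for (k in unique(c(0, floor(d$n / 2), d$n))) {
      expect_lt(abs(g_binomial_exact(k, bd) -
                      g_binomial_oracle(k, d$n, d$N0, d$N - d$N0, p0, 0.025)),
                1e-12)
    }
  }
  # full k range on a small design
  bd <- binomial_design(0.5, 5, 10, 5, 0.025)
  for (k in 0:5)
    expect_lt(abs(g_binomial_exact(k, bd) -
                    g_binomial_oracle(k, 5, 10, 5, 0.5, 0.025)),
              1e-12)
})

test_that("conditional tails via the shifted remainder match joint ratios", {
  # P(X_N0 > t | X_n = k) as a ratio of joint probabilities, fully enumerated
  n <- 4; N0 <- 9; p0 <- 0.35; k <- 3; t <- 5
  joint <- sum(dbinom(k, n, p0) * dbinom((t - k + 1):(N0 - n), N0 - n, p0))
  cond_ratio <- joint / dbinom(k, n, p0)
  expect_equal(1 - pbinom(t - k, N0 - n, p0), cond_ratio, tolerance = 1e-12)
})

test_that("degenerate bars clamp to empty or certain tails", {
  # bars beyond the remaining sample sizes give G = 0 through empty events
  bd <- binomial_design(0.5, 5, 10, 5, alpha = 1e-4)
  expect_equal(g_binomial_exact(0, bd), 0, tolerance = 1e-15)
  # huge interim counts make both tails certain, G = 0 again
  bd2 <- binomial_design(0.5, 30, 35, 5)
  expect_equal(g_binomial_exact(30, bd2), 0, tolerance = 1e-12)
  expect_error(g_binomial_exact(31, bd2), "0..n")
})

test_that("Cornish-Fisher approximation tracks the exact sign", {
  set.seed(23)
  n_designs <- 1000
  n <- sample(20:100, n_designs, replace = TRUE)
  agree <- logical(n_designs)
  for (i in seq_len(n_designs)) {
    p0 <- runif(1, 5 / n[i] + 0.01, 1 - 5 / n[i] - 0.01)
    bd <- binomial_design(p0, n[i], 2 * n[i], n[i])
    k <- rbinom(1, n[i], p0)
    ge <- g_binomial_exact(k, bd)
    gc <- g_binomial_cf_approx(k, bd)
    agree[i] <- sign(ge) == sign(gc) || abs(ge) < 1e-3 || abs(gc) < 1e-3
  }
  expect_gte(mean(agree), 0.95)
})

test_that("count threshold decomposes as stated and controls the CF sign", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(20:100, 1)
    N0 <- 2 * n
    r <- n
    p0 <- runif(1, 5 / n + 0.01, 1 - 5 / n - 0.01)
    bd <- binomial_design(p0, n, N0, r)
    tm <- k_threshold(bd, terms = TRUE)
    expect_equal(tm$term_null, n * p0, tolerance = 1e-12)
    # skewness term is negative exactly when p0 > 0.5
    expect_identical(tm$term_skew < 0, p0 > 0.5)
    # third term is positive: the count-scale image of the z bound,
    # sqrt(n) * b * z_alpha * sigma0
    expect_gt(tm$term_bound, 0)
    expect_equal(tm$term_bound,
                 sqrt(n) * bound_b(n, N0, r) * qnorm(0.975) * bd$sigma0,
                 tolerance = 1e-10)
    # above the threshold the CF-approximated change is non-positive
    k_lo <- ceiling(tm$threshold + 1e-9)
    if (k_lo <= n)
      expect_true(all(g_binomial_cf_approx(k_lo:n, bd) <= 1e-12))
  }
  # exact zero of the skewness term at p0 = 0.5
  expect_equal(k_threshold(binomial_design(0.5, 30, 60, 30), terms = TRUE)$term_skew,
               0, tolerance = 1e-15)
})

test_that("simple count threshold is the score criterion in disguise", {
  bd <- binomial_design(0.5, 55, 110, 55)
  expect_equal(simple_k_threshold(bd),
               55 * 0.5 + 55 * 0.5 * qnorm(0.975) / sqrt(110),
               tolerance = 1e-12)
  # score statistic at the threshold equals z_alpha * sqrt(n/N0)
  k <- simple_k_threshold(bd)
  z <- sqrt(55) * (k / 55 - 0.5) / 0.5
  expect_equal(z, qnorm(0.975) * sqrt(55 / 110), tolerance = 1e-12)
  # normal-theory conditional power at this score is exactly 50%
  expect_equal(conditional_power(z, 55, 110, 0.025), 0.5, tolerance = 1e-12)
})

test_that("interim score and log-odds statistics behave", {
  s <- interim_score_statistics(25, 50, 0.5)
  expect_equal(s$score, 0)
  expect_equal(s$log_odds, 0)
  expect_equal(interim_score_statistics(30, 50, 0.5)$score,
               sqrt(50) * 0.1 / 0.5, tolerance = 1e-12)
  # same sign everywhere in the interior
  for (k in 1:19) {
    s <- interim_score_statistics(k, 20, 0.35)
    expect_true(sign(s$score) == sign(s$log_odds) ||
                  (s$score == 0 && s$log_odds == 0))
  }
  expect_error(interim_score_statistics(0, 20, 0.35), "log-odds")
  expect_silent(interim_score_statistics(0, 20, 0.35, statistic = "score"))
})

test_that("raising zone approximately preserves the error rate on average", {
  # sum of G(k) P(X_n = k) over retained k: the threshold is calibrated on
  # the Cornish-Fisher approximation, so discreteness can push the exact
  # average slightly positive for individual designs; it stays within a small
  # approximation allowance and is non-positive for the clear majority
  set.seed(31)
  avgs <- vapply(1:50, function(i) {
    n <- sample(25:80, 1)
    p0 <- runif(1, 6 / n, 1 - 6 / n)
    bd <- binomial_design(p0, n, 2 * n, n)
    k_lo <- ceiling(k_threshold(bd) + 1e-9)
    if (k_lo > n) return(0)
    ks <- k_lo:n
    sum(g_binomial_exact(ks, bd) * dbinom(ks, n, p0))
  }, numeric(1))
  expect_true(all(avgs <= 0.005))
  expect_gte(mean(avgs <= 1e-10), 0.75)
  expect_lt(mean(avgs), 0)
})

test_that("the replication study is reproducible and orders the criteria", {
  a <- binom_ssr_study(20000, "derived", seed = 101L)
  b <- binom_ssr_study(20000, "derived", seed = 101L)
  expect_identical(a$median, b$median)
  expect_identical(a$n_retained, b$n_retained)
  s <- binom_ssr_study(20000, "simple", seed = 101L)
  # the simple criterion retains a subset deeper in the promising region,
  # hence more conservative (more negative) average G
  expect_lt(s$mean, a$mean)
  expect_lt(a$mean, 0)
  expect_lt(s$n_retained, a$n_retained)
  expect_error(binom_ssr_study(100), "at least 1000")
})
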