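test_that("ICC(A,1) matches the ANOVA oracle and its edge cases", {
  # perfect agreement
  p1 <- observer_pairs(1:6, c(1, 3, 5, 7, 9, 11), c(1, 3, 5, 7, 9, 11))
  r1 <- icc_absolute_agreement(p1)
  expect_equal(r1$icc, 1)
  expect_equal(r1$icc_ci, c(1, 1))

  # small 6-subject table equals the brute-force mean-squares oracle
  set.seed(101)
  x <- matrix(rnorm(12, 50, 10), 6, 2)
  r <- icc_absolute_agreement(observer_pairs(1:6, x[, 1], x[, 2]))
  expect_equal(r$icc, oracle_icc_a1(x), tolerance = 1e-12)
  expect_gte(r$icc, r$icc_ci[1])
  expect_lte(r$icc, r$icc_ci[2])

  # independent raters: ICC near 0 at large n
  set.seed(202)
  big <- observer_pairs(1:10000, rnorm(10000), rnorm(10000))
  expect_lt(abs(icc_absolute_agreement(big)$icc), 0.05)

  # degenerate all-identical table: ICC 1 by convention, with a warning
  expect_warning(
    rdeg <- icc_absolute_agreement(observer_pairs(1:4, rep(5, 4), rep(5, 4))),
    "convention")
  expect_equal(rdeg$icc, 1)

  expect_error(icc_absolute_agreement(observer_pairs(1:2, 1:2, 2:3)),
               class = "neckct_sample_error")
})

test_that("ICC equals the oracle on random small tables (property)", {
  set.seed(303)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(2 * n, 100, 25), n, 2)
    x[, 2] <- x[, 1] * runif(1, 0.5, 1.5) + rnorm(n, 0, runif(1, 0.1, 20))
    r <- icc_absolute_agreement(observer_pairs(1:n, x[, 1], x[, 2]))
    expect_equal(r$icc, oracle_icc_a1(x), tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias, limits and fixed-bias test behave", {
  # identical observers: bias 0, p 1 by the zero-variance convention
  p0 <- observer_pairs(1:5, 1:5, 1:5)
  r0 <- bland_altman(p0)
  expect_equal(r0$bias, 0)
  expect_equal(r0$fixed_bias_p, 1)

  # constant offset: degenerate SD collapses the limits onto the bias
  pc <- observer_pairs(1:5, c(10, 20, 30, 40, 50) + 5, c(10, 20, 30, 40, 50))
  rc <- bland_altman(pc)
  expect_equal(rc$bias, 5)
  expect_equal(rc$loa, c(5, 5))
  expect_equal(rc$fixed_bias_p, 0)

  # simulated differences around the reference bias of 4.17 cc (SD 13.35):
  # the recovered bias must sit inside its own t-based CI around 4.17
  pairs <- simulate_observer_pairs(rnorm(70, 660, 266), bias = 4.17,
                                   diff_sd = 13.35, seed = 10)
  r <- bland_altman(pairs)
  half <- qt(0.975, 69) * r$bias_sd / sqrt(70)
  expect_lt(abs(r$bias - 4.17), half)
  expect_equal(r$loa, r$bias + c(-1, 1) * 1.96 * r$bias_sd)
  expect_error(bland_altman(observer_pairs(1, 1, 2)),
               class = "neckct_sample_error")
})

test_that("Bland-Altman limits contain ~95% of normal differences", {
  pairs <- simulate_observer_pairs(rnorm(10000, 660, 266), seed = 4)
  r <- bland_altman(pairs)
  d <- pairs$obs1 - pairs$obs2
  frac <- mean(d >= r$loa[1] & d <= r$loa[2])
  expect_gt(frac, 0.94)
  expect_lt(frac, 0.96)
})

test_that("Spearman correlation matches the midrank oracle", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_rho(1:10, (1:10)^2)$p, 0)

  # 8-point table with a tie equals brute-force Pearson on midranks
  x <- c(1, 2, 2, 3, 5, 6, 7, 9)
  y <- c(2, 1, 4, 3, 7, 6, 6, 10)
  r <- spearman_rho(x, y)
  o <- oracle_spearman(x, y)
  expect_equal(r$rho, o$rho, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "neckct_degenerate_error")
})

test_that("BMI categorization uses right-open WHO cutoffs 25/30", {
  expect_equal(as.character(bmi_category(c(24.9, 25, 29.999, 30, 41))),
               c("normal_or_under", "overweight", "overweight",
                 "obese", "obese"))
  expect_error(bmi_category(c(22, -1)))
})

test_that("group_compare: Mann-Whitney exact and asymptotic paths", {
  # no overlap, n = 5 each: U = 0, exact p = 2/252
  r <- group_compare(c(1:5, 6:10), rep(c("a", "b"), each = 5))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)

  # identical distributions: statistic at its null mean, p = 1
  r2 <- group_compare(c(1:4, 1:4), rep(c("a", "b"), each = 4))
  expect_equal(r2$statistic, 8)   # n1 n2 / 2
  expect_equal(r2$p, 1)

  # oracle comparison with ties (asymptotic path)
  set.seed(77)
  x <- sample(1:6, 12, replace = TRUE)
  y <- sample(2:8, 15, replace = TRUE)
  r3 <- group_compare(c(x, y), rep(c("a", "b"), c(12, 15)))
  o <- oracle_mann_whitney(x, y)
  expect_equal(r3$statistic, o$u)
  expect_equal(r3$p, o$asym_p, tolerance = 1e-12)

  expect_error(group_compare(1:5, rep("a", 5)),
               class = "neckct_input_error")
})

test_that("group_compare: Kruskal-Wallis equals the rank-sum oracle", {
  vals <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- group_compare(vals, g)
  expect_equal(r$method, "kruskal_wallis")
  expect_equal(r$statistic, oracle_kruskal(vals, g), tolerance = 1e-12)

  # identical values in each group -> statistic 0, p 1
  r0 <- group_compare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
})

test_that("top_quartile_split follows the type-7 quantile convention", {
  s <- top_quartile_split(1:8)
  expect_equal(s$threshold, 6.25)
  expect_equal(which(s$labels == "upper_quartile"), c(7L, 8L))

  expect_warning(s2 <- top_quartile_split(rep(3, 6)), "upper")
  expect_true(all(s2$labels == "upper_quartile"))

  # 519 continuous ratios: counting under the rule gives 129 or 130
  set.seed(88)
  s3 <- top_quartile_split(rlnorm(519, 3.4, 0.5))
  expect_true(sum(s3$labels == "upper_quartile") %in% c(129L, 130L))

  expect_error(top_quartile_split(1:3), class = "neckct_sample_error")
})

test_that("log-rank equals the observed-minus-expected oracle", {
  # hand-computable 6-subject table
  times <- c(2, 4, 4, 6, 8, 10)
  events <- c(1, 1, 0, 1, 1, 0)
  groups <- c("a", "b", "a", "b", "a", "b")
  r <- km_logrank(times, events, groups)
  expect_equal(r$chisq, oracle_logrank(times, events, groups),
               tolerance = 1e-10)

  # identical groups: statistic 0, p 1 (duplicate each subject into both)
  t2 <- rep(times, 2); e2 <- rep(events, 2)
  g2 <- rep(c("a", "b"), each = 6)
  r2 <- km_logrank(t2, e2, g2)
  expect_equal(r2$chisq, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-10)
  # invariant under relabeling
  r2b <- km_logrank(t2, e2, rev(g2))
  expect_equal(r2b$chisq, r2$chisq, tolerance = 1e-12)

  # single group all censored: survival constant at 1
  fit <- survival::survfit(survival::Surv(c(5, 6, 7), c(0, 0, 0)) ~ 1)
  expect_true(all(fit$surv == 1))

  expect_error(km_logrank(times, rep(0, 6), groups),
               class = "neckct_degenerate_error")
})

test_that("Cox regression: null coverage, closed form, and scaling", {
  # null: independent covariate, hr near 1
  d0 <- simulate_survival_data(2000, beta = 0, event_frac = 0.4, seed = 5)
  f0 <- cox_univariate(d0$time, d0$event, d0$x)
  expect_gt(f0$hr, 0.9); expect_lt(f0$hr, 1.1)
  expect_gte(f0$hr, f0$hr_ci[1]); expect_lte(f0$hr, f0$hr_ci[2])

  # two-subject, one-event: partial likelihood at beta equals the
  # closed-form single-risk-set expression beta - log(1 + e^beta)
  tt <- c(1, 2); ee <- c(1, 0); xx <- c(1, 0)
  for (b in c(-0.5, 0, 0.8)) {
    ll <- survival::coxph(survival::Surv(tt, ee) ~ xx, ties = "breslow",
                          init = b,
                          control = survival::coxph.control(iter.max = 0))
    expect_equal(ll$loglik[2], b - log(1 + exp(b)), tolerance = 1e-12)
    expect_equal(ll$loglik[2], oracle_cox_loglik(b, tt, ee, xx),
                 tolerance = 1e-12)
  }

  # parameter recovery at the reference design
  d1 <- simulate_survival_data(1000, beta = 0.7, event_frac = 0.4, seed = 6)
  f1 <- cox_univariate(d1$time, d1$event, d1$x)
  expect_lt(abs(f1$beta - 0.7), 0.15)

  # covariate scaling: beta scales by 1/c, per-unit hr consistent
  f2 <- cox_univariate(d1$time, d1$event, d1$x * 10)
  expect_equal(f2$beta * 10, f1$beta, tolerance = 1e-6)

  expect_error(cox_univariate(d1$time, d1$event, rep(1, 1000)),
               class = "neckct_input_error")
  expect_error(cox_univariate(d1$time, rep(0, 1000), d1$x),
               class = "neckct_degenerate_error")
})

test_that("ICC sample size: reference inputs, monotonicity in width and k", {
  r <- icc_sample_size(0.9, 0.1, 2)
  expect_equal(r$n, 57L)          # Bonett approximation at the inputs
  expect_equal(r$method, "bonett2002_expected_width")
  expect_lte(icc_sample_size(0.9, 0.2, 2)$n, r$n)
  expect_lte(icc_sample_size(0.9, 0.1, 3)$n, r$n)
  # wider grid of monotone checks
  ns <- vapply(seq(0.05, 0.3, by = 0.05),
               function(w) icc_sample_size(0.8, w, 2)$n, 1L)
  expect_true(all(diff(ns) <= 0))
  expect_error(icc_sample_size(1, 0.1, 2), class = "neckct_domain_error")
  expect_error(icc_sample_size(0.9, 0, 2), class = "neckct_domain_error")
})
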