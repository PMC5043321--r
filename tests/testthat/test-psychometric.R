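test_that("psi has the correct asymptotes and midpoint", {
  expect_equal(psi(-1e6, a = 3, b = 0.8, gamma = 0.5, lapse = 0.1), 0.5)
  expect_equal(psi(1e6, a = 3, b = 0.8, gamma = 0.5, lapse = 0.1), 0.9)
  expect_equal(psi(3, a = 3, b = 0.8, gamma = 0.5, lapse = 0.1),
               0.5 + (1 - 0.5 - 0.1) / 2)
  expect_error(psi(0, a = 1, b = -1), "positive")
})

test_that("binomial criterion reproduces exact one-tailed tail bounds", {
  c30 <- binomial_criterion(30, 0.5, 0.05)
  expect_identical(c30$k_min, 20L)
  expect_equal(c30$proportion, 20 / 30)
  # exact tail sums: P(X>=9 | 10, .5) = 11/1024 < .05, P(X>=8) ~ .0547 >= .05
  c10 <- binomial_criterion(10, 0.5, 0.05)
  expect_identical(c10$k_min, 9L)
  expect_error(binomial_criterion(1, 0.5, 0.05), "unattainable")
})

test_that("threshold_from_fit inverts psi in closed form", {
  fit <- list(a = 3, b = 0.8, gamma = 0.5, lapse = 0)
  expect_equal(threshold_from_fit(fit, 0.75), 3)          # logistic midpoint
  x23 <- threshold_from_fit(fit, 2 / 3)
  expect_equal(x23, 3 - 0.8 * log(2), tolerance = 1e-12)
  # mutual inverses
  for (crit in c(0.55, 2 / 3, 0.8, 0.95)) {
    xs <- threshold_from_fit(fit, crit)
    expect_equal(psi(xs, fit$a, fit$b, fit$gamma, fit$lapse), crit,
                 tolerance = 1e-10)
  }
  # criterion monotone in level
  expect_gt(threshold_from_fit(fit, 0.7), threshold_from_fit(fit, 0.6))
  expect_error(threshold_from_fit(list(a = 3, b = 0.8, gamma = 0.5, lapse = 0.2),
                                  0.9), "unattainable")
})

test_that("noise-free data on the curve are recovered to numerical precision", {
  a <- 3; b <- 0.8
  p <- c(0.55, 0.6, 0.7, 0.8, 0.9, 0.95)
  x <- a - b * log(0.5 / (p - 0.5) - 1)
  d <- data.frame(level = x, n_trials = 60, n_correct = as.integer(60 * p))
  fit <- fit_psychometric(d)
  expect_true(fit$converged)
  expect_equal(psi(x, fit$a, fit$b, fit$gamma, fit$lapse), p, tolerance = 1e-6)
})

test_that("degenerate chance-level data yield no fabricated threshold", {
  d <- data.frame(level = c(1, 2, 3, 4, 5, 6), n_trials = 30, n_correct = 15)
  fit <- fit_psychometric(d)
  expect_false(fit$converged)
  expect_identical(fit$flag, "no_signal")
  expect_true(is.na(fit$threshold))
})

test_that("a ceiling observer gets the highest level as flagged threshold", {
  # only the top level is above chance (20/30 is the n=30 cut-off)
  d <- data.frame(level = c(0.1, 0.6, 2.1, 3.7, 5.2, 6.9), n_trials = 30,
                  n_correct = c(14, 16, 15, 17, 18, 26))
  fit <- fit_psychometric(d)
  expect_identical(fit$flag, "ceiling")
  expect_equal(fit$threshold, 6.9)
})

test_that("simulated observers are recovered without systematic threshold bias", {
  # default design: 6 levels x 30 trials, gamma 0.5, criterion 66.7%
  levels <- c(0.1, 0.6, 2.1, 3.7, 5.2, 6.9)
  obs <- simulated_observer(a = 3, b = 0.8, lapse = 0.05)
  crit <- binomial_criterion(30, 0.5, 0.05)$proportion
  true_thr <- threshold_from_fit(list(a = 3, b = 0.8, gamma = 0.5, lapse = 0.05),
                                 crit)
  thr <- rep(NA_real_, 500)
  for (i in seq_len(500)) {
    d <- simulate_session(obs, levels, 30, seed = 4000 + i)
    f <- fit_psychometric(d)
    if (!is.na(f$threshold)) thr[i] <- f$threshold
  }
  expect_gt(mean(!is.na(thr)), 0.9)
  expect_lt(abs(median(thr, na.rm = TRUE) - true_thr) / true_thr, 0.10)
})

test_that("widening the lapse bound never decreases the fitted likelihood", {
  levels <- c(0.1, 0.6, 2.1, 3.7, 5.2, 6.9)
  obs <- simulated_observer(a = 2.5, b = 0.6, lapse = 0.1)
  for (s in 1:5) {
    d <- simulate_session(obs, levels, 30, seed = 600 + s)
    ll_narrow <- fit_psychometric(d, lapse_max = 0.05)$loglik
    ll_wide <- fit_psychometric(d, lapse_max = 0.25)$loglik
    expect_gte(ll_wide, ll_narrow - 1e-6)
  }
})

test_that("rank-sum comparison is exact for small samples and symmetric", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  sep <- compare_conditions(c(1, 2, 3), c(10, 20, 30))
  expect_equal(sep$rank_sum, 6)          # minimal possible rank sum
  expect_equal(sep$p_value, 2 / 20)      # 2 of the 20 assignments as extreme

  ab <- compare_conditions(c(1.2, 3.4, 2.2), c(1.9, 4.1, 0.3))
  ba <- compare_conditions(c(1.9, 4.1, 0.3), c(1.2, 3.4, 2.2))
  expect_equal(ab$p_value, ba$p_value)

  # agreement with the reference implementation when no ties (exact branch)
  set.seed(11)
  for (i in 1:20) {
    x <- round(runif(4), 3); y <- round(runif(5) + 0.2, 3)
    ours <- compare_conditions(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})

test_that("per-trial rows aggregate to level counts", {
  raw <- data.frame(level = rep(c(1, 2), each = 4),
                    choice_correct = c(1, 0, 1, 1, 1, 1, 1, 0))
  agg <- aggregate_trials(raw)
  expect_equal(agg$n_trials, c(4, 4))
  expect_equal(agg$n_correct, c(3, 3))
  expect_error(aggregate_trials(data.frame(level = 1, n_trials = 2, n_correct = 5)),
               "between")
})
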