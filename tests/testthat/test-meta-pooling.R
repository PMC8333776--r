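# Inverse-variance pooling of trial risk ratios.

test_that("log-scale SE reconstruction from a 95% CI matches the closed form", {
  z <- qnorm(0.975)
  expect_equal(log_se_from_ci(1, exp(-z), exp(z)), 1)
  expect_equal(log_se_from_ci(1, 0.5, 2), log(4) / (2 * z))
  expect_equal(round(log_se_from_ci(1, 0.5, 2), 4), 0.3537)
  # the VITAL row: RR 0.83 (0.67-1.02)
  expect_equal(round(log_se_from_ci(0.83, 0.67, 1.02), 4), 0.1072)
})

test_that("invalid CI bounds are rejected with the trial named", {
  expect_error(log_se_from_ci(0.9, 1.0, 0.8, study = "BadTrial"),
               "BadTrial", class = "preventyll_invalid_input")
  expect_error(trial_effects("NegTrial", 0.9, -0.1, 1.2),
               "NegTrial", class = "preventyll_invalid_input")
  expect_error(trial_effects(character(0), numeric(0), numeric(0), numeric(0)),
               class = "preventyll_invalid_input")
  expect_error(pool_random_dl(trial_effects("solo", 0.83, 0.67, 1.02)),
               class = "preventyll_invalid_input")
})

test_that("fixed-effect pooling obeys singleton and equal-weight algebra", {
  solo <- pool_fixed(trial_effects("solo", 0.83, 0.67, 1.02))
  expect_equal(solo$rr, 0.83, tolerance = 0.005)
  expect_equal(solo$ci_lower, 0.67, tolerance = 0.005)
  expect_equal(solo$ci_upper, 1.02, tolerance = 0.005)
  expect_equal(sum(solo$weights), 1)

  twin <- pool_fixed(trial_effects(c("a", "b"), c(0.83, 0.83),
                                   c(0.67, 0.67), c(1.02, 1.02)))
  expect_equal(twin$log_rr, solo$log_rr)
  expect_equal(twin$se_log, solo$se_log / sqrt(2))
  expect_equal(unname(twin$weights), c(0.5, 0.5))
})

test_that("the five-trial set is homogeneous: Q below df, tau^2 truncated at 0", {
  fx <- pool_fixed(keum_trials())
  dl <- pool_random_dl(keum_trials())
  expect_lt(fx$q_statistic, 4)
  expect_equal(dl$q_statistic, fx$q_statistic)
  expect_identical(dl$tau_squared, 0)
  # with tau^2 = 0 the two estimators coincide entirely
  expect_equal(dl$log_rr, fx$log_rr)
  expect_equal(dl$se_log, fx$se_log)
  expect_equal(dl$ci_lower, fx$ci_lower)
  expect_equal(dl$ci_upper, fx$ci_upper)
})

test_that("random-effects pooling of the five trials reproduces the published effect", {
  dl <- pool_random_dl(keum_trials())
  expect_equal(round(dl$rr, 2), 0.87)
  expect_equal(round(dl$ci_lower, 2), 0.79)
  expect_equal(round(dl$ci_upper, 2), 0.96)
  red <- reduction_percent(dl)
  expect_equal(unname(red$rounded), c(13, 4, 21))
})

test_that("two identical trials pool to their common RR with no heterogeneity", {
  dl <- pool_random_dl(trial_effects(c("a", "b"), c(0.9, 0.9),
                                     c(0.8, 0.8), c(1.05, 1.05)))
  expect_equal(dl$rr, 0.9)
  expect_identical(dl$tau_squared, 0)
})

test_that("reduction_percent converts RR scale to percent-reduction scale", {
  null <- pool_fixed(trial_effects("null", 1, exp(-0.1), exp(0.1)))
  expect_equal(reduction_percent(null)$point, 0)
  dl <- pool_random_dl(keum_trials())
  red <- reduction_percent(dl)
  expect_equal(red$point, 100 * (1 - dl$rr))
  expect_equal(red$upper, 100 * (1 - dl$ci_lower))
  expect_equal(red$lower, 100 * (1 - dl$ci_upper))
})

test_that("pooling matches the brute-force oracle on random trial sets", {
  set.seed(4821)
  for (rep in 1:100) {
    tr <- random_trials(sample(2:10, 1))
    for (m in c("fixed", "random")) {
      got <- if (m == "fixed") pool_fixed(tr) else pool_random_dl(tr)
      ref <- oracle_pool(tr$rr, tr$ci_lower, tr$ci_upper, m)
      expect_equal(got$log_rr, ref$log_rr, tolerance = 1e-10)
      expect_equal(got$se_log, ref$se_log, tolerance = 1e-10)
      expect_equal(got$tau_squared, ref$tau2, tolerance = 1e-10)
      expect_equal(got$q_statistic, ref$q, tolerance = 1e-10)
    }
  }
})

test_that("pooled log-RR is a convex combination of trial log-RRs", {
  set.seed(77)
  for (rep in 1:25) {
    tr <- random_trials(sample(2:8, 1))
    for (p in list(pool_fixed(tr), pool_random_dl(tr))) {
      expect_gte(p$log_rr, min(log(tr$rr)) - 1e-12)
      expect_lte(p$log_rr, max(log(tr$rr)) + 1e-12)
      expect_true(all(p$weights >= 0))
      expect_equal(sum(p$weights), 1, tolerance = 1e-9)
    }
  }
})

test_that("trial order never changes any pooled output", {
  set.seed(99)
  tr <- random_trials(6)
  perm <- sample(6)
  shuffled <- trial_effects(tr$study[perm], tr$rr[perm],
                            tr$ci_lower[perm], tr$ci_upper[perm])
  for (m in list(pool_fixed, pool_random_dl)) {
    a <- m(tr); b <- m(shuffled)
    expect_equal(a$log_rr, b$log_rr)
    expect_equal(a$se_log, b$se_log)
    expect_equal(a$tau_squared, b$tau_squared)
    expect_equal(a$q_statistic, b$q_statistic)
    expect_equal(a$weights[tr$study], b$weights[tr$study])
  }
})

test_that("DL pooling agrees with metafor as an independent implementation", {
  skip_if_not_installed("metafor")
  tr <- keum_trials()
  se <- log_se_from_ci(tr$rr, tr$ci_lower, tr$ci_upper)
  fit <- metafor::rma(yi = log(tr$rr), sei = se, method = "DL")
  dl <- pool_random_dl(tr)
  expect_equal(dl$log_rr, as.numeric(fit$beta), tolerance = 1e-8)
  expect_equal(dl$ci_lower, exp(fit$ci.lb), tolerance = 1e-6)
  expect_equal(dl$ci_upper, exp(fit$ci.ub), tolerance = 1e-6)
  expect_equal(dl$tau_squared, fit$tau2, tolerance = 1e-8)
})
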