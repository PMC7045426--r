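test_that("dichotomization uses a closed lower bound at the cutoff", {
  expect_identical(dichotomize_score(c(29, 30, 31), 30), c(0L, 1L, 1L))
  expect_identical(dichotomize_score(rep(10, 4), 30), rep(0L, 4L))
})

test_that("group tests reproduce pooled t and ANOVA F hand values", {
  covs <- data.frame(g = factor(rep(c("a", "b"), each = 3)))
  gt <- group_tests(c(1, 2, 3, 4, 5, 6), covs, "g")
  expect_equal(gt$tests$statistic, -3.674, tolerance = 1e-3)
  expect_identical(gt$tests$test, "t")
  expect_equal(gt$groups$mean, c(2, 5))

  # identical groups: t = 0
  gt0 <- group_tests(rep(c(1, 2, 3), 2), covs, "g")
  expect_equal(gt0$tests$statistic, 0)

  # for two groups F = t^2
  f <- anova(aov(c(1, 2, 3, 4, 5, 6) ~ covs$g))$`F value`[1]
  expect_equal(f, gt$tests$statistic^2, tolerance = 1e-10)

  # >2 levels gives F
  covs3 <- data.frame(g = factor(rep(c("a", "b", "c"), each = 3)))
  gt3 <- group_tests(c(1, 2, 3, 2, 3, 4, 6, 7, 8), covs3, "g")
  expect_identical(gt3$tests$test, "F")
  expect_error(group_tests(1:3, data.frame(g = factor(c("a", "a", "b"))),
                           "g"),
               "fewer than 2")
})

test_that("one-predictor logistic fits reproduce the closed-form 2x2 odds ratio", {
  # exposed: 10 events / 10 non-events; unexposed: 5 / 20 -> OR = 4 exactly
  outcome <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 20))
  covs <- data.frame(exposed = factor(c(rep("yes", 20), rep("no", 25)),
                                      levels = c("no", "yes")))
  fit <- fit_logistic(outcome, covs, "exposed")
  expect_equal(fit$coef$or, 4.0, tolerance = 1e-8)
  expect_true(fit$coef$ci_lower < 4 && fit$coef$ci_upper > 4)

  expect_error(fit_logistic(rep(1L, 20), covs[1:20, , drop = FALSE],
                            "exposed"),
               "both classes")
})

test_that("logistic estimates are consistent under a null predictor", {
  set.seed(12)
  n <- 100000
  covs <- data.frame(x = factor(sample(c("a", "b"), n, replace = TRUE)))
  outcome <- rbinom(n, 1, 0.4)
  fit <- fit_logistic(outcome, covs, "x")
  expect_lt(abs(fit$coef$estimate), 0.05)
  expect_false(fit$coef$significant)
})

test_that("pooled logistic degenerates correctly and never understates variance", {
  d <- rses_fixture(n = 600, seed = 71)
  amp <- ampute(d, missingness_plan("MCAR", 0.15, seed = 73))
  mi <- impute_mi(amp, m = 4, n_iter = 4, seed = 79)
  preds <- c("gender", "grade", "record", "residence", "communication")
  pooled <- pooled_logistic_mi(mi, preds)
  per_fit_se <- sapply(mi$items, function(it) {
    fit_logistic(dichotomize_score(total_score(it), 30), mi$covariates,
                 preds)$coef$se
  })
  expect_true(all(pooled$se >= rowMeans(per_fit_se^2)^0.5 - 1e-12))

  # m identical completed datasets: B = 0, pooled fit equals a single fit
  mi2 <- mi
  mi2$items <- list(mi$items[[1L]], mi$items[[1L]])
  pooled2 <- pooled_logistic_mi(mi2, preds)
  single <- fit_logistic(dichotomize_score(total_score(mi$items[[1L]]), 30),
                         mi$covariates, preds)
  expect_equal(pooled2$estimate, single$coef$estimate, tolerance = 1e-12)
  expect_equal(pooled2$or, single$coef$or, tolerance = 1e-12)
  expect_equal(pooled2$ci_lower, single$coef$ci_lower, tolerance = 1e-10)
  expect_true(all(is.infinite(pooled2$df)))
})

test_that("compare_analyses reports zero deltas for an identical arm", {
  d <- rses_fixture(n = 500, seed = 83)
  # an arm that is literally the complete data (no missingness to fill)
  amp <- ampute(d, missingness_plan("MCAR", 1e-12, seed = 89))
  arm <- impute_mode(amp)
  cmp <- compare_analyses(d, list(SAME = arm),
                          group_vars = c("gender", "record"),
                          predictors = c("gender", "grade", "record",
                                         "residence", "communication"))
  same <- cmp$descriptives[cmp$descriptives$arm == "SAME", ]
  expect_true(all(abs(same$delta_mean) < 1e-12))
  expect_true(all(abs(same$delta_sd) < 1e-12))
  ors <- cmp$odds_ratios[cmp$odds_ratios$arm == "SAME", ]
  expect_true(all(abs(ors$delta_log_or) < 1e-12))
  expect_true(all(ors$sign_agrees))
})
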