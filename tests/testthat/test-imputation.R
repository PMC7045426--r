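test_that("complete-case analysis keeps exactly the fully observed rows", {
  d <- make_survey(matrix(rep(1:4, length.out = 30), 10, 3),
                   covariates = data.frame(age = 1:10),
                   scale = tiny_scale())
  mask <- matrix(FALSE, 10, 3)
  expect_identical(complete_case(make_amputed(d, mask))$items[[1L]], d$items)

  mask[2, 1] <- mask[5, 3] <- mask[5, 2] <- mask[9, 2] <- TRUE # rows 2, 5, 9
  cc <- complete_case(make_amputed(d, mask))
  expect_identical(cc$provenance$kept_ids, c(1L, 3L, 4L, 6L, 7L, 8L, 10L))
  expect_identical(cc$items[[1L]], d$items[-c(2, 5, 9), ])
  expect_identical(cc$covariates$age, c(1L, 3L, 4L, 6L, 7L, 8L, 10L))

  expect_error(complete_case(make_amputed(d, matrix(TRUE, 10, 3))),
               "no respondent")
})

test_that("mode imputation fills the most frequent value with a low tie-break", {
  d <- make_survey(cbind(c(1L, 1L, 2L, 3L), c(1L, 1L, 2L, 2L),
                         c(4L, 4L, 4L, 1L)),
                   scale = tiny_scale())
  mask <- rbind(c(FALSE, FALSE, FALSE), c(FALSE, FALSE, FALSE),
                c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE))
  md <- impute_mode(make_amputed(d, mask))
  # col 1: observed {1,1,2} -> 1; col 2: tie {1,1,2,2} -> 1; col 3: {4,4,4} -> 4
  expect_identical(md$items[[1L]][4, ], c(item_01 = 1L, item_02 = 1L,
                                          item_03 = 4L))
  # observed cells bit-identical, and pure-function determinism
  expect_identical(md$items[[1L]][!mask], d$items[!mask])
  expect_identical(md$items[[1L]], impute_mode(make_amputed(d, mask))$items[[1L]])

  no_missing <- impute_mode(make_amputed(d, matrix(FALSE, 4, 3)))
  expect_identical(no_missing$items[[1L]], d$items)
})

test_that("hot-deck draws uniformly from the donor class and falls back when empty", {
  covs <- data.frame(gender = factor(c("male", "male", "male",
                                       "female", "female")))
  d <- make_survey(cbind(c(2L, 3L, 2L, 1L, 4L), c(1L, 1L, 1L, 1L, 1L)),
                   covariates = covs,
                   scale = tiny_scale(n_items = 2L))
  mask <- matrix(FALSE, 5, 2)
  mask[3, 1] <- TRUE # male row; male donors observed on item 1: {2, 3}
  draws <- vapply(1:2000, function(s) {
    impute_hotdeck(make_amputed(d, mask), "gender", seed = s)$items[[1L]][3, 1]
  }, integer(1L))
  expect_true(all(draws %in% c(2L, 3L)))
  expect_lt(abs(mean(draws == 2L) - 0.5), 0.04)

  # class with nothing observed on an item falls back to the global pool
  mask2 <- matrix(FALSE, 5, 2)
  mask2[4, 1] <- mask2[5, 1] <- TRUE # every female value of item 1 missing
  hd <- impute_hotdeck(make_amputed(d, mask2), "gender", seed = 1)
  expect_true(all(hd$items[[1L]][4:5, 1] %in% c(2L, 3L)))
  expect_identical(hd$provenance$fallback_pools_used, 1L)

  # identity without missingness
  hd0 <- impute_hotdeck(make_amputed(d, matrix(FALSE, 5, 2)), "gender",
                        seed = 1)
  expect_identical(hd0$items[[1L]], d$items)
})

test_that("multiple imputation preserves observed data and imputes donor values", {
  d <- rses_fixture(n = 300, seed = 17)
  amp <- ampute(d, missingness_plan("MCAR", 0.2, seed = 23))
  mi <- impute_mi(amp, m = 4, n_iter = 4, seed = 29)
  expect_length(mi$items, 4L)
  obs <- !amp$mask
  for (l in 1:4) {
    expect_identical(mi$items[[l]][obs], d$items[obs])
    expect_true(all(mi$items[[l]] >= 1L & mi$items[[l]] <= 4L))
    # donor origin: every imputed value is an observed value of its column
    for (j in seq_len(ncol(d$items))) {
      imputed <- mi$items[[l]][amp$mask[, j], j]
      expect_true(all(imputed %in% unique(d$items[obs[, j], j])))
    }
  }
  # between-imputation variability exists whenever cells were imputed
  per_imp_means <- vapply(mi$items, function(m) mean(rowSums(m)), numeric(1L))
  expect_gt(var(per_imp_means), 0)
  expect_error(impute_mi(amp, m = 1, seed = 1), "m >= 2")
})

test_that("all strategies coincide in the vanishing-missingness limit", {
  d <- rses_fixture(n = 10000, seed = 53)
  amp <- ampute(d, missingness_plan("MCAR", 1e-3, seed = 59))
  stats0 <- summary_statistics(d)
  for (method in c("deletion", "mode", "hotdeck", "mi")) {
    comp <- switch(method,
                   deletion = complete_case(amp),
                   mode = impute_mode(amp),
                   hotdeck = impute_hotdeck(amp, "gender", seed = 61),
                   mi = impute_mi(amp, m = 3, n_iter = 3, seed = 67))
    s <- summary_statistics(comp)
    expect_lt(abs(s[["mean"]] - stats0[["mean"]]), 0.05)
    expect_lt(abs(s[["sd"]] - stats0[["sd"]]), 0.05)
    expect_lt(abs(s[["corr"]] - stats0[["corr"]]), 0.02)
  }
})

test_that("Rubin pooling reproduces hand calculations and its algebra", {
  p <- rubins_pool(c(1, 3), c(1, 1))
  expect_equal(p$point, 2)
  expect_equal(p$within_var, 1)
  expect_equal(p$between_var, 2)
  expect_equal(p$total_var, 4) # 1 + 1.5 * 2

  degen <- rubins_pool(c(5, 5, 5), c(0.3, 0.3, 0.3))
  expect_equal(degen$point, 5)
  expect_equal(degen$between_var, 0)
  expect_equal(degen$total_var, 0.3)
  expect_identical(degen$df, Inf)

  set.seed(101)
  for (i in 1:25) {
    m <- sample(2:12, 1)
    q <- rnorm(m); u <- rexp(m)
    pp <- rubins_pool(q, u)
    expect_equal(pp$total_var,
                 pp$within_var + (1 + 1 / m) * pp$between_var)
    expect_gte(pp$total_var, pp$within_var)
    expect_equal(pp$point, mean(q))
  }
  expect_error(rubins_pool(1, 1), "at least 2")
  expect_error(rubins_pool(c(1, 2), c(1, -1)), "nonnegative")
})
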