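test_that("covariate generation honours the empty case, marginals and determinism", {
  gender <- covariate_spec("gender", "categorical",
                           levels = c("male", "female"),
                           probs = c(0.515, 0.485))
  age <- covariate_spec("age", "continuous", mean = 16.3, sd = 1.6)

  empty <- generate_covariates(list(gender, age), n = 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("gender", "age"))

  big <- generate_covariates(list(gender, age), n = 100000, seed = 42)
  expect_lt(abs(mean(big$gender == "male") - 0.515), 0.005)
  expect_lt(abs(mean(big$age) - 16.3), 0.05)

  expect_identical(generate_covariates(list(gender, age), n = 50, seed = 7),
                   generate_covariates(list(gender, age), n = 50, seed = 7))
  expect_error(generate_covariates(list(gender), n = -1, seed = 1),
               "nonnegative")
  expect_error(covariate_spec("g", "categorical", levels = c("a", "b"),
                              probs = c(0.6, 0.5)),
               "sum to 1")
})

test_that("zero-loading item marginals match the threshold-implied multinomial", {
  # with zero loadings the latent item response is standard normal, so the
  # closed-form cell probabilities are Phi differences at the thresholds
  sc <- tiny_scale(n_items = 4L)
  tau <- c(-1.0, 0.2, 1.1)
  params <- item_params(loadings = rep(0, 4L),
                        thresholds = matrix(rep(tau, each = 4L), nrow = 4L))
  covs <- data.frame(age = rnorm(100000))
  cov_spec <- list(covariate_spec("age", "continuous", mean = 0, sd = 1))
  d <- generate_item_responses(covs, sc, params, seed = 99, specs = cov_spec)
  p_expected <- diff(c(0, pnorm(tau), 1))
  for (j in 1:4) {
    counts <- tabulate(d$items[, j], nbins = 4L)
    gof <- chisq.test(counts, p = p_expected)
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("generated items stay in range and respond to covariate effects", {
  d <- rses_fixture(n = 50000, seed = 21)
  expect_true(all(d$items >= 1L & d$items <= 4L))
  expect_false(anyNA(d$items))
  # record has a negative per-level effect: excellent students score higher
  tot <- total_score(d)
  m <- tapply(tot, d$covariates$record, mean)
  expect_gt(m[["excellent"]], m[["average"]])
  expect_gt(m[["average"]], m[["poor"]])
  # males load higher on the trait than females
  expect_gt(mean(tot[d$covariates$gender == "male"]),
            mean(tot[d$covariates$gender == "female"]))
})

test_that("the RSES-like population hits its calibration targets", {
  d <- rses_fixture(n = 3513, seed = 2020)
  tot <- total_score(d)
  expect_lt(abs(mean(tot) - 28.22), 0.5)
  expect_lt(abs(sd(tot) - 4.63), 0.5)
})

test_that("survey generation is reproducible and handles boundaries", {
  pop <- saq_population()
  a <- generate_survey(pop$scale, pop$covariates, pop$items, n = 80, seed = 5)
  b <- generate_survey(pop$scale, pop$covariates, pop$items, n = 80, seed = 5)
  expect_identical(a$items, b$items)
  expect_identical(a$covariates, b$covariates)
  one <- generate_survey(pop$scale, pop$covariates, pop$items, n = 1, seed = 5)
  expect_identical(nrow(one$items), 1L)
  expect_true(all(one$items >= 1L & one$items <= 4L))
  expect_error(item_params(loadings = c(1, 1),
                           thresholds = rbind(c(0, -1, 1), c(-1, 0, 1))),
               "strictly increasing")
})

test_that("total scores sum items and refuse missing cells", {
  d <- make_survey(rbind(rep(1L, 10), rep(4L, 10),
                         c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 1L, 2L)))
  expect_equal(total_score(d), c(10, 40, 23))
  d$items[2, 5] <- NA_integer_
  expect_error(total_score(d), "impute or delete")
})
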