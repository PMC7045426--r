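test_that("configuration validation rejects malformed runs", {
  expect_error(run_config("saq", rates = c(0.1, 1.2)), "between 0 and 1")
  expect_error(run_config("saq", rates = c(0.1, 0.1)), "unique")
  expect_error(run_config("saq", methods = character(0)), "non-empty")
  expect_error(run_config("saq", methods = "median"), "subset")
  expect_error(run_config("saq", n_reps = 0), "at least 1")
})

test_that("configurations round-trip through YAML", {
  cfg <- run_config("rses", n = 321, rates = c(0.05, 0.2), n_reps = 3,
                    mi_m = 4, master_seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back$rates, cfg$rates)
  expect_identical(back$n, cfg$n)
  expect_identical(back$master_seed, cfg$master_seed)
  expect_equal(back$mar_drivers, cfg$mar_drivers)
  expect_equal(back$population$scale$cutoff, 30L)
  expect_equal(back$population$items$thresholds,
               cfg$population$items$thresholds, ignore_attr = TRUE)
  # serialize -> parse -> serialize is idempotent
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the simulation tier writes its artifacts deterministically", {
  cfg <- run_config("saq", n = 120, rates = 0.1, n_reps = 2,
                    methods = c("deletion", "mode"), master_seed = 17)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  b <- run_simulation_tier(cfg, out1)
  expect_s3_class(b, "imputation_benchmark")
  files <- c("dataset.csv", "benchmark.csv", "evaluation_table.csv",
             "config.yaml", "manifest.yaml")
  expect_true(all(file.exists(file.path(out1, files))))
  run_simulation_tier(cfg, out2)
  for (f in setdiff(files, "manifest.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
  # stored records re-summarize to the same table
  tab <- recompute_metrics(file.path(out1, "benchmark.csv"))
  expect_equal(tab$rmse, b$table$rmse, tolerance = 1e-12)
})

test_that("the validation tier emits its comparison tables", {
  cfg <- run_config("rses", n = 400, rates = c(0.05, 0.2), mi_m = 3,
                    mi_iter = 3, master_seed = 23)
  out <- withr::local_tempdir()
  cmp <- run_validation_tier(cfg, out)
  expect_length(cmp, 2L)
  score <- read.csv(file.path(out, "score_comparison.csv"))
  # one complete row plus HD and MI rows per rate
  expect_identical(nrow(score), 1L + 2L * 2L)
  expect_true(all(c("delta_mean", "delta_sd") %in% names(score)))
  expect_setequal(unique(score$arm), c("complete", "HD", "MI"))
  t3 <- read.csv(file.path(out, "table3_analog.csv"))
  expect_true(all(c("or", "ci_lower", "ci_upper", "delta_log_or",
                    "sign_agrees") %in% names(t3)))
  t2 <- read.csv(file.path(out, "table2_analog.csv"))
  expect_true(all(c("mean", "sd", "statistic") %in% names(t2)))
})

test_that("survey and mask CSVs round-trip including missing cells", {
  pop <- rses_population()
  d <- generate_survey(pop$scale, pop$covariates, pop$items, n = 60,
                       seed = 101)
  amp <- ampute(d, missingness_plan("MCAR", 0.2, seed = 103))
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(amp, f)
  back <- read_survey_csv(f, pop$scale, cov_specs = pop$covariates)
  expect_identical(unname(is.na(back$items)), unname(amp$mask))
  expect_identical(back$items[!amp$mask], d$items[!amp$mask])
  expect_identical(back$covariates$gender, d$covariates$gender)

  fm <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(amp, fm)
  mask_back <- as.matrix(read.csv(fm)[, -1]) == 1
  expect_identical(unname(mask_back), unname(amp$mask))

  fc <- withr::local_tempfile(fileext = ".csv")
  # at n = 60 some conditional fits are rank deficient; the engine warns
  mi <- suppressWarnings(impute_mi(amp, m = 2, n_iter = 2, seed = 107))
  written <- write_completed_csv(mi, fc)
  expect_length(written, 2L)
  expect_true(file.exists(paste0(sub("\\.csv$", "", fc),
                                 "_provenance.yaml")))
})
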