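write_manifest <- function(out_dir, cfg, files) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "scalemiss",
    version = as.character(utils::packageVersion("scalemiss")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    master_seed = cfg$master_seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    files = lapply(seq_along(sums), function(i) {
      list(path = basename(names(sums)[i]), md5 = unname(sums[i]))
    }))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the simulation tier end to end
#'
#' Generates the complete dataset once, executes the replicated benchmark
#' over every configured rate, method and replication, and writes the run
#' artifacts to `out_dir`: `dataset.csv` (the complete data),
#' `benchmark.csv` (long per-replication records), `evaluation_table.csv`,
#' `config.yaml`, and `manifest.yaml` with an md5 checksum of every output.
#' Re-running with the same configuration and seed reproduces every file
#' byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `imputation_benchmark` object, invisibly.
#' @export
run_simulation_tier <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  pop <- config$population
  dataset <- generate_survey(pop$scale, pop$covariates, pop$items,
                             n = config$n,
                             seed = derive_seed(config$master_seed, 11L))
  bench <- run_benchmark(config, dataset = dataset)
  write_survey_csv(dataset, file.path(out_dir, "dataset.csv"))
  utils::write.csv(bench$records, file.path(out_dir, "benchmark.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(bench$table, file.path(out_dir, "evaluation_table.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  write_manifest(out_dir, config,
                 file.path(out_dir, c("dataset.csv", "benchmark.csv",
                                      "evaluation_table.csv", "config.yaml")))
  invisible(bench)
}

#' Run the validation tier end to end
#'
#' The "routine survey analysis" arm: for each configured rate the complete
#' dataset is amputed once (no replication), completed by hot-deck and by
#' multiple imputation, and the downstream battery — group means/SDs with
#' t/F tests, and logistic regression on the dichotomized total score — is
#' run on every arm and compared with the complete data. Writes
#' `score_comparison.csv` (overall mean/SD per arm and rate, with deltas),
#' `table2_analog.csv` (group descriptives and test statistics),
#' `table3_analog.csv` (odds ratios with intervals), `config.yaml` and
#' `manifest.yaml`.
#'
#' @param config A [run_config()]; its population must carry a
#'   dichotomization cutoff. Methods are fixed to hot-deck and MI in this
#'   tier.
#' @param out_dir Output directory.
#' @param group_vars Categorical covariates for the group tests; defaults
#'   to every categorical covariate of the population.
#' @param predictors Logistic-model covariates; defaults to every
#'   categorical covariate.
#' @return A list of `analysis_comparison` objects, one per rate, invisibly.
#' @export
run_validation_tier <- function(config, out_dir, group_vars = NULL,
                                predictors = NULL) {
  config <- validate_config(config)
  pop <- config$population
  if (is.null(pop$scale$cutoff)) {
    stop("validation tier needs a scale with a dichotomization cutoff")
  }
  categorical <- vapply(pop$covariates, function(s) s$kind == "categorical",
                        logical(1L))
  cat_names <- vapply(pop$covariates[categorical], `[[`, "", "name")
  if (is.null(group_vars)) group_vars <- cat_names
  if (is.null(predictors)) predictors <- cat_names
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  dataset <- generate_survey(pop$scale, pop$covariates, pop$items,
                             n = config$n,
                             seed = derive_seed(config$master_seed, 11L))
  totals0 <- total_score(dataset)
  score_rows <- list(data.frame(
    rate = NA_real_, arm = "complete", mean = mean(totals0),
    sd = stats::sd(totals0), delta_mean = 0, delta_sd = 0))
  t2 <- list(); t3 <- list()
  comparisons <- list()
  for (ri in seq_along(config$rates)) {
    rate <- config$rates[ri]
    plan <- missingness_plan(config$mechanism, rate,
                             drivers = config$mar_drivers,
                             seed = derive_seed(config$master_seed,
                                                90000L + ri),
                             replication = 1L)
    amp <- ampute(dataset, plan, cov_specs = pop$covariates)
    arms <- list(
      HD = impute_hotdeck(amp, config$donor_class_vars,
                          seed = derive_seed(config$master_seed,
                                             91000L + ri)),
      MI = impute_mi(amp, m = config$mi_m, n_iter = config$mi_iter,
                     k_pmm = config$mi_k_pmm,
                     seed = derive_seed(config$master_seed, 92000L + ri)))
    cmp <- compare_analyses(dataset, arms, group_vars, predictors)
    comparisons[[as.character(rate)]] <- cmp
    for (arm_name in names(arms)) {
      stats_arm <- summary_statistics(arms[[arm_name]],
                                      corr_with = config$corr_with)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        rate = rate, arm = arm_name, mean = stats_arm[["mean"]],
        sd = stats_arm[["sd"]],
        delta_mean = stats_arm[["mean"]] - mean(totals0),
        delta_sd = stats_arm[["sd"]] - stats::sd(totals0))
    }
    t2[[ri]] <- cbind(rate = rate,
                      merge(cmp$descriptives,
                            cmp$tests[c("arm", "covariate", "test",
                                        "statistic")],
                            by = c("arm", "covariate"), sort = FALSE))
    t3[[ri]] <- cbind(rate = rate, cmp$odds_ratios)
  }
  utils::write.csv(do.call(rbind, score_rows),
                   file.path(out_dir, "score_comparison.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(do.call(rbind, t2), file.path(out_dir, "table2_analog.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(do.call(rbind, t3), file.path(out_dir, "table3_analog.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  write_manifest(out_dir, config,
                 file.path(out_dir, c("score_comparison.csv",
                                      "table2_analog.csv",
                                      "table3_analog.csv", "config.yaml")))
  invisible(comparisons)
}

#' Recompute evaluation tables from stored records
#'
#' Re-derives the evaluation table from a `benchmark.csv` written by
#' [run_simulation_tier()], without re-running any imputation. Useful as an
#' independent check that the summaries match the raw records.
#'
#' @param records_csv Path to a benchmark records CSV.
#' @param out_dir Optional directory; when given, writes
#'   `evaluation_table.csv` there.
#' @return The evaluation table data.frame.
#' @export
recompute_metrics <- function(records_csv, out_dir = NULL) {
  records <- utils::read.csv(records_csv, stringsAsFactors = FALSE)
  tab <- evaluation_table(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "evaluation_table.csv"),
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  tab
}
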