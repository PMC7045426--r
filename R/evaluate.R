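#' Summary statistics of a (completed) dataset
#'
#' The three statistics the benchmark tracks: mean and sample standard
#' deviation (denominator `n - 1`) of the total score, and the Pearson
#' correlation between the total score and a configured covariate (default
#' `"age"`). For multiply imputed data each statistic is computed per
#' completed dataset and averaged across the `m` imputations.
#'
#' @param x A `completed_data` or `survey_data` object.
#' @param corr_with Name of the covariate column to correlate the total
#'   score with (default `"age"`).
#' @return Named numeric vector `c(mean, sd, corr)`.
#' @export
summary_statistics <- function(x, corr_with = "age") {
  one <- function(items, covs) {
    t <- total_score(items)
    if (length(t) < 2L) stop("need at least 2 respondents for sd/corr")
    v <- covs[[corr_with]]
    if (is.null(v)) stop(sprintf("covariate '%s' not found", corr_with))
    c(mean = mean(t), sd = stats::sd(t),
      corr = stats::cor(t, as.numeric(v)))
  }
  if (inherits(x, "survey_data")) {
    return(one(x$items, x$covariates))
  }
  if (inherits(x, "completed_data")) {
    stats <- vapply(x$items, one, numeric(3L), covs = x$covariates)
    return(rowMeans(stats))
  }
  stop("'x' must be a survey_data or completed_data object")
}

#' Replication-level error metrics
#'
#' The three summaries comparing a statistic computed after imputation
#' (`y_ij`, method `j`, replication `i`) with its complete-data value
#' (`y_i0`):
#'
#' * `absolute_deviation(y_ij, y_i0)` — `|y_ij - y_i0|` per replication;
#' * `rmse(y_ij, y_i0)` — `sqrt(sum((y_ij - y_i0)^2) / n)` over the `n`
#'   replications of one condition;
#' * `average_relative_error(y_ij, y_i0)` — `mean((y_i0 - y_ij) / y_i0)`,
#'   signed (deviations of opposite sign cancel; an absolute-valued variant
#'   is available via `absolute = TRUE`).
#'
#' @param y_ij Numeric vector of post-imputation statistics.
#' @param y_i0 Complete-data statistics (recycled if scalar).
#' @param absolute For `average_relative_error()`: take `|.|` of each
#'   relative deviation before averaging (default `FALSE`, the signed
#'   definition).
#' @return Numeric: per-replication deviations (`absolute_deviation`) or a
#'   scalar (`rmse`, `average_relative_error`).
#' @examples
#' rmse(c(2, 4), c(1, 2))                    # sqrt(2.5)
#' average_relative_error(c(1, 2), c(2, 4))  # 0.5
#' @export
absolute_deviation <- function(y_ij, y_i0) {
  stopifnot(is.finite(y_ij), is.finite(y_i0))
  abs(y_ij - y_i0)
}

#' @rdname absolute_deviation
#' @export
rmse <- function(y_ij, y_i0) {
  if (length(y_ij) == 0L) stop("no replications to summarize")
  stopifnot(length(y_i0) %in% c(1L, length(y_ij)))
  sqrt(sum((y_ij - y_i0)^2) / length(y_ij))
}

#' @rdname absolute_deviation
#' @export
average_relative_error <- function(y_ij, y_i0, absolute = FALSE) {
  if (length(y_ij) == 0L) stop("no replications to summarize")
  stopifnot(length(y_i0) %in% c(1L, length(y_ij)))
  if (any(y_i0 == 0)) stop("complete-data statistic is 0; relative error undefined")
  rel <- (y_i0 - y_ij) / y_i0
  if (absolute) rel <- abs(rel)
  mean(rel)
}

#' Run the replicated imputation benchmark
#'
#' The full factorial experiment: one complete dataset is generated (or
#' supplied), then for every missingness rate and replication the dataset
#' is amputed under the configured mechanism, each handling strategy is
#' applied, and the total-score mean, SD and correlation are recorded
#' against their complete-data values. Everything is deterministic given
#' the master seed; replication `i` at every rate draws its own mask and
#' method seeds from documented sub-streams.
#'
#' @param config A [run_config()] (or the list it returns).
#' @param dataset Optional pre-built complete `survey_data`; generated from
#'   the config's population when omitted.
#' @return An `imputation_benchmark` object: `records` (long per-replication
#'   data.frame with columns rate, method, replication, statistic, y_i0,
#'   y_ij) and `table` (per method x rate x statistic: mean and SD of
#'   absolute deviation, RMSE, signed average relative error, n).
#' @seealso [evaluation_table()], [run_simulation_tier()]
#' @export
run_benchmark <- function(config, dataset = NULL) {
  config <- validate_config(config)
  pop <- config$population
  if (is.null(dataset)) {
    dataset <- generate_survey(pop$scale, pop$covariates, pop$items,
                               n = config$n, seed = derive_seed(config$master_seed, 11L))
  }
  y0 <- summary_statistics(dataset, corr_with = config$corr_with)
  recs <- vector("list", length(config$rates) * config$n_reps *
                   length(config$methods))
  idx <- 0L
  for (ri in seq_along(config$rates)) {
    rate <- config$rates[ri]
    for (rep_i in seq_len(config$n_reps)) {
      rep_stream <- ri * 10000L + rep_i
      plan <- missingness_plan(config$mechanism, rate,
                               drivers = config$mar_drivers,
                               seed = derive_seed(config$master_seed, rep_stream),
                               replication = rep_i)
      amp <- ampute(dataset, plan, cov_specs = pop$covariates)
      for (method in config$methods) {
        comp <- switch(method,
          deletion = complete_case(amp),
          mode = impute_mode(amp),
          hotdeck = impute_hotdeck(amp, config$donor_class_vars,
                                   seed = derive_seed(config$master_seed,
                                                      rep_stream + 1L)),
          mi = impute_mi(amp, m = config$mi_m, n_iter = config$mi_iter,
                         k_pmm = config$mi_k_pmm,
                         seed = derive_seed(config$master_seed,
                                            rep_stream + 2L)))
        yj <- summary_statistics(comp, corr_with = config$corr_with)
        idx <- idx + 1L
        recs[[idx]] <- data.frame(
          rate = rate, method = method, replication = rep_i,
          statistic = names(y0), y_i0 = unname(y0), y_ij = unname(yj),
          row.names = NULL)
      }
    }
  }
  records <- do.call(rbind, recs)
  structure(
    list(records = records, table = evaluation_table(records),
         config = config, baseline = y0),
    class = "imputation_benchmark"
  )
}

#' Summarize per-replication records into the evaluation table
#'
#' Aggregates long-format benchmark records into one row per
#' (method, rate, statistic): mean and SD of the absolute deviation across
#' replications, RMSE, the signed average relative error, and the
#' replication count. Usable on records reloaded from disk, so stored runs
#' can be re-summarized without recomputation.
#'
#' @param records Data.frame with columns `rate`, `method`, `replication`,
#'   `statistic`, `y_i0`, `y_ij`.
#' @return A data.frame, one row per condition.
#' @export
evaluation_table <- function(records) {
  need <- c("rate", "method", "statistic", "y_i0", "y_ij")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  key <- interaction(records$method, records$rate, records$statistic,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    dev <- absolute_deviation(d$y_ij, d$y_i0)
    data.frame(
      method = d$method[1L], rate = d$rate[1L], statistic = d$statistic[1L],
      abs_dev_mean = mean(dev), abs_dev_sd = if (nrow(d) > 1L) stats::sd(dev) else NA_real_,
      rmse = rmse(d$y_ij, d$y_i0),
      avg_rel_error = average_relative_error(d$y_ij, d$y_i0),
      n = nrow(d), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rate, out$statistic, out$method), ]
  rownames(out) <- NULL
  out
}

#' @export
print.imputation_benchmark <- function(x, ...) {
  cat(sprintf(
    "<imputation_benchmark> %s: %d rate(s) x %d method(s) x %d replication(s)\n",
    x$config$population$scale$name, length(x$config$rates),
    length(x$config$methods), x$config$n_reps))
  cat(sprintf("  complete-data statistics: mean %.3f, sd %.3f, corr %.3f\n",
              x$baseline["mean"], x$baseline["sd"], x$baseline["corr"]))
  invisible(x)
}

#' @export
summary.imputation_benchmark <- function(object, statistic = "mean", ...) {
  tab <- object$table[object$table$statistic == statistic, ]
  cat(sprintf("Absolute deviation / RMSE of the total-score %s\n", statistic))
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Plot RMSE against missingness rate
#'
#' One line per handling strategy for the chosen statistic, mirroring the
#' usual presentation of imputation benchmarks.
#'
#' @param x An `imputation_benchmark` object.
#' @param statistic `"mean"`, `"sd"` or `"corr"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.imputation_benchmark <- function(x, statistic = "mean", ...) {
  tab <- x$table[x$table$statistic == statistic, ]
  methods <- sort(unique(tab$method))
  rates <- sort(unique(tab$rate))
  m <- sapply(methods, function(me) {
    tab$rmse[tab$method == me][order(tab$rate[tab$method == me])]
  })
  graphics::matplot(rates, m, type = "b", pch = 19, lty = 1,
                    xlab = "missingness rate",
                    ylab = sprintf("RMSE of total-score %s", statistic), ...)
  graphics::legend("topleft", legend = methods, col = seq_along(methods),
                   pch = 19, bty = "n")
  invisible(x)
}
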