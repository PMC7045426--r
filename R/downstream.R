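#' Dichotomize total scores at a cutoff
#'
#' Binary outcome for the downstream logistic model: 1 when the total score
#' reaches the cutoff (high trait), 0 below it.
#'
#' @param totals Numeric vector of total scores.
#' @param cutoff Integer cutoff.
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize_score(c(29, 30, 31), 30)
#' @export
dichotomize_score <- function(totals, cutoff) {
  stopifnot(is.numeric(totals), is.numeric(cutoff), length(cutoff) == 1L)
  as.integer(totals >= cutoff)
}

#' Group comparisons of the total score
#'
#' For each grouping covariate: group means and sample SDs of the total
#' score, plus a pooled-variance two-sample t statistic (two levels) or a
#' one-way ANOVA F statistic (more than two levels), with the p-value and a
#' significance flag at `alpha`.
#'
#' @param totals Numeric vector of total scores.
#' @param covariates Covariate data.frame aligned with `totals`.
#' @param group_vars Character vector of categorical covariate names.
#' @param alpha Significance level (default 0.05).
#' @return A list with `groups` (one row per covariate level: mean, sd, n)
#'   and `tests` (one row per covariate: statistic type, value, df,
#'   p-value, significant).
#' @export
group_tests <- function(totals, covariates, group_vars, alpha = 0.05) {
  stopifnot(length(totals) == nrow(covariates))
  groups <- list()
  tests <- list()
  for (v in group_vars) {
    g <- covariates[[v]]
    if (is.null(g)) stop(sprintf("grouping covariate '%s' not found", v))
    g <- droplevels(factor(g))
    counts <- table(g)
    if (any(counts < 2L)) {
      bad <- names(counts)[counts < 2L]
      stop(sprintf("group '%s' of '%s' has fewer than 2 observations",
                   bad[1L], v))
    }
    gm <- tapply(totals, g, mean)
    gs <- tapply(totals, g, stats::sd)
    groups[[v]] <- data.frame(
      covariate = v, level = names(gm), n = as.integer(counts),
      mean = as.numeric(gm), sd = as.numeric(gs), row.names = NULL)
    if (nlevels(g) == 2L) {
      tt <- stats::t.test(totals ~ g, var.equal = TRUE)
      tests[[v]] <- data.frame(
        covariate = v, test = "t", statistic = unname(tt$statistic),
        df = unname(tt$parameter), p_value = tt$p.value,
        significant = tt$p.value < alpha, row.names = NULL)
    } else {
      an <- stats::anova(stats::aov(totals ~ g))
      tests[[v]] <- data.frame(
        covariate = v, test = "F", statistic = an$`F value`[1L],
        df = an$Df[1L], p_value = an$`Pr(>F)`[1L],
        significant = an$`Pr(>F)`[1L] < alpha, row.names = NULL)
    }
  }
  list(groups = do.call(rbind, groups), tests = do.call(rbind, tests))
}

# Integer-score (trend) coding of the downstream predictors: categorical
# covariates enter as a single 1..L term, continuous ones as-is.
trend_code <- function(covariates, predictors) {
  out <- lapply(predictors, function(v) {
    col <- covariates[[v]]
    if (is.null(col)) stop(sprintf("predictor '%s' not found", v))
    if (is.factor(col) || is.character(col)) as.integer(factor(col))
    else as.numeric(col)
  })
  names(out) <- predictors
  as.data.frame(out)
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit of a binary outcome on trend-coded
#' predictors (single integer-scored term per multi-level covariate).
#' Reports per predictor the odds ratio `exp(beta)`, the Wald 95% interval
#' `exp(beta +/- 1.96 se)`, and a non-significance flag when the interval
#' spans 1.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param covariates Covariate data.frame.
#' @param predictors Character vector of covariate names.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `coef` (data.frame: term, estimate, se, or,
#'   ci_lower, ci_upper, significant), the fitted `model`, and `vcov`.
#' @export
fit_logistic <- function(outcome, covariates, predictors,
                         conf_level = 0.95) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2L) {
    stop("outcome must contain both classes")
  }
  X <- trend_code(covariates, predictors)
  dat <- cbind(.y = outcome, X)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100L))
  if (!fit$converged) stop("logistic fit did not converge")
  if (any(abs(stats::coef(fit)) > 15)) {
    stop("logistic fit suggests complete or quasi-complete separation")
  }
  est <- stats::coef(fit)[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef_tab <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_lower = exp(unname(est) - z * unname(se)),
    ci_upper = exp(unname(est) + z * unname(se)),
    row.names = NULL)
  coef_tab$significant <- coef_tab$ci_lower > 1 | coef_tab$ci_upper < 1
  list(coef = coef_tab, model = fit, vcov = stats::vcov(fit))
}

#' Pooled logistic regression over multiply imputed datasets
#'
#' Fits the logistic model in each of the `m` completed datasets, pools
#' every coefficient and its squared standard error with [rubins_pool()],
#' and forms odds-ratio intervals from the pooled point, total variance and
#' Rubin degrees of freedom (t quantile).
#'
#' @param completed A `completed_data` object with `m >= 2` datasets
#'   (method `"mi"`).
#' @param predictors Character vector of covariate names.
#' @param cutoff Dichotomization cutoff for the total score (defaults to
#'   the scale's cutoff).
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame: term, estimate (pooled log-odds), se, or,
#'   ci_lower, ci_upper, df, significant.
#' @export
pooled_logistic_mi <- function(completed, predictors, cutoff = NULL,
                               conf_level = 0.95) {
  stopifnot(inherits(completed, "completed_data"))
  m <- length(completed$items)
  if (m < 2L) stop("pooling needs m >= 2 completed datasets")
  if (is.null(cutoff)) cutoff <- completed$scale$cutoff
  if (is.null(cutoff)) stop("no dichotomization cutoff available")
  fits <- lapply(seq_len(m), function(l) {
    f <- tryCatch(
      fit_logistic(dichotomize_score(total_score(completed$items[[l]]), cutoff),
                   completed$covariates, predictors, conf_level),
      error = function(e) {
        stop(sprintf("logistic fit failed in imputation %d: %s",
                     l, conditionMessage(e)), call. = FALSE)
      })
    f$coef
  })
  terms <- fits[[1L]]$term
  rows <- lapply(seq_along(terms), function(t_i) {
    est <- vapply(fits, function(f) f$estimate[t_i], numeric(1L))
    va <- vapply(fits, function(f) f$se[t_i]^2, numeric(1L))
    p <- rubins_pool(est, va)
    se <- sqrt(p$total_var)
    q <- if (is.finite(p$df)) stats::qt(1 - (1 - conf_level) / 2, p$df)
         else stats::qnorm(1 - (1 - conf_level) / 2)
    data.frame(term = terms[t_i], estimate = p$point, se = se,
               or = exp(p$point), ci_lower = exp(p$point - q * se),
               ci_upper = exp(p$point + q * se), df = p$df,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$ci_lower > 1 | out$ci_upper < 1
  out
}

#' Compare downstream analyses across complete and imputed arms
#'
#' Runs the same battery — group means/SDs with t/F tests and the logistic
#' model on the dichotomized total score — on the complete dataset and on
#' each completed arm, and tabulates the deltas against the complete-data
#' arm. For an MI arm, descriptives are averaged across imputations and the
#' logistic model is pooled by Rubin's rules.
#'
#' @param dataset The complete `survey_data`.
#' @param arms Named list of `completed_data` objects (e.g.
#'   `list(HD = ..., MI = ...)`).
#' @param group_vars Categorical covariates for the group tests.
#' @param predictors Covariates for the logistic model.
#' @param cutoff Dichotomization cutoff (defaults to the scale's).
#' @return An `analysis_comparison` object: `descriptives` (long: arm,
#'   covariate, level, mean, sd, plus delta vs complete), `tests`
#'   (arm, covariate, statistic), `odds_ratios` (arm, term, or, ci, delta
#'   of log-OR and OR sign agreement vs complete).
#' @export
compare_analyses <- function(dataset, arms, group_vars, predictors,
                             cutoff = NULL) {
  stopifnot(inherits(dataset, "survey_data"))
  if (is.null(cutoff)) cutoff <- dataset$scale$cutoff
  battery_single <- function(totals, covs, arm) {
    gt <- group_tests(totals, covs, group_vars)
    lg <- fit_logistic(dichotomize_score(totals, cutoff), covs, predictors)
    desc <- cbind(arm = arm, gt$groups)
    tests <- cbind(arm = arm, gt$tests)
    ors <- cbind(arm = arm, lg$coef[, c("term", "estimate", "or",
                                        "ci_lower", "ci_upper",
                                        "significant")])
    list(desc = desc, tests = tests, ors = ors)
  }
  battery <- function(x, arm) {
    if (inherits(x, "survey_data")) {
      return(battery_single(total_score(x), x$covariates, arm))
    }
    stopifnot(inherits(x, "completed_data"))
    if (length(x$items) == 1L) {
      return(battery_single(total_score(x$items[[1L]]), x$covariates, arm))
    }
    # MI arm: average descriptives and test statistics across imputations,
    # pool the logistic coefficients
    per <- lapply(x$items, function(it)
      battery_single(total_score(it), x$covariates, arm))
    desc <- per[[1L]]$desc
    desc$mean <- rowMeans(sapply(per, function(p) p$desc$mean))
    desc$sd <- rowMeans(sapply(per, function(p) p$desc$sd))
    tests <- per[[1L]]$tests
    tests$statistic <- rowMeans(sapply(per, function(p) p$tests$statistic))
    tests$p_value <- NA_real_
    tests$significant <- NA
    pl <- pooled_logistic_mi(x, predictors, cutoff)
    ors <- cbind(arm = arm, pl[, c("term", "estimate", "or", "ci_lower",
                                   "ci_upper", "significant")])
    list(desc = desc, tests = tests, ors = ors)
  }
  ref <- battery(dataset, "complete")
  all_arms <- c(list(complete = ref),
                lapply(seq_along(arms), function(i)
                  battery(arms[[i]], names(arms)[i])))
  names(all_arms) <- c("complete", names(arms))
  desc <- do.call(rbind, lapply(all_arms, `[[`, "desc"))
  tests <- do.call(rbind, lapply(all_arms, `[[`, "tests"))
  ors <- do.call(rbind, lapply(all_arms, `[[`, "ors"))
  rownames(desc) <- rownames(tests) <- rownames(ors) <- NULL
  # deltas against the complete arm, matched on covariate level / term
  ref_key <- paste(ref$desc$covariate, ref$desc$level)
  desc$delta_mean <- desc$mean -
    ref$desc$mean[match(paste(desc$covariate, desc$level), ref_key)]
  desc$delta_sd <- desc$sd -
    ref$desc$sd[match(paste(desc$covariate, desc$level), ref_key)]
  ors$delta_log_or <- ors$estimate -
    ref$ors$estimate[match(ors$term, ref$ors$term)]
  ors$sign_agrees <- sign(ors$estimate) ==
    sign(ref$ors$estimate[match(ors$term, ref$ors$term)])
  structure(list(descriptives = desc, tests = tests, odds_ratios = ors),
            class = "analysis_comparison")
}

#' @export
print.analysis_comparison <- function(x, ...) {
  cat("<analysis_comparison>\n")
  cat(sprintf("  arms: %s\n",
              paste(unique(x$descriptives$arm), collapse = ", ")))
  cat(sprintf("  max |delta mean| vs complete: %.4f\n",
              max(abs(x$descriptives$delta_mean), na.rm = TRUE)))
  cat(sprintf("  all log-OR signs agree with complete: %s\n",
              all(x$odds_ratios$sign_agrees)))
  invisible(x)
}
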