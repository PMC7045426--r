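#' Describe a missingness mechanism
#'
#' A `missingness_plan` specifies how item cells of a complete dataset are
#' set missing: the mechanism (MCAR or MAR), the marginal cell-level rate to
#' attain, and — for MAR — which fully observed covariates drive
#' missingness and with what logistic slopes. Every respondent gets one
#' missingness probability `plogis(alpha + sum beta_p x_p)` applied
#' independently to each of their item cells; `alpha` is solved by
#' [calibrate_intercept()] so the population-average probability equals
#' `target_rate`. Under MCAR the probability is simply `target_rate`.
#'
#' Covariate values `x_p` enter on the same centred scale the trait model
#' uses (integer level codes centred at their expected value; standardized
#' continuous values), so slopes are per level step / per SD.
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param target_rate Marginal probability a cell goes missing, in (0, 1).
#' @param drivers Named numeric vector of slopes on covariates (MAR only),
#'   e.g. `c(gender = 0.6, record = 0.3)`.
#' @param seed Integer master seed.
#' @param replication Replication index (>= 1); combined with `seed` to give
#'   each replication its own reproducible mask.
#' @return An object of class `missingness_plan` (intercept unset until
#'   calibrated).
#' @examples
#' missingness_plan("MCAR", 0.10, seed = 1)
#' @export
missingness_plan <- function(mechanism = c("MAR", "MCAR"), target_rate,
                             drivers = NULL, seed, replication = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(target_rate), length(target_rate) == 1L)
  if (target_rate <= 0 || target_rate >= 1) {
    stop("'target_rate' must lie strictly between 0 and 1")
  }
  if (mechanism == "MAR") {
    if (is.null(drivers) || length(drivers) < 1L || is.null(names(drivers))) {
      stop("MAR needs at least one named driver covariate slope")
    }
  }
  structure(
    list(mechanism = mechanism, target_rate = target_rate,
         drivers = drivers, intercept = NULL,
         seed = as.integer(seed), replication = as.integer(replication)),
    class = "missingness_plan"
  )
}

#' @export
print.missingness_plan <- function(x, ...) {
  cat(sprintf("<missingness_plan> %s, target cell rate %.3g, replication %d\n",
              x$mechanism, x$target_rate, x$replication))
  if (!is.null(x$drivers)) {
    cat("  drivers:", paste(sprintf("%s=%.3g", names(x$drivers), x$drivers),
                            collapse = ", "), "\n")
  }
  if (!is.null(x$intercept)) cat(sprintf("  intercept: %.6f\n", x$intercept))
  invisible(x)
}

# Linear predictor sum(beta * x) per respondent, on the centred covariate
# scale. `cov_specs` supplies the centring; without it, categorical columns
# are centred at their empirical level frequencies.
mar_linpred <- function(drivers, covariates, cov_specs = NULL) {
  lp <- numeric(nrow(covariates))
  spec_of <- function(nm) {
    if (is.null(cov_specs)) return(NULL)
    for (s in cov_specs) if (s$name == nm) return(s)
    NULL
  }
  for (nm in names(drivers)) {
    col <- covariates[[nm]]
    if (is.null(col)) stop(sprintf("driver covariate '%s' not found", nm))
    if (anyNA(col)) stop(sprintf("driver covariate '%s' has missing values", nm))
    s <- spec_of(nm)
    x <- if (!is.null(s)) {
      trait_score(col, s)
    } else if (is.factor(col) || is.character(col)) {
      code <- as.integer(factor(col))
      code - mean(code)
    } else {
      as.numeric(scale(col))
    }
    lp <- lp + drivers[[nm]] * x
  }
  lp
}

#' Solve the MAR intercept for a target marginal rate
#'
#' Finds the intercept `alpha` such that the mean over respondents of
#' `plogis(alpha + linpred)` equals the plan's target rate to within 1e-6,
#' by bisection (the mean is strictly increasing in `alpha`). With all
#' slopes zero this reduces to the closed form `qlogis(target_rate)`.
#'
#' @param plan A [missingness_plan()].
#' @param covariates Covariate `data.frame` of the dataset to be amputed.
#' @param cov_specs Optional [covariate_spec()] list used for centring.
#' @return The intercept (numeric scalar).
#' @examples
#' p <- missingness_plan("MCAR", 0.10, seed = 1)
#' calibrate_intercept(p, data.frame(x = 1:5))  # qlogis(0.1)
#' @export
calibrate_intercept <- function(plan, covariates, cov_specs = NULL) {
  stopifnot(inherits(plan, "missingness_plan"))
  if (plan$mechanism == "MCAR" || is.null(plan$drivers)) {
    return(stats::qlogis(plan$target_rate))
  }
  lp <- mar_linpred(plan$drivers, covariates, cov_specs)
  if (max(lp) - min(lp) == 0) {
    return(stats::qlogis(plan$target_rate) - lp[1L])
  }
  f <- function(a) mean(stats::plogis(a + lp)) - plan$target_rate
  lo <- stats::qlogis(plan$target_rate) - max(lp)
  hi <- stats::qlogis(plan$target_rate) - min(lp)
  if (f(lo) > 0 || f(hi) < 0) stop("target rate unattainable for these drivers")
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  if (abs(f(alpha)) > 1e-6) stop("intercept calibration did not converge")
  alpha
}

#' Impose missingness on a complete dataset
#'
#' Draws the missingness mask implied by the plan: each item cell of
#' respondent `i` is set missing independently with probability
#' `plogis(alpha + linpred_i)` (MAR) or `target_rate` (MCAR). The mask is a
#' deterministic function of `(plan$seed, plan$replication)`; the item
#' values themselves are never altered, so observed cells equal the base
#' dataset exactly.
#'
#' @param dataset A complete `survey_data` object.
#' @param plan A [missingness_plan()]; calibrated automatically if its
#'   intercept is unset.
#' @param cov_specs Optional [covariate_spec()] list for driver centring.
#' @return An `amputed_data` object: list with `base`, logical `mask`
#'   (`TRUE` = missing), and the calibrated `plan`.
#' @export
ampute <- function(dataset, plan, cov_specs = NULL) {
  stopifnot(inherits(dataset, "survey_data"),
            inherits(plan, "missingness_plan"))
  n <- nrow(dataset$items)
  k <- ncol(dataset$items)
  if (plan$mechanism == "MAR") {
    if (is.null(plan$intercept)) {
      plan$intercept <- calibrate_intercept(plan, dataset$covariates, cov_specs)
    }
    p <- stats::plogis(plan$intercept +
                         mar_linpred(plan$drivers, dataset$covariates,
                                     cov_specs))
  } else {
    plan$intercept <- stats::qlogis(plan$target_rate)
    p <- rep(plan$target_rate, n)
  }
  mask <- with_seed(derive_seed(plan$seed, 1000L + plan$replication), {
    matrix(stats::runif(n * k) < p, n, k) # recycles p down columns
  })
  dimnames(mask) <- dimnames(dataset$items)
  structure(list(base = dataset, mask = mask, plan = plan),
            class = "amputed_data")
}

#' @export
print.amputed_data <- function(x, ...) {
  cat(sprintf(
    "<amputed_data> %s: %d x %d cells, %s target %.3g, realized %.4f (complete cases %.3f)\n",
    x$base$scale$name, nrow(x$mask), ncol(x$mask), x$plan$mechanism,
    x$plan$target_rate, realized_missing_rate(x), complete_case_fraction(x)))
  invisible(x)
}

#' Realized missingness summaries
#'
#' `realized_missing_rate()` is the fraction of item cells missing;
#' `complete_case_fraction()` the fraction of respondents with no missing
#' item. Both matter: even modest cell-level rates can leave few complete
#' respondents once missing cells scatter across people (at cell rate `r`
#' over `k` independent items the complete-case fraction is about
#' `(1 - r)^k`).
#'
#' @param amputed An `amputed_data` object.
#' @return A numeric scalar.
#' @export
realized_missing_rate <- function(amputed) {
  stopifnot(inherits(amputed, "amputed_data"))
  mean(amputed$mask)
}

#' @rdname realized_missing_rate
#' @export
complete_case_fraction <- function(amputed) {
  stopifnot(inherits(amputed, "amputed_data"))
  mean(rowSums(amputed$mask) == 0L)
}

# Item matrix with masked cells set NA.
amputed_items <- function(amputed) {
  m <- amputed$base$items
  m[amputed$mask] <- NA_integer_
  m
}
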