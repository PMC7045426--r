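# Completed-data container shared by all four handling strategies: a list
# of one (deletion/mode/hotdeck) or m (MI) complete item matrices, the
# covariates aligned to their rows, and provenance.
new_completed <- function(method, items_list, covariates, scale, provenance) {
  structure(
    list(method = method, items = items_list, covariates = covariates,
         scale = scale, provenance = provenance),
    class = "completed_data"
  )
}

#' @export
print.completed_data <- function(x, ...) {
  cat(sprintf("<completed_data> method '%s': %d dataset(s) of %d x %d\n",
              x$method, length(x$items), nrow(x$items[[1L]]),
              ncol(x$items[[1L]])))
  invisible(x)
}

#' Complete-case (direct deletion) analysis set
#'
#' Drops every respondent with at least one missing item and keeps the rest
#' untouched. The simplest handling strategy — and the one that both shrinks
#' the sample and biases it whenever missingness is related to the
#' covariates that also drive the scores.
#'
#' @param amputed An `amputed_data` object.
#' @return A `completed_data` object with a single dataset containing only
#'   the complete respondents (ids preserved in order).
#' @export
complete_case <- function(amputed) {
  stopifnot(inherits(amputed, "amputed_data"))
  keep <- rowSums(amputed$mask) == 0L
  if (!any(keep)) stop("no respondent is complete; nothing left to analyse")
  items <- amputed$base$items[keep, , drop = FALSE]
  covs <- amputed$base$covariates[keep, , drop = FALSE]
  prov <- list(plan = amputed$plan, kept_ids = amputed$base$ids[keep])
  new_completed("deletion", list(items), covs, amputed$base$scale, prov)
}

#' Mode imputation
#'
#' Fills each missing cell with the most frequent observed value of its item
#' column; ties are broken deterministically toward the smallest value. A
#' pure function of its input (no randomness).
#'
#' @param amputed An `amputed_data` object.
#' @return A `completed_data` object with one completed dataset.
#' @export
impute_mode <- function(amputed) {
  stopifnot(inherits(amputed, "amputed_data"))
  items <- amputed_items(amputed)
  for (j in seq_len(ncol(items))) {
    obs <- items[!is.na(items[, j]), j]
    if (length(obs) == 0L) {
      stop(sprintf("item column %d has no observed value to take a mode from", j))
    }
    tab <- table(obs)
    # names(tab) sorts numerically-as-strings for single digits; take the
    # smallest value among maximal counts explicitly
    vals <- as.integer(names(tab))
    items[is.na(items[, j]), j] <- min(vals[tab == max(tab)])
  }
  new_completed("mode", list(items), amputed$base$covariates,
                amputed$base$scale, list(plan = amputed$plan))
}

#' Random hot-deck imputation within donor classes
#'
#' Partitions respondents into donor classes by the joint levels of the
#' given (fully observed) covariates. Each missing cell `(i, j)` is filled
#' with item `j`'s value from a donor drawn uniformly at random, with
#' replacement across cells, among class members observed on item `j`. A
#' class with no observed value for an item falls back to the pool of all
#' respondents observed on that item (recorded in the provenance).
#'
#' @param amputed An `amputed_data` object.
#' @param donor_class_vars Character vector of covariate names defining the
#'   classes (default `"gender"`).
#' @param seed Integer seed.
#' @return A `completed_data` object with one completed dataset.
#' @export
impute_hotdeck <- function(amputed, donor_class_vars = "gender", seed) {
  stopifnot(inherits(amputed, "amputed_data"))
  covs <- amputed$base$covariates
  missing_vars <- setdiff(donor_class_vars, names(covs))
  if (length(missing_vars)) {
    stop("donor class variables not found: ",
         paste(missing_vars, collapse = ", "))
  }
  for (v in donor_class_vars) {
    if (anyNA(covs[[v]])) stop(sprintf("donor class variable '%s' has missing values", v))
  }
  items <- amputed_items(amputed)
  class_id <- interaction(covs[donor_class_vars], drop = TRUE)
  fallbacks <- 0L
  items <- with_seed(derive_seed(seed, 3L), {
    for (j in seq_len(ncol(items))) {
      mis <- which(is.na(items[, j]))
      if (!length(mis)) next
      obs_val <- items[, j]
      for (cl in unique(class_id[mis])) {
        cells <- mis[class_id[mis] == cl]
        pool <- obs_val[!is.na(obs_val) & class_id == cl]
        if (!length(pool)) {
          pool <- obs_val[!is.na(obs_val)]
          fallbacks <- fallbacks + 1L
        }
        if (!length(pool)) {
          stop(sprintf("item column %d has no observed donor at all", j))
        }
        # sample() would misread a length-1 numeric pool as 1:pool
        items[cells, j] <- pool[sample.int(length(pool), length(cells),
                                           replace = TRUE)]
      }
    }
    items
  })
  prov <- list(plan = amputed$plan, donor_class_vars = donor_class_vars,
               seed = seed, fallback_pools_used = fallbacks)
  new_completed("hotdeck", list(items), covs, amputed$base$scale, prov)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation estimates and their squared standard errors:
#' point estimate `qbar = mean(q)`, within-imputation variance
#' `ubar = mean(u)`, between-imputation variance `B = var(q)`, total
#' variance `T = ubar + (1 + 1/m) B`, and small-sample degrees of freedom
#' `df = (m - 1) (1 + ubar / ((1 + 1/m) B))^2` (`Inf` when `B = 0`).
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (length m >= 2).
#' @param variances Their squared standard errors (same length, >= 0).
#' @return An object of class `pooled_estimate` with fields `point`,
#'   `within_var`, `between_var`, `total_var`, `df`, `m`.
#' @examples
#' rubins_pool(c(1, 3), c(1, 1))  # point 2, total variance 4
#' @export
rubins_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2L) stop("Rubin's rules need at least 2 imputations")
  if (length(variances) != m) stop("'estimates' and 'variances' lengths differ")
  if (any(variances < 0)) stop("variances must be nonnegative")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  B <- stats::var(estimates)
  Tv <- ubar + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + ubar / ((1 + 1 / m) * B))^2
  structure(
    list(point = qbar, within_var = ubar, between_var = B,
         total_var = Tv, df = df, m = m),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> %.6g (total var %.6g = within %.6g + %.6g between; df %.4g; m=%d)\n",
    x$point, x$total_var, x$within_var, (1 + 1 / x$m) * x$between_var,
    x$df, x$m))
  invisible(x)
}

#' Apply one handling strategy to an amputed dataset
#'
#' Dispatcher over the four strategies. Extra arguments are passed to the
#' method-specific worker ([complete_case()], [impute_mode()],
#' [impute_hotdeck()], [impute_mi()]).
#'
#' @param amputed An `amputed_data` object.
#' @param method One of `"deletion"`, `"mode"`, `"hotdeck"`, `"mi"`.
#' @param ... Method arguments (e.g. `seed`, `donor_class_vars`, `m`).
#' @return A `completed_data` object.
#' @export
impute <- function(amputed, method = c("deletion", "mode", "hotdeck", "mi"),
                   ...) {
  method <- match.arg(method)
  switch(method,
         deletion = complete_case(amputed),
         mode = impute_mode(amputed),
         hotdeck = impute_hotdeck(amputed, ...),
         mi = impute_mi(amputed, ...))
}
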