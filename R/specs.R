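#' Define a questionnaire scale
#'
#' A `scale_spec` records the schema of a Likert-type instrument: how many
#' items it has, the ordinal response range shared by all items, and the
#' scoring rule (total score = sum of items). An optional dichotomization
#' cutoff turns the total score into a binary outcome (`total >= cutoff`),
#' and optional calibration targets record the total-score mean and SD that
#' a synthetic population generated for this scale should approximate.
#'
#' @param name Character label for the scale.
#' @param n_items Number of items (>= 2).
#' @param response_min,response_max Integer bounds of the ordinal response
#'   range, e.g. 1 and 4 for a four-point agreement scale.
#' @param cutoff Optional integer dichotomization cutoff on the total score;
#'   must lie within the attainable total-score range.
#' @param target_mean,target_sd Optional calibration targets for the
#'   total-score distribution of a synthetic population.
#' @return An object of class `scale_spec`.
#' @examples
#' scale_spec("RSES", 10, 1, 4, cutoff = 30)
#' @export
scale_spec <- function(name, n_items, response_min, response_max,
                       cutoff = NULL, target_mean = NULL, target_sd = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  n_items <- as.integer(n_items)
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  if (n_items < 2L) stop("a scale needs at least 2 items")
  if (response_min >= response_max) {
    stop("'response_min' must be strictly below 'response_max'")
  }
  if (!is.null(cutoff)) {
    cutoff <- as.integer(cutoff)
    lo <- n_items * response_min
    hi <- n_items * response_max
    if (cutoff < lo || cutoff > hi) {
      stop(sprintf("cutoff %d outside attainable total range [%d, %d]",
                   cutoff, lo, hi))
    }
  }
  structure(
    list(name = name, n_items = n_items,
         response_min = response_min, response_max = response_max,
         cutoff = cutoff, target_mean = target_mean, target_sd = target_sd),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> %s: %d items, responses %d..%d, totals %d..%d\n",
              x$name, x$n_items, x$response_min, x$response_max,
              x$n_items * x$response_min, x$n_items * x$response_max))
  if (!is.null(x$cutoff)) cat(sprintf("  dichotomization: total >= %d\n", x$cutoff))
  if (!is.null(x$target_mean)) {
    cat(sprintf("  calibration target: mean %.2f, sd %.2f\n",
                x$target_mean, x$target_sd))
  }
  invisible(x)
}

#' Define a respondent covariate
#'
#' Describes one background variable of the synthetic population and its
#' loading on the latent trait that drives item responses. Categorical
#' covariates are drawn i.i.d. from the stated level probabilities;
#' continuous covariates from a normal distribution. The trait contribution
#' is `effect` times the centred level code (categorical, codes 1..L centred
#' at their expected value) or the standardized value (continuous), so
#' `effect` is expressed per level step / per SD on the latent-trait scale.
#'
#' @param name Column name.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels Character vector of level labels (categorical only). The
#'   first level is the reference; levels are integer-scored 1..L in model
#'   matrices downstream.
#' @param probs Level probabilities, summing to 1 (categorical only).
#' @param mean,sd Normal parameters (continuous only); `sd > 0`.
#' @param effect Loading on the latent trait (default 0).
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec("gender", "categorical",
#'                levels = c("male", "female"), probs = c(0.515, 0.485),
#'                effect = -0.2)
#' @export
covariate_spec <- function(name, kind = c("categorical", "continuous"),
                           levels = NULL, probs = NULL,
                           mean = NULL, sd = NULL, effect = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, is.numeric(effect))
  if (kind == "categorical") {
    if (is.null(levels) || is.null(probs) || length(levels) != length(probs)) {
      stop("categorical covariate needs matching 'levels' and 'probs'")
    }
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
      stop("'probs' must be nonnegative and sum to 1")
    }
  } else {
    if (is.null(mean) || is.null(sd)) {
      stop("continuous covariate needs 'mean' and 'sd'")
    }
    if (sd <= 0) stop("'sd' must be positive")
  }
  structure(
    list(name = name, kind = kind, levels = levels, probs = probs,
         mean = mean, sd = sd, effect = effect),
    class = "covariate_spec"
  )
}

#' @export
print.covariate_spec <- function(x, ...) {
  if (x$kind == "categorical") {
    cat(sprintf("<covariate_spec> %s: categorical {%s}, effect %.3g/level\n",
                x$name, paste(x$levels, collapse = ", "), x$effect))
  } else {
    cat(sprintf("<covariate_spec> %s: continuous N(%.3g, %.3g^2), effect %.3g/SD\n",
                x$name, x$mean, x$sd, x$effect))
  }
  invisible(x)
}

#' Item measurement parameters for the ordinal-threshold generator
#'
#' Bundles, for every item of a scale, a factor loading on the unidimensional
#' latent trait and a strictly increasing vector of category thresholds.
#' Item level `c` is observed when the item's latent response
#' `loading * trait + noise` falls between thresholds `c - 1` and `c`.
#'
#' @param loadings Numeric vector, one loading per item.
#' @param thresholds Numeric matrix with one row per item and
#'   `n_categories - 1` columns; each row strictly increasing.
#' @return An object of class `item_params`.
#' @export
item_params <- function(loadings, thresholds) {
  thresholds <- as.matrix(thresholds)
  if (length(loadings) != nrow(thresholds)) {
    stop("need one row of thresholds per loading")
  }
  if (any(apply(thresholds, 1L, function(r) any(diff(r) <= 0)))) {
    stop("item thresholds must be strictly increasing")
  }
  structure(list(loadings = as.numeric(loadings), thresholds = thresholds),
            class = "item_params")
}
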