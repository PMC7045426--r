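#' Built-in synthetic populations
#'
#' Three ready-made population descriptions emulating the structure of the
#' cross-sectional questionnaire studies the benchmark is designed around:
#'
#' * `rses_population()` — a self-esteem scale for middle-school students:
#'   10 items scored 1–4, total dichotomized at 30, with age, gender, grade,
#'   academic record, residence and communication-frequency covariates. The
#'   item parameters are calibrated so that a population of a few thousand
#'   respondents has total-score mean near 28.2 and SD near 4.6.
#' * `saq_population()` — a self-acceptance scale for college students:
#'   16 items scored 1–4.
#' * `adl_population()` — an activities-of-daily-living scale for elders:
#'   14 items scored 1–4.
#'
#' The item counts and response ranges of the SAQ- and ADL-like scales
#' follow the conventional published forms of those instruments; their
#' covariate effects and thresholds are package defaults chosen to give
#' realistic inter-item correlations and covariate–score associations.
#' Calibration constants were tuned once (coarse grid plus bisection on a
#' common threshold shift, then a spread rescale) and are frozen here.
#'
#' @return A list with elements `scale` ([scale_spec()]), `covariates`
#'   (list of [covariate_spec()]), and `items` ([item_params()]).
#' @examples
#' pop <- rses_population()
#' pop$scale
#' @name populations
NULL

# Common thresholds: shift + spread * base gives the per-category cutpoints
# of every item; loadings are constant across items.
threshold_bank <- function(k, shift, spread, base = c(-1.25, -0.35, 0.65)) {
  matrix(rep(shift + spread * base, each = k), nrow = k)
}

#' @rdname populations
#' @export
rses_population <- function() {
  scale <- scale_spec("RSES-like", n_items = 10L,
                      response_min = 1L, response_max = 4L,
                      cutoff = 30L, target_mean = 28.22, target_sd = 4.63)
  covs <- list(
    covariate_spec("age", "continuous", mean = 16.3, sd = 1.6, effect = 0.10),
    covariate_spec("gender", "categorical",
                   levels = c("male", "female"),
                   probs = c(0.515, 0.485), effect = -0.25),
    covariate_spec("grade", "categorical",
                   levels = c("junior", "senior"),
                   probs = c(0.70, 0.30), effect = -0.05),
    covariate_spec("record", "categorical",
                   levels = c("excellent", "good", "average", "poor"),
                   probs = c(0.12, 0.28, 0.45, 0.15), effect = -0.35),
    covariate_spec("residence", "categorical",
                   levels = c("urban", "rural"),
                   probs = c(0.045, 0.955), effect = -0.08),
    covariate_spec("communication", "categorical",
                   levels = c("usually", "sometimes", "scarcely",
                              "never", "unclear"),
                   probs = c(0.45, 0.30, 0.10, 0.07, 0.08), effect = -0.25)
  )
  params <- item_params(
    loadings = rep(RSES_LOADING, 10L),
    thresholds = threshold_bank(10L, shift = RSES_SHIFT, spread = RSES_SPREAD)
  )
  list(scale = scale, covariates = covs, items = params)
}

#' @rdname populations
#' @export
saq_population <- function() {
  scale <- scale_spec("SAQ-like", n_items = 16L,
                      response_min = 1L, response_max = 4L)
  covs <- list(
    covariate_spec("age", "continuous", mean = 19.6, sd = 1.3, effect = 0.10),
    covariate_spec("gender", "categorical",
                   levels = c("male", "female"),
                   probs = c(0.48, 0.52), effect = -0.40),
    covariate_spec("residence", "categorical",
                   levels = c("urban", "rural"),
                   probs = c(0.55, 0.45), effect = -0.15)
  )
  # cutpoints place ~10/20/40/30% in the four categories, a unimodal shape
  # whose mode (3) sits close to the item mean (~2.9)
  params <- item_params(
    loadings = rep(0.9, 16L),
    thresholds = threshold_bank(16L, shift = 0, spread = 1.355,
                                base = c(-1.282, -0.524, 0.524))
  )
  list(scale = scale, covariates = covs, items = params)
}

#' @rdname populations
#' @export
adl_population <- function() {
  scale <- scale_spec("ADL-like", n_items = 14L,
                      response_min = 1L, response_max = 4L)
  covs <- list(
    covariate_spec("age", "continuous", mean = 71.8, sd = 6.5, effect = 0.30),
    covariate_spec("gender", "categorical",
                   levels = c("male", "female"),
                   probs = c(0.46, 0.54), effect = 0.10),
    covariate_spec("living", "categorical",
                   levels = c("with_family", "alone", "institution"),
                   probs = c(0.68, 0.22, 0.10), effect = 0.25)
  )
  # ADL scores are right-skewed (most elders fully independent): asymmetric
  # cutpoints concentrate mass in the lowest category.
  params <- item_params(
    loadings = rep(1.0, 14L),
    thresholds = threshold_bank(14L, shift = 0.9, spread = 0.8,
                                base = c(0, 0.9, 1.9))
  )
  list(scale = scale, covariates = covs, items = params)
}

# Frozen calibration constants for the RSES-like item model (see the
# methods vignette for the tuning procedure).
RSES_LOADING <- 0.5
RSES_SHIFT <- -0.01877
RSES_SPREAD <- 1.311
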