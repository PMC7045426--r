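#' Draw a synthetic covariate table
#'
#' Generates `n` respondents' background variables from a list of
#' [covariate_spec()]s. Categorical covariates are sampled i.i.d. from their
#' level probabilities (stored as factors with the declared level order);
#' continuous covariates from their normal distribution. Columns are drawn
#' in spec order under a single seeded stream, so identical
#' `(specs, n, seed)` reproduce the table bit for bit.
#'
#' @param specs List of [covariate_spec()] objects.
#' @param n Number of respondents (>= 0).
#' @param seed Integer seed.
#' @return A `data.frame` with `n` rows and one column per spec.
#' @examples
#' gender <- covariate_spec("gender", "categorical",
#'                          levels = c("male", "female"),
#'                          probs = c(0.515, 0.485))
#' generate_covariates(list(gender), n = 5, seed = 1)
#' @export
generate_covariates <- function(specs, n, seed) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  lapply(specs, function(s) {
    if (!inherits(s, "covariate_spec")) stop("'specs' must be covariate_spec objects")
  })
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a nonnegative integer")
  cols <- with_seed(seed, {
    lapply(specs, function(s) {
      if (s$kind == "categorical") {
        factor(sample(s$levels, n, replace = TRUE, prob = s$probs),
               levels = s$levels)
      } else {
        stats::rnorm(n, s$mean, s$sd)
      }
    })
  })
  names(cols) <- vapply(specs, `[[`, "", "name")
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (n == 0L) { # as.data.frame drops structure for zero rows pre-4.3 quirks
    out <- out[0L, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Centred numeric trait contribution of one covariate column: categorical
# levels are integer-scored 1..L and centred at their spec-implied mean;
# continuous values are standardized. Keeps effects on a common scale.
trait_score <- function(column, spec) {
  if (spec$kind == "categorical") {
    code <- as.integer(factor(column, levels = spec$levels))
    code - sum(seq_along(spec$levels) * spec$probs)
  } else {
    (column - spec$mean) / spec$sd
  }
}

#' Latent trait of each respondent
#'
#' The unidimensional trait driving all item responses:
#' `sum_p effect_p * x_p + N(0, 1)` noise, where `x_p` is the centred level
#' code (categorical) or standardized value (continuous) of covariate `p`.
#'
#' @param covariates Covariate `data.frame` as from [generate_covariates()].
#' @param specs The [covariate_spec()] list that generated it.
#' @param seed Integer seed for the trait noise.
#' @return Numeric vector of traits, one per respondent.
#' @export
latent_trait <- function(covariates, specs, seed) {
  n <- nrow(covariates)
  lin <- numeric(n)
  for (s in specs) {
    lin <- lin + s$effect * trait_score(covariates[[s$name]], s)
  }
  lin + with_seed(seed, stats::rnorm(n))
}

#' Generate ordinal item responses from a latent trait
#'
#' Graded (ordinal-threshold) measurement model: item `j`'s latent response
#' is `loading_j * trait + N(0, 1)`, cut at the item's strictly increasing
#' thresholds into the categories `response_min..response_max`. With
#' positive loadings this yields positively inter-correlated items whose
#' total score tracks the trait.
#'
#' @param covariates Covariate `data.frame`.
#' @param scale A [scale_spec()].
#' @param params An [item_params()] object with `scale$n_items` loadings and
#'   `n_categories - 1` thresholds per item.
#' @param seed Integer seed.
#' @param specs Covariate spec list (for the trait); or pass `trait` directly.
#' @param trait Optional precomputed latent trait vector.
#' @return A `survey_data` object: list with `ids`, integer `items` matrix
#'   (`n` x `n_items`), `covariates`, and `scale`.
#' @export
generate_item_responses <- function(covariates, scale, params, seed,
                                    specs = NULL, trait = NULL) {
  stopifnot(inherits(scale, "scale_spec"), inherits(params, "item_params"))
  k <- scale$n_items
  n_cat <- scale$response_max - scale$response_min + 1L
  if (length(params$loadings) != k || ncol(params$thresholds) != n_cat - 1L) {
    stop("item parameters do not match the scale's items/categories")
  }
  n <- nrow(covariates)
  if (is.null(trait)) {
    if (is.null(specs)) stop("supply either 'specs' or a precomputed 'trait'")
    trait <- latent_trait(covariates, specs, derive_seed(seed, 1L))
  }
  items <- with_seed(derive_seed(seed, 2L), {
    m <- matrix(scale$response_min, n, k)
    for (j in seq_len(k)) {
      z <- params$loadings[j] * trait + stats::rnorm(n)
      # count thresholds exceeded -> category index
      above <- rowSums(outer(z, params$thresholds[j, ], `>`))
      m[, j] <- scale$response_min + as.integer(above)
    }
    m
  })
  colnames(items) <- sprintf("item_%02d", seq_len(k))
  structure(
    list(ids = seq_len(n), items = items, covariates = covariates,
         scale = scale),
    class = "survey_data"
  )
}

#' Generate a complete synthetic questionnaire dataset
#'
#' One-call wrapper: draws covariates, the latent trait and ordinal item
#' responses for `n` respondents. The result is complete by construction
#' (no missing cells) and fully reproducible from the seed.
#'
#' @param scale A [scale_spec()].
#' @param cov_specs List of [covariate_spec()]s.
#' @param params An [item_params()] object.
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @return A `survey_data` object.
#' @examples
#' pop <- rses_population()
#' d <- generate_survey(pop$scale, pop$covariates, pop$items, n = 200, seed = 7)
#' mean(total_score(d))
#' @export
generate_survey <- function(scale, cov_specs, params, n, seed) {
  covs <- generate_covariates(cov_specs, n, derive_seed(seed, 101L))
  generate_item_responses(covs, scale, params, derive_seed(seed, 102L),
                          specs = cov_specs)
}

#' @export
print.survey_data <- function(x, ...) {
  cat(sprintf("<survey_data> %s: %d respondents x %d items (+%d covariates)\n",
              x$scale$name, nrow(x$items), ncol(x$items),
              ncol(x$covariates)))
  invisible(x)
}

#' Total scale score per respondent
#'
#' Sums the item responses of each respondent. Totals are undefined for
#' incomplete rows — the workflow imputes or deletes first — so any missing
#' cell is an error.
#'
#' @param x A `survey_data` object, or a bare item matrix / data.frame of
#'   item columns.
#' @return Numeric vector of total scores.
#' @export
total_score <- function(x) {
  items <- if (inherits(x, "survey_data")) x$items else as.matrix(x)
  if (anyNA(items)) {
    stop("items contain missing cells; impute or delete incomplete rows ",
         "before scoring")
  }
  rowSums(items)
}
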