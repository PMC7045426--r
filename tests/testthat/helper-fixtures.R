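# Hand-built fixtures: tiny datasets with known values, constructed through
# the same containers the pipeline uses.

tiny_scale <- function(n_items = 3L, lo = 1L, hi = 4L, ...) {
  scale_spec("tiny", n_items = n_items, response_min = lo,
             response_max = hi, ...)
}

# survey_data from an explicit item matrix + covariates
make_survey <- function(items, covariates = NULL, scale = NULL) {
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  colnames(items) <- sprintf("item_%02d", seq_len(ncol(items)))
  if (is.null(scale)) {
    scale <- scale_spec("fixture", n_items = ncol(items),
                        response_min = min(items), response_max = max(items))
  }
  if (is.null(covariates)) {
    covariates <- data.frame(age = seq_len(nrow(items)))
  }
  structure(list(ids = seq_len(nrow(items)), items = items,
                 covariates = covariates, scale = scale),
            class = "survey_data")
}

# amputed_data from a survey and an explicit logical mask
make_amputed <- function(survey, mask,
                         plan = missingness_plan("MCAR", 0.1, seed = 1L)) {
  mask <- matrix(as.logical(mask), nrow(survey$items), ncol(survey$items))
  dimnames(mask) <- dimnames(survey$items)
  structure(list(base = survey, mask = mask, plan = plan),
            class = "amputed_data")
}

# small generated RSES-like dataset, cached per test run
rses_fixture <- function(n = 400L, seed = 11L) {
  pop <- rses_population()
  generate_survey(pop$scale, pop$covariates, pop$items, n = n, seed = seed)
}
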