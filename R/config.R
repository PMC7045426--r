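#' Configure a benchmark or validation run
#'
#' Collects everything a run needs: the synthetic population, the sample
#' size, missingness mechanism and rates, the handling strategies to
#' compare, method parameters, and the master seed. Defaults follow the
#' benchmark design: cell-level missingness rates of 5/10/15/20% under MAR,
#' 50 replications, all four strategies.
#'
#' @param population A population list as returned by [rses_population()],
#'   [saq_population()] or [adl_population()], or one of the names
#'   `"rses"`, `"saq"`, `"adl"`.
#' @param n Respondents in the complete dataset; defaults to the study size
#'   associated with the population (RSES-like 3513, SAQ-like 742,
#'   ADL-like 1242).
#' @param rates Missingness rates, each in (0, 1), unique.
#' @param n_reps Replications per rate (>= 1).
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param mar_drivers Named slopes of the MAR mechanism on fully observed
#'   covariates (ignored under MCAR).
#' @param methods Subset of `c("deletion", "mode", "hotdeck", "mi")`.
#' @param mi_m,mi_iter,mi_k_pmm Multiple-imputation parameters.
#' @param donor_class_vars Hot-deck donor-class covariates.
#' @param corr_with Covariate for the correlation statistic.
#' @param master_seed Integer master seed for all randomness.
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config("saq", n_reps = 2, rates = 0.1, methods = c("deletion", "mode"))
#' @export
run_config <- function(population = "saq", n = NULL,
                       rates = c(0.05, 0.10, 0.15, 0.20), n_reps = 50L,
                       mechanism = c("MAR", "MCAR"),
                       mar_drivers = c(gender = 1.0, age = 0.5),
                       methods = c("deletion", "mode", "hotdeck", "mi"),
                       mi_m = 20L, mi_iter = 10L, mi_k_pmm = 5L,
                       donor_class_vars = "gender", corr_with = "age",
                       master_seed = 20200227L) {
  mechanism <- match.arg(mechanism)
  if (is.character(population)) {
    nm <- match.arg(population, c("rses", "saq", "adl"))
    if (is.null(n)) n <- c(rses = 3513L, saq = 742L, adl = 1242L)[[nm]]
    population <- switch(nm, rses = rses_population(),
                         saq = saq_population(), adl = adl_population())
  }
  if (is.null(n)) stop("'n' required for a custom population")
  cfg <- structure(
    list(population = population, n = as.integer(n), rates = rates,
         n_reps = as.integer(n_reps), mechanism = mechanism,
         mar_drivers = if (mechanism == "MAR") mar_drivers else NULL,
         methods = methods, mi_m = as.integer(mi_m),
         mi_iter = as.integer(mi_iter), mi_k_pmm = as.integer(mi_k_pmm),
         donor_class_vars = donor_class_vars, corr_with = corr_with,
         master_seed = as.integer(master_seed)),
    class = "run_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) {
    stop("'config' must be a run_config object")
  }
  if (length(cfg$rates) < 1L || any(cfg$rates <= 0 | cfg$rates >= 1)) {
    stop("missingness rates must lie strictly between 0 and 1")
  }
  if (anyDuplicated(cfg$rates)) stop("missingness rates must be unique")
  if (cfg$n_reps < 1L) stop("'n_reps' must be at least 1")
  bad <- setdiff(cfg$methods, c("deletion", "mode", "hotdeck", "mi"))
  if (length(bad) || length(cfg$methods) == 0L) {
    stop("'methods' must be a non-empty subset of deletion/mode/hotdeck/mi")
  }
  if (cfg$mechanism == "MAR" &&
      (is.null(cfg$mar_drivers) || is.null(names(cfg$mar_drivers)))) {
    stop("MAR configuration needs named driver slopes")
  }
  pop <- cfg$population
  if (!all(c("scale", "covariates", "items") %in% names(pop))) {
    stop("population must provide scale, covariates and items")
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s (n=%d): %s at rates {%s}, %d reps, methods %s, seed %d\n",
    x$population$scale$name, x$n, x$mechanism,
    paste(x$rates, collapse = ", "), x$n_reps,
    paste(x$methods, collapse = "/"), x$master_seed))
  invisible(x)
}

# ---- YAML serialization -------------------------------------------------

config_to_list <- function(cfg) {
  pop <- cfg$population
  list(
    population = list(
      scale = list(name = pop$scale$name, n_items = pop$scale$n_items,
                   response_min = pop$scale$response_min,
                   response_max = pop$scale$response_max,
                   cutoff = pop$scale$cutoff,
                   target_mean = pop$scale$target_mean,
                   target_sd = pop$scale$target_sd),
      covariates = lapply(pop$covariates, function(s) {
        list(name = s$name, kind = s$kind, levels = s$levels,
             probs = s$probs, mean = s$mean, sd = s$sd, effect = s$effect)
      }),
      items = list(loadings = pop$items$loadings,
                   thresholds = apply(pop$items$thresholds, 1L, c,
                                      simplify = FALSE))),
    n = cfg$n, rates = as.numeric(cfg$rates), n_reps = cfg$n_reps,
    mechanism = cfg$mechanism,
    mar_drivers = if (!is.null(cfg$mar_drivers)) as.list(cfg$mar_drivers),
    methods = cfg$methods, mi_m = cfg$mi_m, mi_iter = cfg$mi_iter,
    mi_k_pmm = cfg$mi_k_pmm, donor_class_vars = cfg$donor_class_vars,
    corr_with = cfg$corr_with, master_seed = cfg$master_seed)
}

config_from_list <- function(x) {
  sc <- x$population$scale
  scale <- scale_spec(sc$name, sc$n_items, sc$response_min, sc$response_max,
                      cutoff = sc$cutoff, target_mean = sc$target_mean,
                      target_sd = sc$target_sd)
  covs <- lapply(x$population$covariates, function(s) {
    covariate_spec(s$name, s$kind, levels = unlist(s$levels),
                   probs = unlist(s$probs), mean = s$mean, sd = s$sd,
                   effect = s$effect)
  })
  params <- item_params(unlist(x$population$items$loadings),
                        do.call(rbind, x$population$items$thresholds))
  run_config(population = list(scale = scale, covariates = covs,
                               items = params),
             n = x$n, rates = unlist(x$rates), n_reps = x$n_reps,
             mechanism = x$mechanism,
             mar_drivers = if (!is.null(x$mar_drivers)) unlist(x$mar_drivers),
             methods = unlist(x$methods), mi_m = x$mi_m, mi_iter = x$mi_iter,
             mi_k_pmm = x$mi_k_pmm,
             donor_class_vars = unlist(x$donor_class_vars),
             corr_with = x$corr_with, master_seed = x$master_seed)
}

#' Read or write a run configuration as YAML
#'
#' The whole configuration — including the population's scale, covariate
#' and item-parameter specifications — round-trips through YAML:
#' `read_run_config(write_run_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A [run_config()].
#' @param path File path (`.yaml`; JSON is valid YAML and also accepted on
#'   read).
#' @return `write_run_config()` the path, invisibly; `read_run_config()` a
#'   `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(validate_config(cfg)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}
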