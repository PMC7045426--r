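#' Read and write dataset CSVs
#'
#' The dataset dialect is one row per respondent: an `id` column, the item
#' columns `item_01..item_k`, then the covariate columns; UTF-8 with a
#' header row. Missing item cells (after amputation) are written as empty
#' fields and read back as `NA`.
#'
#' @param x A `survey_data`, `amputed_data`, or bare item matrix with
#'   attached covariates.
#' @param path File path.
#' @param scale A [scale_spec()] describing the items being read.
#' @param cov_specs Optional [covariate_spec()] list; categorical columns
#'   are restored as factors with the declared level order.
#' @return `write_survey_csv()` returns `path` invisibly;
#'   `read_survey_csv()` a `survey_data` object (its `items` may contain
#'   `NA` if the file was written from amputed data).
#' @export
write_survey_csv <- function(x, path) {
  if (inherits(x, "amputed_data")) {
    items <- amputed_items(x)
    covs <- x$base$covariates
    ids <- x$base$ids
  } else if (inherits(x, "survey_data")) {
    items <- x$items
    covs <- x$covariates
    ids <- x$ids
  } else {
    stop("'x' must be a survey_data or amputed_data object")
  }
  df <- cbind(data.frame(id = ids), as.data.frame(items), covs)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, scale, cov_specs = NULL) {
  stopifnot(inherits(scale, "scale_spec"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  item_cols <- sprintf("item_%02d", seq_len(scale$n_items))
  if (!all(item_cols %in% names(df))) {
    stop("file does not contain the expected item columns")
  }
  items <- as.matrix(df[item_cols])
  storage.mode(items) <- "integer"
  ok <- items[!is.na(items)]
  if (any(ok < scale$response_min | ok > scale$response_max)) {
    stop("item values outside the declared response range")
  }
  covs <- df[setdiff(names(df), c("id", item_cols))]
  if (!is.null(cov_specs)) {
    for (s in cov_specs) {
      if (s$kind == "categorical" && s$name %in% names(covs)) {
        covs[[s$name]] <- factor(covs[[s$name]], levels = s$levels)
      }
    }
  }
  structure(list(ids = df$id, items = items, covariates = covs,
                 scale = scale),
            class = "survey_data")
}

#' Write a missingness mask as 0/1 CSV
#'
#' Mirrors the dataset layout: `id` column then one 0/1 column per item
#' (1 = missing).
#'
#' @param amputed An `amputed_data` object.
#' @param path File path.
#' @export
write_mask_csv <- function(amputed, path) {
  stopifnot(inherits(amputed, "amputed_data"))
  df <- cbind(data.frame(id = amputed$base$ids),
              as.data.frame(amputed$mask * 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write completed datasets with provenance
#'
#' Single-dataset methods write one CSV at `path`; multiple imputation
#' writes `m` files suffixed `_imp001` ... plus a YAML provenance sidecar
#' (method, seeds, parameters) next to the first file.
#'
#' @param completed A `completed_data` object.
#' @param path Base file path (`.csv`).
#' @return Character vector of files written, invisibly.
#' @export
write_completed_csv <- function(completed, path) {
  stopifnot(inherits(completed, "completed_data"))
  write_one <- function(items, p) {
    df <- cbind(data.frame(id = seq_len(nrow(items))),
                as.data.frame(items), completed$covariates)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    p
  }
  files <- if (length(completed$items) == 1L) {
    write_one(completed$items[[1L]], path)
  } else {
    stem <- sub("\\.csv$", "", path)
    vapply(seq_along(completed$items), function(l) {
      write_one(completed$items[[l]], sprintf("%s_imp%03d.csv", stem, l))
    }, character(1L))
  }
  prov <- completed$provenance
  prov$plan <- if (!is.null(prov$plan)) {
    unclass(prov$plan)[c("mechanism", "target_rate", "drivers", "intercept",
                         "seed", "replication")]
  }
  prov$method <- completed$method
  yaml::write_yaml(prov, paste0(sub("\\.csv$", "", path), "_provenance.yaml"))
  invisible(files)
}
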