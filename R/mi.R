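# Least-squares fit with a proper posterior draw of (beta, sigma), used by
# the chained-equations sampler. The fast path solves the normal equations
# by Cholesky; a rank-deficient cross-product falls back to pivoted QR,
# which zeroes aliased coefficients (their count is reported so the caller
# can warn once per run).
bayes_ols_draw <- function(X, y) {
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (!is.null(R)) {
    beta_hat <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
    r <- p
    piv <- seq_len(p)
    n_aliased <- 0L
  } else {
    qrx <- qr(X)
    r <- qrx$rank
    piv <- qrx$pivot[seq_len(r)]
    R <- qr.R(qrx)[seq_len(r), seq_len(r), drop = FALSE]
    beta_hat <- numeric(p)
    beta_hat[piv] <- backsolve(R, qr.qty(qrx, y)[seq_len(r)])
    n_aliased <- p - r
  }
  resid <- y - drop(X %*% beta_hat)
  df <- max(length(y) - r, 1L)
  sigma2_star <- sum(resid^2) / stats::rchisq(1L, df)
  # var(beta | sigma) = sigma^2 (R'R)^{-1}; draw via backsolve against R
  u <- backsolve(R, stats::rnorm(r))
  beta_star <- as.numeric(beta_hat)
  beta_star[piv] <- beta_star[piv] + sqrt(sigma2_star) * u
  list(beta_hat = as.numeric(beta_hat), beta_star = beta_star,
       n_aliased = n_aliased)
}

# Predictive-mean-matching step: for each missing cell pick, uniformly at
# random, one of the k observed donors whose predicted value is nearest the
# cell's prediction, and impute that donor's observed y. The k nearest
# sorted neighbours of an insertion point lie within k positions on either
# side, so a window search on the sorted observed predictions plus k
# vectorized min-extraction passes does the whole batch without a per-cell
# loop.
pmm_match <- function(pred_obs, y_obs, pred_mis, k) {
  n_obs <- length(pred_obs)
  n_mis <- length(pred_mis)
  k <- min(k, n_obs)
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  pos <- findInterval(pred_mis, po)
  offs <- seq.int(-k + 1L, k)
  cand <- outer(pos, offs, `+`)
  cand[cand < 1L] <- 1L
  cand[cand > n_obs] <- n_obs
  diffs <- abs(matrix(po[cand], nrow = n_mis) - pred_mis)
  # k passes of row-wise min extraction give each row's k nearest donors
  rows <- seq_len(n_mis)
  nearest <- matrix(0L, n_mis, k)
  for (s in seq_len(k)) {
    j <- max.col(-diffs, ties.method = "first")
    nearest[, s] <- cand[cbind(rows, j)]
    diffs[cbind(rows, j)] <- Inf
  }
  pick <- nearest[cbind(rows, sample.int(k, n_mis, replace = TRUE))]
  yo[pick]
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Produces `m` completed datasets. Missing cells are initialized by random
#' draws from each item's observed values; then for `n_iter` sweeps each
#' incomplete item is regressed (ordinary least squares, items treated as
#' numeric for prediction only) on all other items at their current values
#' plus the covariates, regression parameters are drawn from their
#' posterior, and the item's missing cells are refilled by predictive mean
#' matching against the `k_pmm` nearest observed predictions. Because every
#' imputed value is an observed donor value of the same item, imputations
#' are automatically integers inside the response range. The `m` chains run
#' independently under distinct sub-seeds.
#'
#' @param amputed An `amputed_data` object.
#' @param m Number of imputations (>= 2; default 20).
#' @param n_iter Chained-equation sweeps per imputation (default 10).
#' @param k_pmm Donor pool size for predictive mean matching (default 5).
#' @param seed Integer seed.
#' @return A `completed_data` object holding `m` completed item matrices.
#' @export
impute_mi <- function(amputed, m = 20L, n_iter = 10L, k_pmm = 5L, seed) {
  stopifnot(inherits(amputed, "amputed_data"))
  m <- as.integer(m)
  if (m < 2L) stop("multiple imputation needs m >= 2")
  items0 <- amputed_items(amputed)
  n <- nrow(items0)
  k <- ncol(items0)
  mask <- amputed$mask
  if (any(colSums(!mask) == 0L)) {
    stop("an item column is fully missing; no observed values to draw from")
  }
  covX <- stats::model.matrix(~ ., data = amputed$base$covariates)[, -1L,
                                                                   drop = FALSE]
  # visit incomplete columns in order of increasing missingness
  mis_counts <- colSums(mask)
  visit <- order(mis_counts)
  visit <- visit[mis_counts[visit] > 0L]
  aliased <- 0L
  completed <- lapply(seq_len(m), function(l) {
    with_seed(derive_seed(seed, 5000L + l), {
      cur <- items0
      for (j in seq_len(k)) {
        mis <- mask[, j]
        if (any(mis)) {
          obs_vals <- items0[!mis, j]
          cur[mis, j] <- obs_vals[sample.int(length(obs_vals), sum(mis),
                                             replace = TRUE)]
        }
      }
      num <- matrix(as.numeric(cur), n, k)
      for (it in seq_len(n_iter)) {
        for (j in visit) {
          mis <- mask[, j]
          X <- cbind(1, num[, -j, drop = FALSE], covX)
          fit <- bayes_ols_draw(X[!mis, , drop = FALSE], num[!mis, j])
          aliased <<- aliased + fit$n_aliased
          pred_obs <- drop(X[!mis, , drop = FALSE] %*% fit$beta_hat)
          pred_mis <- drop(X[mis, , drop = FALSE] %*% fit$beta_star)
          num[mis, j] <- pmm_match(pred_obs, num[!mis, j], pred_mis, k_pmm)
        }
      }
      out <- items0
      out[] <- as.integer(num)
      out
    })
  })
  if (aliased > 0L) {
    warning(sprintf(
      "dropped %d aliased predictor column(s) across conditional fits", aliased))
  }
  prov <- list(plan = amputed$plan, m = m, n_iter = n_iter, k_pmm = k_pmm,
               seed = seed)
  new_completed("mi", completed, amputed$base$covariates,
                amputed$base$scale, prov)
}
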