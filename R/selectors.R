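# Direction-invariant univariate concordance of every column, vectorized
# over features: max(C, 1 - C) of each feature used as the sole risk score.
univariate_cindex_scores <- function(x, time, event) {
  comp <- which(outer(time, time, "<") & (event == 1), arr.ind = TRUE)
  if (nrow(comp) == 0) return(NULL)
  xi <- x[comp[, 1], , drop = FALSE]
  xj <- x[comp[, 2], , drop = FALSE]
  conc <- colSums(xi > xj) + 0.5 * colSums(xi == xj)
  c_idx <- conc / nrow(comp)
  pmax(c_idx, 1 - c_idx)
}

# Kraskov-Stoegbauer-Grassberger kNN mutual information estimator (variant 1)
# between two scalar variables; ties are broken with a deterministic jitter.
knn_mutual_information <- function(x, y, k = 3) {
  n <- length(x)
  if (n <= k + 1 || sd(x) == 0 || sd(y) == 0) return(0)
  jit <- function(v) v + seq_len(n) * 1e-10 * max(sd(v), 1e-12)
  x <- jit(rank(x)); y <- jit(rank(y))
  dx <- abs(outer(x, x, "-")); dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1, function(r) sort(r)[k])
  nx <- rowSums(dx < eps) - 1
  ny <- rowSums(dy < eps) - 1
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(mi, 0)
}

# Shared bootstrap-aggregation scaffold of the two filter selectors:
# per-bootstrap feature scores -> within-bootstrap ranks -> importance =
# mean reciprocal rank across bootstraps; ties in the final ordering break
# by feature name.
bootstrap_filter_rank <- function(x, time, event, score_fun, n_boot, seed) {
  p <- ncol(x)
  inv_rank_sum <- setNames(numeric(p), colnames(x))
  used <- 0
  skipped <- 0
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
      if (sum(event[idx]) < 2) { skipped <- skipped + 1; next }
      sc <- score_fun(x[idx, , drop = FALSE], time[idx], event[idx])
      if (is.null(sc)) { skipped <- skipped + 1; next }
      rk <- rank(-sc, ties.method = "average")
      inv_rank_sum <- inv_rank_sum + 1 / rk
      used <- used + 1
    }
  })
  if (used == 0) abort("all bootstrap resamples lacked enough events")
  importance <- inv_rank_sum / used
  ord <- order(-importance, names(importance))
  tibble(feature = names(importance)[ord],
         importance = unname(importance[ord]),
         n_bootstraps = used, n_skipped = skipped)
}

#' Bootstrap-aggregated univariate C-index feature ranking
#'
#' In each bootstrap resample of the training fold every feature is scored by
#' the direction-invariant concordance \code{max(C, 1 - C)} of the feature as
#' sole risk score; features are ranked within the resample and the overall
#' importance is the mean reciprocal rank across resamples.
#'
#' @param x Standardized feature matrix or tibble.
#' @param time,event Outcomes of the fold.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @return A tibble of features sorted by descending importance.
#' @export
rank_by_univariate_cindex <- function(x, time, event, n_boot = 500, seed = 1) {
  if (!is.matrix(x)) x <- feature_matrix(x)
  assert_that(sum(event) >= 2, "need at least two events")
  bootstrap_filter_rank(x, time, event, univariate_cindex_scores, n_boot, seed)
}

#' Bootstrap-aggregated mutual-information feature ranking
#'
#' Mutual information between each feature and the observed time, estimated
#' with the k-nearest-neighbour estimator (k = 3) on event cases only (all
#' cases, with a warning, when fewer than 5 events are available), aggregated
#' across bootstraps exactly like the C-index filter.
#'
#' @inheritParams rank_by_univariate_cindex
#' @param k Number of neighbours for the estimator (default 3).
#' @return A tibble of features sorted by descending importance.
#' @export
rank_by_mutual_info <- function(x, time, event, n_boot = 500, seed = 1, k = 3) {
  if (!is.matrix(x)) x <- feature_matrix(x)
  assert_that(sum(event) >= 2, "need at least two events")
  warned <- FALSE
  score_fun <- function(xb, tb, eb) {
    if (sum(eb) >= 5) {
      keep <- eb == 1
    } else {
      if (!warned) {
        warn("fewer than 5 events in resample: mutual information uses all cases")
        warned <<- TRUE
      }
      keep <- rep(TRUE, length(eb))
    }
    apply(xb[keep, , drop = FALSE], 2, knn_mutual_information,
          y = tb[keep], k = k)
  }
  bootstrap_filter_rank(x, time, event, score_fun, n_boot, seed)
}

#' LASSO Cox feature selection
#'
#' Computes the L1-penalized Cox regularization path and returns, at the
#' largest penalty yielding at least \code{k} nonzero coefficients, the
#' \code{k} features with largest absolute coefficient. If the path never
#' reaches \code{k} nonzero coefficients, all features that are nonzero at
#' the smallest penalty are returned with a warning.
#'
#' @param x Standardized feature matrix or tibble.
#' @param time,event Outcomes.
#' @param k Number of features to select.
#' @return Character vector of selected feature names.
#' @export
select_by_lasso_cox <- function(x, time, event, k) {
  if (!is.matrix(x)) x <- feature_matrix(x)
  assert_that(sum(event) >= 2, "need at least two events")
  if (ncol(x) == 1) return(colnames(x))
  if (k >= ncol(x)) k <- ncol(x)
  fit <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                        alpha = 1, nlambda = 100, standardize = FALSE)
  B <- as.matrix(fit$beta)
  nz <- colSums(B != 0)
  ok <- which(nz >= k)
  if (length(ok) == 0) {
    warn("LASSO path never reached k nonzero coefficients; returning the nonzero set at the smallest penalty")
    b <- B[, ncol(B)]
    return(sort(names(b)[b != 0]))
  }
  b <- B[, ok[1]]
  ord <- order(-abs(b), names(b))
  names(b)[ord][seq_len(k)]
}

#' Recursive feature elimination
#'
#' Repeatedly fits the given linear regressor and drops the feature with the
#' smallest absolute weight (one per step, ties dropping the
#' lexicographically last name) until \code{k} features remain. Because every
#' refit is deterministic, the k = 1 selection nests inside k = 2 inside
#' k = 3 for a fixed fold and estimator.
#'
#' @param x Standardized feature matrix or tibble.
#' @param time,event Outcomes.
#' @param k Number of features to keep.
#' @param regressor Regressor kind providing per-feature weights.
#' @param hyperparams Passed to \code{\link{fit_regressor}}.
#' @return Character vector of the surviving feature names (column order).
#' @export
select_by_rfe <- function(x, time, event, k, regressor = "svm",
                          hyperparams = list()) {
  if (!is.matrix(x)) x <- feature_matrix(x)
  current <- colnames(x)
  while (length(current) > k) {
    fit <- fit_regressor(regressor, x[, current, drop = FALSE], time, event,
                         hyperparams)
    aw <- abs(fit$coef)
    worst <- which(aw == min(aw))
    drop_name <- sort(names(aw)[worst], decreasing = TRUE)[1]
    current <- setdiff(current, drop_name)
  }
  current
}

#' Dispatch one of the four feature-selection methods
#'
#' @param kind \code{"cindex"}, \code{"mutual_info"}, \code{"lasso_cox"} or
#'   \code{"rfe"}.
#' @param x Standardized feature matrix or tibble.
#' @param time,event Outcomes.
#' @param k Number of features to select.
#' @param n_boot Bootstrap count for the filter methods (default 500).
#' @param seed Integer seed (filter methods).
#' @param regressor,hyperparams RFE estimator and its hyperparameters.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(kind = c("cindex", "mutual_info", "lasso_cox", "rfe"),
                            x, time, event, k, n_boot = 500, seed = 1,
                            regressor = "svm", hyperparams = list()) {
  kind <- match.arg(kind)
  if (!is.matrix(x)) x <- feature_matrix(x)
  k <- min(k, ncol(x))
  switch(kind,
    cindex = rank_by_univariate_cindex(x, time, event, n_boot, seed)$feature[seq_len(k)],
    mutual_info = rank_by_mutual_info(x, time, event, n_boot, seed)$feature[seq_len(k)],
    lasso_cox = select_by_lasso_cox(x, time, event, k),
    rfe = select_by_rfe(x, time, event, k, regressor, hyperparams))
}
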