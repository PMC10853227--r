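#' Cross-validation scheme
#'
#' @param n_folds Number of folds (>= 2; default 4).
#' @param n_repeats Number of repetitions with fresh fold assignments
#'   (default 25).
#' @param stratify_by_event Balance events across folds (default TRUE: tiny
#'   cohorts otherwise risk event-free test folds).
#' @param seed Integer master seed for the fold assignments.
#' @return A \code{cv_scheme} list.
#' @export
cv_scheme <- function(n_folds = 4, n_repeats = 25, stratify_by_event = TRUE,
                      seed = 1) {
  assert_that(n_folds >= 2, "n_folds must be at least 2")
  assert_that(n_repeats >= 1, "n_repeats must be at least 1")
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 stratify_by_event = stratify_by_event, seed = seed),
            class = "cv_scheme")
}

#' Stratified fold assignment
#'
#' Deals shuffled event and censored patients round-robin into folds so every
#' fold carries events whenever arithmetically possible.
#'
#' @param event Event indicator vector.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @param stratify Stratify by event status (default TRUE).
#' @return Integer fold id per patient.
#' @export
make_folds <- function(event, n_folds, seed = 1, stratify = TRUE) {
  n <- length(event)
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (grp in unique(event)) {
        idx <- sample(which(event == grp))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  })
}

#' Pipeline configuration
#'
#' Names the train-fold-fitted chain: consensus-clustering controls, the
#' feature-selection method with its target feature count, and the
#' time-to-event regressor with its hyperparameters.
#'
#' @param selector Selection method (\code{"cindex"}, \code{"mutual_info"},
#'   \code{"lasso_cox"}, \code{"rfe"}, or \code{"none"} to keep all medoids).
#' @param k Number of features to select (1-3 in the study design).
#' @param regressor Regressor kind (see \code{\link{fit_regressor}}).
#' @param hyperparams Regressor hyperparameters.
#' @param cluster Run consensus clustering before selection (default TRUE).
#' @param n_boot_cluster Consensus bootstrap count (default 500).
#' @param n_boot_filter Filter-selector bootstrap count (default 500).
#' @param co_threshold,spearman_threshold Clustering cut parameters.
#' @param restrict_features Optional character vector: run the pipeline on
#'   this fixed feature subset (used by the fine-tuned transfer stage).
#' @return A \code{ds_pipeline} list.
#' @export
ds_pipeline <- function(selector = "rfe", k = 1, regressor = "svm",
                        hyperparams = list(), cluster = TRUE,
                        n_boot_cluster = 500, n_boot_filter = 500,
                        co_threshold = 0.5, spearman_threshold = 0.9,
                        restrict_features = NULL) {
  structure(list(selector = selector, k = k, regressor = regressor,
                 hyperparams = hyperparams, cluster = cluster,
                 n_boot_cluster = n_boot_cluster,
                 n_boot_filter = n_boot_filter,
                 co_threshold = co_threshold,
                 spearman_threshold = spearman_threshold,
                 restrict_features = restrict_features),
            class = "ds_pipeline")
}

# Fit the full chain on one training fold and score one test fold.
fit_score_fold <- function(x_df, time, event, train_idx, pipeline, fold_seed) {
  test_idx <- setdiff(seq_along(time), train_idx)
  xtr <- x_df[train_idx, , drop = FALSE]
  if (!is.null(pipeline$restrict_features)) {
    keep <- c("patient_id", pipeline$restrict_features)
    missing_cols <- setdiff(pipeline$restrict_features, names(x_df))
    if (length(missing_cols) > 0) {
      abort(paste0("restricted features absent from the table: ",
                   paste(missing_cols, collapse = ", ")))
    }
    xtr <- xtr[intersect(keep, names(xtr))]
  }
  prep <- fit_preprocess(xtr, cluster = pipeline$cluster,
                         n_boot = pipeline$n_boot_cluster,
                         co_threshold = pipeline$co_threshold,
                         threshold = pipeline$spearman_threshold,
                         seed = fold_seed)
  ztr <- apply_preprocess(prep, xtr)
  ttr <- time[train_idx]; etr <- event[train_idx]

  selected <- if (pipeline$selector == "none" || ncol(ztr) <= pipeline$k) {
    colnames(ztr)
  } else {
    select_features(pipeline$selector, ztr, ttr, etr, k = pipeline$k,
                    n_boot = pipeline$n_boot_filter, seed = fold_seed,
                    regressor = pipeline$regressor,
                    hyperparams = pipeline$hyperparams)
  }

  model <- fit_regressor(pipeline$regressor, ztr[, selected, drop = FALSE],
                         ttr, etr, pipeline$hyperparams)
  zte <- apply_scaling(prep$scaling, x_df[test_idx, , drop = FALSE])
  risk_tr <- predict(model, ztr)
  risk_te <- predict(model, zte[, selected, drop = FALSE])
  tte <- time[test_idx]; ete <- event[test_idx]

  safe_c <- function(t, e, r) tryCatch(concordance_index(t, e, r),
                                       error = function(err) NA_real_)
  list(train_c = safe_c(ttr, etr, risk_tr),
       test_c = safe_c(tte, ete, risk_te),
       train_iauc = as.numeric(integrated_auc(ttr, etr, ttr, etr, risk_tr)),
       test_iauc = as.numeric(integrated_auc(ttr, etr, tte, ete, risk_te)),
       preprocess = prep, selected = selected, model = model)
}

#' Repeated stratified cross-validation of one pipeline
#'
#' Per repetition a fresh seeded event-stratified fold assignment is drawn;
#' within each fold all transforms (zero-variance removal, Z-scoring,
#' consensus clustering, feature selection) are fitted on the training part
#' only and the held-out part is scored. Folds whose test part has no event
#' are skipped and recorded.
#'
#' @param features Feature tibble (patient_id + numeric columns).
#' @param outcomes Outcome tibble (\code{patient_id}, \code{time},
#'   \code{event}) in the same patient order.
#' @param pipeline A \code{\link{ds_pipeline}}.
#' @param scheme A \code{\link{cv_scheme}}.
#' @param keep_folds Keep per-fold preprocessing models, selections and
#'   fitted models for the robustness report (default TRUE).
#' @return A \code{ds_cv} object: \code{$scores} tibble (one row per
#'   repetition x fold with train/test C-index and iAUC), \code{$folds}
#'   (per-fold details), the pipeline and the scheme.
#' @export
run_repeated_cv <- function(features, outcomes, pipeline, scheme,
                            keep_folds = TRUE) {
  assert_that(identical(features$patient_id, outcomes$patient_id),
              "features and outcomes must share patient order")
  time <- outcomes$time; event <- outcomes$event
  rows <- list(); folds <- list()
  for (r in seq_len(scheme$n_repeats)) {
    fold_id <- make_folds(event, scheme$n_folds,
                          seed = derive_seed(scheme$seed, r),
                          stratify = scheme$stratify_by_event)
    for (f in seq_len(scheme$n_folds)) {
      train_idx <- which(fold_id != f)
      status <- "ok"
      if (sum(event[-train_idx]) == 0 || sum(event[train_idx]) < 2) {
        res <- list(train_c = NA_real_, test_c = NA_real_,
                    train_iauc = NA_real_, test_iauc = NA_real_,
                    preprocess = NULL, selected = character(0), model = NULL)
        status <- "skipped_no_events"
      } else {
        res <- fit_score_fold(features, time, event, train_idx, pipeline,
                              fold_seed = derive_seed(scheme$seed, r, f))
      }
      rows[[length(rows) + 1]] <- tibble(
        rep = r, fold = f, status = status,
        train_cindex = res$train_c, test_cindex = res$test_c,
        train_iauc = res$train_iauc, test_iauc = res$test_iauc,
        selected = list(res$selected))
      if (keep_folds) {
        folds[[length(folds) + 1]] <- list(
          rep = r, fold = f, status = status, preprocess = res$preprocess,
          selected = res$selected, model = res$model, train_idx = train_idx)
      }
    }
  }
  structure(list(scores = dplyr::bind_rows(rows), folds = folds,
                 pipeline = pipeline, scheme = scheme),
            class = "ds_cv")
}

#' @export
print.ds_cv <- function(x, ...) {
  cat(sprintf("<ds_cv> %d folds x %d repeats; mean test C-index %.3f\n",
              x$scheme$n_folds, x$scheme$n_repeats,
              mean(x$scores$test_cindex, na.rm = TRUE)))
  invisible(x)
}

#' Tidy per-fold cross-validation scores
#'
#' @param x A \code{ds_cv}.
#' @param ... Unused.
#' @return The per-fold score tibble.
#' @export
tidy.ds_cv <- function(x, ...) x$scores

#' Bootstrap summary of a cross-validation run
#'
#' @param x A \code{ds_cv}.
#' @param n_boot,seed Passed to \code{\link{bootstrap_summary}}.
#' @param ... Unused.
#' @return One row per metric (test C-index, test iAUC) with bootstrap mean,
#'   SE and 95 percent CI.
#' @export
glance.ds_cv <- function(x, n_boot = 1000, seed = 1, ...) {
  dplyr::bind_rows(
    dplyr::mutate(bootstrap_summary(x$scores$test_cindex, n_boot, seed),
                  metric = "test_cindex", .before = 1),
    dplyr::mutate(bootstrap_summary(x$scores$test_iauc, n_boot, seed),
                  metric = "test_iauc", .before = 1))
}
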