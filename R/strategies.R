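#' Enumerate the selector x regressor x k model grid
#'
#' The study design crosses 4 feature-selection methods with 4 time-to-event
#' regressors (16 models), each run with 1, 2 and 3 selected features.
#'
#' @param selectors,regressors,k Character/integer vectors to cross.
#' @return A tibble with one row per grid cell.
#' @export
model_grid <- function(selectors = c("cindex", "mutual_info", "lasso_cox", "rfe"),
                       regressors = c("coxph", "coxnet", "svm", "gb_linear"),
                       k = 1:3) {
  tidyr::expand_grid(selector = selectors, regressor = regressors, k = k)
}

#' Run the default strategy on a paired cohort
#'
#' For every feature-set kind x source x selector x regressor x k cell the
#' pipeline is evaluated by repeated stratified cross-validation with fixed
#' hyperparameters. One-sided Mann-Whitney comparisons (delta vs
#' single-time-point radiomics, and radiomics vs conventional within each
#' delta kind) are computed on the per-fold test C-indices and
#' Benjamini-Hochberg corrected across the whole comparison family.
#'
#' @param cohort A \code{ds_cohort}.
#' @param kinds Feature-set kinds to run (default all five).
#' @param sources \code{"radiomics"}, \code{"conventional"} or both.
#' @param grid Model grid (default the full 4 x 4 x \{1,2,3\} grid).
#' @param scheme CV scheme (default 4 folds x 25 repeats).
#' @param n_boot_cluster,n_boot_filter Bootstrap counts of the clustering and
#'   filter-selection steps (defaults 500).
#' @param hyperparams Named list of per-regressor hyperparameter lists.
#' @param keep_folds Keep fold details of every cell (needed for robustness
#'   reports; default FALSE keeps only the cell named by
#'   \code{robustness_cell}).
#' @param robustness_cell A list like \code{list(kind = "delta_abs", source =
#'   "radiomics", selector = "rfe", regressor = "svm", k = 1)} whose fold
#'   details are always kept.
#' @return A \code{ds_strategy} object with \code{$results} (one row per
#'   cell: mean scores, bootstrap summary columns, the \code{ds_cv} in a
#'   list column where kept) and \code{$comparisons}.
#' @export
run_default_strategy <- function(cohort,
                                 kinds = c("stp", "delta_abs", "delta_rel",
                                           "wdelta_abs", "wdelta_rel"),
                                 sources = c("radiomics", "conventional"),
                                 grid = model_grid(),
                                 scheme = cv_scheme(4, 25, seed = 1),
                                 n_boot_cluster = 500, n_boot_filter = 500,
                                 hyperparams = list(),
                                 keep_folds = FALSE,
                                 robustness_cell = list(kind = "delta_abs",
                                                        source = "radiomics",
                                                        selector = "rfe",
                                                        regressor = "svm",
                                                        k = 1)) {
  tables <- list()
  for (kind in kinds) for (src in sources) {
    tables[[paste(kind, src, sep = ".")]] <-
      build_feature_set(cohort, kind, src)
  }
  cells <- tidyr::expand_grid(kind = kinds, source = sources) |>
    tidyr::crossing(grid)

  res <- purrr::pmap(cells, function(kind, source, selector, regressor, k) {
    keep <- keep_folds ||
      (!is.null(robustness_cell) &&
         identical(robustness_cell,
                   list(kind = kind, source = source, selector = selector,
                        regressor = regressor, k = k)))
    pipe <- ds_pipeline(selector = selector, k = k, regressor = regressor,
                        hyperparams = hyperparams[[regressor]] %||% list(),
                        n_boot_cluster = n_boot_cluster,
                        n_boot_filter = n_boot_filter)
    cv <- run_repeated_cv(tables[[paste(kind, source, sep = ".")]],
                          cohort$outcomes, pipe, scheme, keep_folds = keep)
    sm <- bootstrap_summary(cv$scores$test_cindex, seed = scheme$seed)
    fold_scores <- cv$scores$test_cindex
    tibble(kind = kind, source = source, selector = selector,
           regressor = regressor, k = k,
           mean_test_cindex = mean(fold_scores, na.rm = TRUE),
           mean_test_iauc = mean(cv$scores$test_iauc, na.rm = TRUE),
           boot_mean = sm$mean, boot_se = sm$se,
           ci_lower = sm$ci_lower, ci_upper = sm$ci_upper,
           scores = list(fold_scores),
           cv = list(if (keep) cv else NULL))
  }) |> dplyr::bind_rows()

  comparisons <- default_strategy_comparisons(res)
  structure(list(results = res, comparisons = comparisons, scheme = scheme,
                 robustness_cell = robustness_cell),
            class = "ds_strategy")
}

# Build the delta-vs-STP and radiomics-vs-conventional comparison family and
# BH-correct it.
default_strategy_comparisons <- function(res) {
  delta_kinds <- intersect(unique(res$kind),
                           c("delta_abs", "delta_rel", "wdelta_abs", "wdelta_rel"))
  out <- list()
  cells <- dplyr::distinct(res[c("selector", "regressor", "k")])
  get_scores <- function(kind, source, sel, reg, kk) {
    row <- dplyr::filter(res, .data$kind == !!kind, .data$source == !!source,
                         .data$selector == sel, .data$regressor == reg,
                         .data$k == kk)
    if (nrow(row) == 0) NULL else row$scores[[1]]
  }
  for (i in seq_len(nrow(cells))) {
    sel <- cells$selector[i]; reg <- cells$regressor[i]; kk <- cells$k[i]
    stp <- get_scores("stp", "radiomics", sel, reg, kk)
    for (dk in delta_kinds) {
      dr <- get_scores(dk, "radiomics", sel, reg, kk)
      if (!is.null(dr) && !is.null(stp)) {
        out[[length(out) + 1]] <- dplyr::mutate(
          compare_models(dr, stp,
                         label = sprintf("%s_radiomics>stp_radiomics|%s+%s k=%d",
                                         dk, sel, reg, kk)),
          selector = sel, regressor = reg, k = kk, comparison = "delta_vs_stp",
          kind = dk)
      }
      dc <- get_scores(dk, "conventional", sel, reg, kk)
      if (!is.null(dr) && !is.null(dc)) {
        out[[length(out) + 1]] <- dplyr::mutate(
          compare_models(dr, dc,
                         label = sprintf("%s_radiomics>%s_conventional|%s+%s k=%d",
                                         dk, dk, sel, reg, kk)),
          selector = sel, regressor = reg, k = kk,
          comparison = "radiomics_vs_conventional", kind = dk)
      }
    }
  }
  if (length(out) == 0) return(tibble())
  cmp <- dplyr::bind_rows(out)
  cmp$p_adj <- bh_adjust(cmp$p)
  cmp
}

#' Baseline models on conventional features
#'
#' A Cox proportional-hazards model on all conventional features, plus the
#' four univariate Cox models on the absolute and relative change of
#' \code{conv_TBR_max} and \code{conv_TBR_mean}, all evaluated with the same
#' cross-validation machinery.
#'
#' @param cohort A \code{ds_cohort} with \code{conv_}-prefixed columns.
#' @param scheme CV scheme.
#' @return A tibble with one row per baseline model (label, mean scores,
#'   bootstrap summary, per-fold score list column).
#' @export
run_baseline <- function(cohort, scheme = cv_scheme(4, 25, seed = 1)) {
  conv1 <- split_sources(cohort$features1)$conventional
  assert_that(ncol(conv1) > 1, "cohort has no conventional features")
  need <- c("conv_TBR_max", "conv_TBR_mean")
  missing_cols <- setdiff(need, names(conv1))
  if (length(missing_cols) > 0) {
    abort(paste0("missing TBR columns: ", paste(missing_cols, collapse = ", ")))
  }
  rows <- list()
  run1 <- function(tab, label, pipe) {
    cv <- run_repeated_cv(tab, cohort$outcomes, pipe, scheme, keep_folds = FALSE)
    sm <- bootstrap_summary(cv$scores$test_cindex, seed = scheme$seed)
    tibble(label = label,
           mean_test_cindex = mean(cv$scores$test_cindex, na.rm = TRUE),
           mean_test_iauc = mean(cv$scores$test_iauc, na.rm = TRUE),
           boot_mean = sm$mean, boot_se = sm$se,
           ci_lower = sm$ci_lower, ci_upper = sm$ci_upper,
           scores = list(cv$scores$test_cindex))
  }
  conv_all <- build_feature_set(cohort, "delta_abs", "conventional")
  rows[["baseline"]] <- run1(
    build_feature_set(cohort, "stp", "conventional"), "baseline_coxph_conventional",
    ds_pipeline(selector = "none", k = 99, regressor = "coxph", cluster = FALSE))
  for (kind in c("delta_abs", "delta_rel")) {
    tab <- build_feature_set(cohort, kind, "conventional")
    for (feat in need) {
      rows[[paste(kind, feat)]] <- run1(
        tab[c("patient_id", feat)],
        paste0("univariate_", kind, "_", sub("conv_", "", feat)),
        ds_pipeline(selector = "none", k = 1, regressor = "coxph",
                    cluster = FALSE))
    }
  }
  dplyr::bind_rows(rows)
}

#' Gaussian-process Bayesian hyperparameter search
#'
#' Expected-improvement search with a radial-basis-function Gaussian-process
#' surrogate over a declared hyperparameter space, maximizing a user
#' objective (typically the mean cross-validated test C-index). The budget is
#' exact: the objective is evaluated \code{n_iter} times (an initial Latin
#' hypercube design followed by EI-chosen points); the full trial log is
#' returned.
#'
#' @param objective Function taking a named list of hyperparameter values and
#'   returning a scalar to maximize.
#' @param space Named list of parameter descriptors, each
#'   \code{list(type = "lin"|"log"|"int", lower =, upper =)}.
#' @param n_iter Total objective evaluations (default 100).
#' @param n_init Initial space-filling design size (default
#'   \code{min(10, n_iter)}).
#' @param seed Integer seed.
#' @return A list: \code{best} (named hyperparameter list), \code{best_value}
#'   and \code{trials} (tibble with one row per evaluation).
#' @export
bayesian_optimize <- function(objective, space, n_iter = 100,
                              n_init = min(10, n_iter), seed = 1) {
  pnames <- names(space)
  d <- length(space)
  from_unit <- function(u) {
    u <- unname(u)
    out <- list()
    for (j in seq_len(d)) {
      sp <- space[[j]]
      v <- switch(sp$type,
        lin = sp$lower + u[j] * (sp$upper - sp$lower),
        log = exp(log(sp$lower) + u[j] * (log(sp$upper) - log(sp$lower))),
        int = as.integer(round(sp$lower + u[j] * (sp$upper - sp$lower))))
      out[[pnames[j]]] <- v
    }
    out
  }
  with_seed(seed, {
    U <- if (requireNamespace("lhs", quietly = TRUE)) {
      lhs::maximinLHS(n_init, d)
    } else {
      matrix(runif(n_init * d), n_init, d)
    }
    y <- numeric(0)
    X <- matrix(numeric(0), 0, d)
    trials <- list()
    evaluate <- function(u) {
      hp <- from_unit(u)
      val <- objective(hp)
      X <<- rbind(X, u); y <<- c(y, val)
      trials[[length(trials) + 1]] <<- tibble(
        iteration = length(y), value = val, !!!hp)
      val
    }
    for (i in seq_len(min(n_init, n_iter))) evaluate(U[i, ])

    ei <- function(mu, s, best) {
      s <- pmax(s, 1e-12)
      z <- (mu - best) / s
      (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
    }
    while (length(y) < n_iter) {
      # GP surrogate on the unit cube, RBF kernel, median-heuristic lengthscale
      if (sd(y) == 0) { evaluate(runif(d)); next }
      ys <- (y - mean(y)) / sd(y)
      D2 <- as.matrix(dist(X))^2
      ell2 <- median(D2[D2 > 0])
      if (!is.finite(ell2) || ell2 <= 0) ell2 <- 1
      K <- exp(-D2 / (2 * ell2)) + diag(1e-6 + 1e-4, nrow(X))
      Kinv_y <- tryCatch(solve(K, ys), error = function(e) NULL)
      if (is.null(Kinv_y)) { evaluate(runif(d)); next }
      cand <- matrix(runif(500 * d), 500, d)
      D2c <- outer(rowSums(cand^2), rowSums(X^2), "+") - 2 * cand %*% t(X)
      Kc <- exp(-pmax(D2c, 0) / (2 * ell2))
      mu <- drop(Kc %*% Kinv_y)
      Kinv <- tryCatch(solve(K), error = function(e) NULL)
      s2 <- if (is.null(Kinv)) rep(1, nrow(cand)) else
        pmax(1 - rowSums((Kc %*% Kinv) * Kc), 0)
      scores <- ei(mu, sqrt(s2), max(ys))
      evaluate(cand[which.max(scores), ])
    }
    trials <- dplyr::bind_rows(trials)
    best_i <- which.max(trials$value)
    list(best = from_unit(X[best_i, ]), best_value = trials$value[best_i],
         trials = trials)
  })
}

#' Exact SHAP importance ranking across cross-validation folds
#'
#' Computes linear SHAP attributions of every kept fold model on its own
#' training rows (the fold's training means as background) and ranks
#' features by the mean absolute attribution across rows and folds; features
#' not selected in a fold contribute zero there.
#'
#' @param cv A \code{ds_cv} run with \code{keep_folds = TRUE}.
#' @param features The feature tibble the CV was run on.
#' @return A list: \code{ranking} tibble (feature, mean_abs_shap) and
#'   \code{per_fold} tibble of per-fold mean absolute attributions.
#' @export
shap_rank <- function(cv, features) {
  folds <- purrr::keep(cv$folds, ~ !is.null(.x$model))
  assert_that(length(folds) > 0, "no fitted fold models (run with keep_folds = TRUE)")
  all_feats <- unique(unlist(purrr::map(folds, ~ .x$preprocess$scaling$kept)))
  per_fold <- purrr::imap(folds, function(fd, i) {
    ztr <- apply_scaling(fd$preprocess$scaling,
                         features[fd$train_idx, , drop = FALSE])
    phi <- shap_values(fd$model, ztr[, fd$selected, drop = FALSE])
    v <- setNames(rep(0, length(all_feats)), all_feats)
    v[colnames(phi)] <- colMeans(abs(phi))
    tibble(fold_index = i, feature = names(v), mean_abs_shap = unname(v))
  }) |> dplyr::bind_rows()
  ranking <- per_fold |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_abs_shap = mean(.data$mean_abs_shap), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap), .data$feature)
  list(ranking = ranking, per_fold = per_fold)
}

#' Clustering-robustness report across cross-validation folds
#'
#' Mean pairwise adjusted Rand index over all training-fold partitions
#' (computed on the intersection of surviving features when folds differ,
#' flagged), and — with the first fold as reference — the percentage of folds
#' in which each reference cluster's medoid is also the medoid of its
#' maximum-Jaccard matching cluster.
#'
#' @param cv A \code{ds_cv} run with \code{keep_folds = TRUE}.
#' @return A list: \code{mean_ari}, \code{medoid_consistency} tibble
#'   (reference cluster, medoid, percent of folds), \code{flagged} (TRUE when
#'   fold feature sets differed).
#' @export
robustness_report <- function(cv) {
  folds <- purrr::keep(cv$folds, ~ !is.null(.x$preprocess))
  assert_that(length(folds) >= 2, "need at least two folds with stored partitions")
  parts <- purrr::map(folds, ~ .x$preprocess$partition)

  flagged <- FALSE
  n <- length(parts)
  aris <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(names(parts[[i]]), names(parts[[j]]))
    if (length(common) < length(parts[[i]]) ||
        length(common) < length(parts[[j]])) flagged <- TRUE
    if (length(common) >= 2) {
      aris <- c(aris, adjusted_rand_index(parts[[i]][common], parts[[j]][common]))
    }
  }

  ref <- folds[[1]]
  ref_part <- ref$preprocess$partition
  ref_medoids <- ref$preprocess$medoids
  ref_clusters <- sort(unique(ref_part))
  cons <- purrr::map(ref_clusters, function(cid) {
    members <- names(ref_part)[ref_part == cid]
    medoid <- ref_medoids[cid]
    hits <- vapply(folds[-1], function(fd) {
      part <- fd$preprocess$partition
      jac <- vapply(sort(unique(part)), function(c2) {
        m2 <- names(part)[part == c2]
        length(intersect(members, m2)) / length(union(members, m2))
      }, numeric(1))
      best <- sort(unique(part))[which.max(jac)]
      isTRUE(fd$preprocess$medoids[best] == medoid)
    }, logical(1))
    tibble(ref_cluster = cid, medoid = unname(medoid), size = length(members),
           consistency_pct = 100 * mean(hits))
  }) |> dplyr::bind_rows()

  list(mean_ari = mean(aris), medoid_consistency = cons, flagged = flagged)
}

#' Run the two-stage fine-tuned strategy
#'
#' Stage 1 works on the larger single-scan cohort: hyperparameters are
#' optimized by Gaussian-process search maximizing the mean cross-validated
#' test C-index of the single-time-point pipeline, and single-time-point
#' features are then ranked by their SHAP importance across the stage-1
#' folds. Stage 2 transfers both to the paired cohort: each feature-set kind
#' is rebuilt restricted to the top 1, 2 and 3 stage-1 features (delta kinds
#' take the delta of those named features) and evaluated with the stage-2
#' cross-validation scheme under the stage-1 hyperparameters.
#'
#' @param single_features,single_outcomes Stage-1 single-scan feature table
#'   and outcomes (e.g. from \code{\link{single_scan_cohort}} of a larger
#'   cohort).
#' @param paired_cohort Stage-2 paired \code{ds_cohort}.
#' @param selector,regressor Model combination to run.
#' @param search_space Hyperparameter space for \code{\link{bayesian_optimize}}
#'   (default a log-uniform space per regressor kind).
#' @param n_iter Bayesian-search budget (default 100 objective evaluations).
#' @param stage1_scheme CV scheme of stage 1 (default 7 folds x 20 repeats).
#' @param stage2_scheme CV scheme of stage 2 (default 4 folds x 25 repeats).
#' @param kinds Stage-2 feature-set kinds.
#' @param k_values Numbers of top-ranked features to transfer (default 1:3).
#' @param n_boot_cluster,n_boot_filter Stage-1 pipeline bootstrap counts.
#' @param seed Master seed.
#' @return A \code{ds_finetuned} list: \code{best_hyperparams},
#'   \code{search}, \code{stage1_ranking}, \code{stage2} results tibble.
#' @export
run_fine_tuned_strategy <- function(single_features, single_outcomes,
                                    paired_cohort,
                                    selector = "rfe", regressor = "svm",
                                    search_space = NULL, n_iter = 100,
                                    stage1_scheme = cv_scheme(7, 20, seed = 11),
                                    stage2_scheme = cv_scheme(4, 25, seed = 12),
                                    kinds = c("stp", "delta_abs", "delta_rel",
                                              "wdelta_abs", "wdelta_rel"),
                                    k_values = 1:3,
                                    n_boot_cluster = 500, n_boot_filter = 500,
                                    seed = 1) {
  if (is.null(search_space)) search_space <- default_search_space(regressor)

  stage1_cv <- function(hp, keep_folds = FALSE) {
    pipe <- ds_pipeline(selector = selector, k = max(k_values),
                        regressor = regressor, hyperparams = hp,
                        n_boot_cluster = n_boot_cluster,
                        n_boot_filter = n_boot_filter)
    run_repeated_cv(single_features, single_outcomes, pipe, stage1_scheme,
                    keep_folds = keep_folds)
  }
  search <- bayesian_optimize(
    function(hp) {
      cv <- stage1_cv(hp)
      mean(cv$scores$test_cindex, na.rm = TRUE)
    },
    space = search_space, n_iter = n_iter, seed = seed)

  cv1 <- stage1_cv(search$best, keep_folds = TRUE)
  ranking <- shap_rank(cv1, single_features)$ranking
  top <- ranking$feature[ranking$mean_abs_shap > 0]
  assert_that(length(top) >= 1, "stage 1 produced no ranked features")

  paired_names <- setdiff(names(paired_cohort$features1), "patient_id")
  if (length(intersect(top, paired_names)) == 0) {
    abort(paste0("stage-1 top features absent from the paired cohort: ",
                 paste(utils::head(top, 3), collapse = ", ")))
  }

  stage2 <- purrr::map(k_values, function(kk) {
    feats <- utils::head(top, kk)
    missing_cols <- setdiff(feats, paired_names)
    if (length(missing_cols) > 0) {
      abort(paste0("stage-1 top features absent from the paired cohort: ",
                   paste(missing_cols, collapse = ", ")))
    }
    purrr::map(kinds, function(kind) {
      tab <- build_feature_set(paired_cohort, kind, "all")
      tab <- tab[c("patient_id", intersect(feats, names(tab)))]
      pipe <- ds_pipeline(selector = "none", k = kk, regressor = regressor,
                          hyperparams = search$best, cluster = FALSE)
      cv <- run_repeated_cv(tab, paired_cohort$outcomes, pipe, stage2_scheme,
                            keep_folds = FALSE)
      sm <- bootstrap_summary(cv$scores$test_cindex, seed = stage2_scheme$seed)
      tibble(kind = kind, k = kk, features = list(feats),
             mean_test_cindex = mean(cv$scores$test_cindex, na.rm = TRUE),
             boot_mean = sm$mean, ci_lower = sm$ci_lower,
             ci_upper = sm$ci_upper,
             scores = list(cv$scores$test_cindex))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  structure(list(best_hyperparams = search$best, search = search,
                 stage1_ranking = ranking, stage2 = stage2),
            class = "ds_finetuned")
}

# Config-declared search spaces per regressor kind.
default_search_space <- function(regressor) {
  switch(regressor,
    coxph = list(ridge_theta = list(type = "log", lower = 1e-6, upper = 1)),
    coxnet = list(penalty = list(type = "log", lower = 1e-4, upper = 1),
                  l1_ratio = list(type = "lin", lower = 0.05, upper = 0.95)),
    svm = list(alpha = list(type = "log", lower = 1e-3, upper = 100)),
    gb_linear = list(n_estimators = list(type = "int", lower = 20, upper = 300),
                     learning_rate = list(type = "log", lower = 0.01, upper = 0.5)),
    abort(paste0("no default search space for regressor ", regressor)))
}
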