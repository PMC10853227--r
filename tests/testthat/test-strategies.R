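test_that("the model grid enumerates the full selector x regressor x k cross-product", {
  g <- model_grid()
  expect_equal(nrow(g), 4 * 4 * 3)
  expect_equal(nrow(dplyr::distinct(g)), 48)
  expect_setequal(unique(g$selector), c("cindex", "mutual_info", "lasso_cox", "rfe"))
  expect_setequal(unique(g$regressor), c("coxph", "coxnet", "svm", "gb_linear"))
  expect_setequal(unique(g$k), 1:3)
})

test_that("the default strategy runs a reduced grid end to end with comparisons", {
  coh <- quiet_cohort(n_patients = 18, seed = 23)
  st <- run_default_strategy(
    coh, kinds = c("stp", "delta_abs"), sources = c("radiomics", "conventional"),
    grid = model_grid(selectors = "rfe", regressors = "svm", k = 1),
    scheme = cv_scheme(4, 2, seed = 3),
    n_boot_cluster = 25, n_boot_filter = 25)
  expect_equal(nrow(st$results), 4)
  expect_true(all(st$results$mean_test_cindex >= 0 &
                    st$results$mean_test_cindex <= 1))
  # delta-vs-stp and radiomics-vs-conventional comparisons, BH-corrected
  expect_equal(nrow(st$comparisons), 2)
  expect_true(all(st$comparisons$p_adj >= st$comparisons$p))
  # the robustness cell's folds were kept
  cell <- dplyr::filter(st$results, kind == "delta_abs", source == "radiomics")
  expect_false(is.null(cell$cv[[1]]))
  p <- plot_cindex_heatmap(st)
  expect_s3_class(p, "ggplot")
})

test_that("baseline models cover the multivariate and four univariate delta-TBR fits", {
  coh <- quiet_cohort(n_patients = 18, seed = 24)
  bl <- run_baseline(coh, cv_scheme(4, 2, seed = 5))
  expect_equal(nrow(bl), 5)
  expect_setequal(
    bl$label,
    c("baseline_coxph_conventional",
      "univariate_delta_abs_TBR_max", "univariate_delta_abs_TBR_mean",
      "univariate_delta_rel_TBR_max", "univariate_delta_rel_TBR_mean"))
  coh_noconv <- coh
  coh_noconv$features0 <- split_sources(coh$features0)$radiomics
  coh_noconv$features1 <- split_sources(coh$features1)$radiomics
  expect_error(run_baseline(coh_noconv), "conventional")
})

test_that("Bayesian optimization honours its budget and finds a convex optimum", {
  # single-point space: one evaluation, that point returned
  one <- bayesian_optimize(function(hp) hp$a,
                           list(a = list(type = "lin", lower = 3, upper = 3)),
                           n_iter = 1, seed = 1)
  expect_equal(nrow(one$trials), 1)
  expect_equal(one$best$a, 3)
  # exact budget
  res <- bayesian_optimize(function(hp) -(log10(hp$a) + 2)^2,
                           list(a = list(type = "log", lower = 1e-4, upper = 1)),
                           n_iter = 40, seed = 7)
  expect_equal(nrow(res$trials), 40)
  # convex 1-D response: best found lies in the top decile of a 50-point grid
  grid <- 10^seq(-4, 0, length.out = 50)
  grid_vals <- -(log10(grid) + 2)^2
  expect_gte(res$best_value, sort(grid_vals, decreasing = TRUE)[5])
  # determinism
  res2 <- bayesian_optimize(function(hp) -(log10(hp$a) + 2)^2,
                            list(a = list(type = "log", lower = 1e-4, upper = 1)),
                            n_iter = 40, seed = 7)
  expect_identical(res$trials, res2$trials)
})

test_that("SHAP ranking across folds puts the planted feature first", {
  coh <- quiet_cohort(n_patients = 18, seed = 25)
  tab <- build_feature_set(coh, "delta_abs", "radiomics")
  pipe <- ds_pipeline(selector = "rfe", k = 1, regressor = "svm",
                      n_boot_cluster = 25)
  cv <- run_repeated_cv(tab, coh$outcomes, pipe, cv_scheme(4, 3, seed = 6))
  sr <- shap_rank(cv, tab)
  expect_true(sr$ranking$feature[1] %in% coh$truth$planted_features)
  expect_true(all(sr$ranking$mean_abs_shap >= 0))
  expect_s3_class(plot_shap_importance(sr), "ggplot")
})

test_that("robustness reports reach ARI 1 with identical partitions and 0 when shuffled", {
  coh <- quiet_cohort(n_patients = 18, within_block_abs_spearman = 1, seed = 26)
  tab <- build_feature_set(coh, "delta_abs", "radiomics")
  pipe <- ds_pipeline(selector = "rfe", k = 1, regressor = "svm",
                      n_boot_cluster = 25)
  cv <- run_repeated_cv(tab, coh$outcomes, pipe, cv_scheme(4, 2, seed = 8))
  rr <- robustness_report(cv)
  # exact duplicate blocks: every fold recovers the same partition
  expect_equal(rr$mean_ari, 1)
  expect_true(all(rr$medoid_consistency$consistency_pct == 100))
  expect_s3_class(plot_medoid_consistency(rr), "ggplot")

  # random partitions average near zero
  set.seed(3)
  fake <- cv
  feats <- names(cv$folds[[1]]$preprocess$partition)
  fake$folds <- lapply(cv$folds, function(fd) {
    fd$preprocess$partition <- setNames(sample(1:6, length(feats), TRUE), feats)
    fd
  })
  expect_lt(abs(robustness_report(fake)$mean_ari), 0.1)
})

test_that("the fine-tuned strategy transfers stage-1 features and hyperparameters", {
  big <- quiet_cohort(n_patients = 35, seed = 27)
  small <- quiet_cohort(n_patients = 18, seed = 28)
  ss <- single_scan_cohort(big)
  ft <- run_fine_tuned_strategy(
    ss$features, ss$outcomes, small,
    selector = "rfe", regressor = "svm", n_iter = 4,
    stage1_scheme = cv_scheme(7, 1, seed = 1),
    stage2_scheme = cv_scheme(4, 2, seed = 2),
    kinds = c("stp", "delta_abs"), k_values = 1:3,
    n_boot_cluster = 25, n_boot_filter = 25, seed = 3)
  expect_equal(nrow(ft$search$trials), 4)
  expect_setequal(unique(ft$stage2$k), 1:3)
  expect_true(all(lengths(ft$stage2$features) == ft$stage2$k))
  expect_true(all(ft$stage2$mean_test_cindex >= 0 & ft$stage2$mean_test_cindex <= 1))

  # disjoint feature names must fail loudly
  renamed <- small
  names(renamed$features0) <- sub("^rad_", "other_", names(renamed$features0))
  names(renamed$features1) <- sub("^rad_", "other_", names(renamed$features1))
  names(renamed$features0) <- sub("^conv_", "oc_", names(renamed$features0))
  names(renamed$features1) <- sub("^conv_", "oc_", names(renamed$features1))
  expect_error(
    run_fine_tuned_strategy(ss$features, ss$outcomes, renamed,
                            selector = "rfe", regressor = "svm", n_iter = 2,
                            stage1_scheme = cv_scheme(7, 1, seed = 1),
                            stage2_scheme = cv_scheme(4, 1, seed = 2),
                            kinds = "delta_abs", k_values = 1,
                            n_boot_cluster = 10, n_boot_filter = 10, seed = 4),
    "absent")
})
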