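#' Heatmap of test C-indices across the model grid
#'
#' One tile per regressor (rows) x selector (columns), faceted by feature-set
#' kind, mirroring the usual presentation of a selector-by-regressor
#' performance grid.
#'
#' @param strategy A \code{ds_strategy} from \code{\link{run_default_strategy}}.
#' @param source Feature source to display (default \code{"radiomics"}).
#' @param k Feature count to display (default 1).
#' @return A ggplot object.
#' @export
plot_cindex_heatmap <- function(strategy, source = "radiomics", k = 1) {
  df <- dplyr::filter(strategy$results, .data$source == !!source, .data$k == !!k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selector, y = .data$regressor,
                                   fill = .data$mean_test_cindex)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_test_cindex)), size = 3) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1),
                                  low = "steelblue", mid = "white",
                                  high = "firebrick", name = "test C-index") +
    ggplot2::labs(x = "feature selection", y = "regressor",
                  title = sprintf("Test C-index (%s features, k = %d)", source, k))
}

#' Bar chart of SHAP feature importance
#'
#' @param shap A result of \code{\link{shap_rank}} (or its \code{ranking}
#'   tibble).
#' @param top_n Number of features to show (default 15).
#' @return A ggplot object.
#' @export
plot_shap_importance <- function(shap, top_n = 15) {
  rk <- if (is.data.frame(shap)) shap else shap$ranking
  rk <- utils::head(rk, top_n)
  ggplot2::ggplot(rk, ggplot2::aes(
    x = .data$mean_abs_shap,
    y = stats::reorder(.data$feature, .data$mean_abs_shap))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL,
                  title = "Feature importance across folds")
}

#' Bar chart of medoid consistency across folds
#'
#' @param robustness A result of \code{\link{robustness_report}}.
#' @return A ggplot object.
#' @export
plot_medoid_consistency <- function(robustness) {
  df <- robustness$medoid_consistency
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$consistency_pct,
    y = stats::reorder(.data$medoid, .data$consistency_pct))) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_vline(xintercept = 80, linetype = "dashed") +
    ggplot2::labs(x = "% of folds with the same medoid", y = "reference medoid",
                  title = sprintf("Medoid consistency (mean pairwise ARI = %.2f)",
                                  robustness$mean_ari))
}

#' Distribution of per-fold test scores of a cross-validation run
#'
#' @param object A \code{ds_cv}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ds_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores,
                            cols = c("test_cindex", "test_iauc"),
                            names_to = "metric", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "per-fold score", y = "count",
                  title = "Cross-validated score distribution")
}
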