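#' Fit the train-fold scaling transform
#'
#' Removes zero-variance features and stores the training-fold mean and
#' standard deviation (n - 1 convention) of the remaining ones. Applying the
#' model to any table — training or held-out — uses only the stored
#' statistics, so held-out rows can never influence the fit.
#'
#' @param train A feature tibble (patient_id + numeric columns) or matrix.
#' @return A \code{scaling_model} with fields \code{kept}, \code{center},
#'   \code{scale}, \code{dropped}.
#' @export
fit_scaling <- function(train) {
  x <- if (is.matrix(train)) train else feature_matrix(train)
  assert_that(nrow(x) >= 2, "need at least two training rows")
  sds <- apply(x, 2, sd)
  kept <- colnames(x)[sds > 0]
  if (length(kept) == 0) abort("all features have zero variance")
  structure(list(kept = kept,
                 center = colMeans(x[, kept, drop = FALSE]),
                 scale = sds[kept],
                 dropped = setdiff(colnames(x), kept)),
            class = "scaling_model")
}

#' Apply a fitted scaling model to a table
#'
#' @param model A \code{scaling_model}.
#' @param table Feature tibble or matrix (must contain the kept columns).
#' @return A numeric matrix of Z-scored kept features.
#' @export
apply_scaling <- function(model, table) {
  x <- if (is.matrix(table)) table else feature_matrix(table)
  missing_cols <- setdiff(model$kept, colnames(x))
  assert_that(length(missing_cols) == 0,
              paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  scale(x[, model$kept, drop = FALSE], center = model$center, scale = model$scale)[, , drop = FALSE]
}

# Absolute Spearman correlation with rank pre-transform; columns that are
# constant get zero similarity to everything (they cannot co-cluster).
abs_spearman <- function(x) {
  r <- apply(x, 2, rank)
  s <- suppressWarnings(abs(cor(r)))
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  s
}

#' Hierarchical Spearman clustering of features
#'
#' Agglomerative clustering with distance \code{1 - |Spearman rho|} and
#' complete linkage, cut at distance \code{1 - threshold}; with the default
#' threshold 0.9 every within-cluster feature pair therefore has
#' \code{|rho| >= 0.9}.
#'
#' @param x Feature matrix or tibble (rows = patients).
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @return Named integer vector of contiguous cluster ids (labelled in
#'   column order of first appearance).
#' @export
spearman_cluster <- function(x, threshold = 0.9) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  assert_that(ncol(m) >= 2, "need at least two features")
  s <- abs_spearman(m)
  hc <- fix_heights(hclust(as.dist(1 - s), method = "complete"))
  cl <- cutree(hc, h = 1 - threshold + 1e-12)
  relabel_partition(cl)
}

# cutree() requires sorted merge heights; average/complete linkage is
# monotone, so any inversion is floating-point noise — clamp it.
fix_heights <- function(hc) {
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  hc
}

# Contiguous relabelling in order of first appearance.
relabel_partition <- function(cl) {
  u <- unique(unname(cl))
  out <- match(cl, u)
  names(out) <- names(cl)
  out
}

#' Bootstrap consensus clustering of features
#'
#' Runs \code{\link{spearman_cluster}} on \code{n_boot} bootstrap resamples
#' of the patients (same size, with replacement), accumulates a
#' co-association matrix (the fraction of resamples placing each feature
#' pair in one cluster), and derives the final partition as the connected
#' components of the graph linking pairs whose co-association reaches
#' \code{co_threshold} (equivalently, single-linkage clustering on
#' \code{1 - co-association} cut at \code{1 - co_threshold}). A feature that
#' is constant in a resample cannot co-cluster in that resample (it
#' contributes a singleton).
#'
#' @param x Scaled feature matrix or tibble.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param co_threshold Co-association threshold for the final cut
#'   (default 0.5).
#' @param threshold Within-resample absolute-Spearman threshold (default 0.9).
#' @param seed Integer seed; the co-association matrix is deterministic
#'   per table + seed.
#' @return A list: \code{partition} (named contiguous ids),
#'   \code{coassociation} (symmetric matrix in \[0, 1\], unit diagonal).
#' @export
consensus_cluster <- function(x, n_boot = 500, co_threshold = 0.5,
                              threshold = 0.9, seed = 1) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  p <- ncol(m)
  assert_that(p >= 2, "need at least two features")
  n <- nrow(m)
  co <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      cl <- spearman_cluster(m[idx, , drop = FALSE], threshold)
      co <- co + outer(cl, cl, "==")
    }
  })
  co <- co / n_boot
  diag(co) <- 1
  hc <- fix_heights(hclust(as.dist(1 - co), method = "single"))
  part <- relabel_partition(cutree(hc, h = 1 - co_threshold + 1e-12))
  list(partition = part, coassociation = co)
}

#' Medoid feature of every cluster
#'
#' The medoid is the member maximizing the summed absolute Spearman
#' correlation to the other members of its cluster, computed on the full
#' training fold; singletons are their own medoid; exact ties break to the
#' lexicographically smallest feature name.
#'
#' @param partition Named cluster ids (from \code{\link{spearman_cluster}} or
#'   \code{\link{consensus_cluster}}).
#' @param x The training feature matrix or tibble the partition refers to.
#' @return Character vector of medoid names, one per cluster, ordered by
#'   cluster id.
#' @export
select_medoids <- function(partition, x) {
  m <- if (is.matrix(x)) x else feature_matrix(x)
  assert_that(all(names(partition) %in% colnames(m)),
              "partition names must match table columns")
  s <- abs_spearman(m[, names(partition), drop = FALSE])
  vapply(sort(unique(partition)), function(cid) {
    members <- sort(names(partition)[partition == cid])
    if (length(members) == 1) return(members)
    sims <- vapply(members, function(f) {
      sum(s[f, setdiff(members, f)])
    }, numeric(1))
    members[which.max(sims)]  # which.max takes the first = smallest name on ties
  }, character(1))
}

#' Fit the full preprocessing chain on a training fold
#'
#' Zero-variance removal, Z-scoring, bootstrap consensus Spearman clustering
#' and medoid extraction, all fitted on the training fold only.
#'
#' @param train Training feature tibble (patient_id + features) or matrix.
#' @param cluster Run the consensus clustering step (default TRUE); when
#'   FALSE all kept features become their own medoid.
#' @param n_boot,co_threshold,threshold,seed Consensus-clustering controls.
#' @return A \code{preprocess_model}: scaling statistics, \code{partition},
#'   \code{medoids}, \code{coassociation}.
#' @export
fit_preprocess <- function(train, cluster = TRUE, n_boot = 500,
                           co_threshold = 0.5, threshold = 0.9, seed = 1) {
  scaling <- fit_scaling(train)
  z <- apply_scaling(scaling, train)
  if (cluster && ncol(z) >= 2) {
    cc <- consensus_cluster(z, n_boot = n_boot, co_threshold = co_threshold,
                            threshold = threshold, seed = seed)
    medoids <- select_medoids(cc$partition, z)
    partition <- cc$partition
    coassoc <- cc$coassociation
  } else {
    partition <- setNames(seq_along(scaling$kept), scaling$kept)
    medoids <- scaling$kept
    coassoc <- NULL
  }
  structure(list(scaling = scaling, partition = partition, medoids = medoids,
                 coassociation = coassoc),
            class = "preprocess_model")
}

#' Apply a fitted preprocessing model
#'
#' @param model A \code{preprocess_model}.
#' @param table Any feature tibble/matrix containing the kept columns.
#' @param medoids_only Restrict the output to the cluster medoids
#'   (default TRUE).
#' @return Z-scored numeric matrix.
#' @export
apply_preprocess <- function(model, table, medoids_only = TRUE) {
  z <- apply_scaling(model$scaling, table)
  if (medoids_only) z[, model$medoids, drop = FALSE] else z
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("<preprocess_model> %d kept features, %d clusters, medoids: %s\n",
              length(x$scaling$kept), length(unique(x$partition)),
              paste(utils::head(x$medoids, 5), collapse = ", ")))
  invisible(x)
}
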