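#' Build one of the five analysis feature sets from a paired cohort
#'
#' Single-time-point uses the second scan as-is; delta-absolute is
#' \code{F1 - F0}; delta-relative is \code{(F1 - F0) / F0}; the weighted
#' variants divide the delta by the scan gap in months. Features whose
#' baseline value is (numerically) zero for any patient are dropped
#' cohort-wide under the relative kinds, with a warning, since per-patient
#' non-finite ratios would corrupt downstream standardization.
#'
#' @param cohort A \code{ds_cohort} (or any list with \code{features0},
#'   \code{features1} and \code{dates} in the same patient order).
#' @param kind One of \code{"stp"}, \code{"delta_abs"}, \code{"delta_rel"},
#'   \code{"wdelta_abs"}, \code{"wdelta_rel"}.
#' @param source \code{"all"}, \code{"radiomics"} or \code{"conventional"}
#'   (conventional columns carry the reserved \code{conv_} prefix).
#' @return A tibble: \code{patient_id} plus the transformed feature columns.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 1))
#' da <- build_feature_set(coh, "delta_abs", "radiomics")
build_feature_set <- function(cohort,
                              kind = c("stp", "delta_abs", "delta_rel",
                                       "wdelta_abs", "wdelta_rel"),
                              source = c("all", "radiomics", "conventional")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  f0 <- feature_matrix(cohort$features0)
  f1 <- feature_matrix(cohort$features1)
  assert_that(identical(colnames(f0), colnames(f1)),
              "feature sets differ between the two time points")
  assert_that(identical(cohort$features0$patient_id, cohort$features1$patient_id),
              "patient ordering differs between the two time points")

  gap <- NULL
  if (kind %in% c("wdelta_abs", "wdelta_rel")) {
    assert_that(!is.null(cohort$dates), "weighted kinds require acquisition dates")
    gap <- cohort$dates$t1_months - cohort$dates$t0_months
    assert_that(all(gap > 0), "scan gap must be positive for every patient")
  }

  x <- switch(kind,
    stp = f1,
    delta_abs = f1 - f0,
    delta_rel = ,
    wdelta_abs = ,
    wdelta_rel = {
      if (kind == "wdelta_abs") {
        sweep(f1 - f0, 1, gap, "/")
      } else {
        zero <- apply(abs(f0) < 1e-12, 2, any)
        if (any(zero)) {
          warn(paste0("dropping ", sum(zero),
                      " feature(s) with zero baseline under a relative kind: ",
                      paste(colnames(f0)[zero], collapse = ", ")))
          f0 <- f0[, !zero, drop = FALSE]
          f1 <- f1[, !zero, drop = FALSE]
        }
        r <- (f1 - f0) / f0
        if (kind == "wdelta_rel") r <- sweep(r, 1, gap, "/")
        r
      }
    })

  keep <- switch(source,
    all = colnames(x),
    radiomics = colnames(x)[!is_conventional(colnames(x))],
    conventional = colnames(x)[is_conventional(colnames(x))])
  as_tibble(cbind(data.frame(patient_id = cohort$features0$patient_id),
                  as.data.frame(x[, keep, drop = FALSE])))
}

#' Split a feature table into radiomics and conventional parts
#'
#' Conventional features are identified by the reserved \code{conv_} prefix;
#' the split is disjoint and exhaustive over the feature columns.
#'
#' @param table A feature tibble with a \code{patient_id} column.
#' @return A list with tibbles \code{radiomics} and \code{conventional}.
#' @export
split_sources <- function(table) {
  feats <- setdiff(names(table), "patient_id")
  bad <- feats[!vapply(table[feats], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("unknown non-numeric columns: ", paste(bad, collapse = ", ")))
  }
  conv <- feats[is_conventional(feats)]
  rad <- setdiff(feats, conv)
  list(radiomics = table[c("patient_id", rad)],
       conventional = table[c("patient_id", conv)])
}
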