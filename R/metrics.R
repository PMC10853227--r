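#' Harrell's concordance index for right-censored survival data
#'
#' The probability, over all comparable patient pairs, that the patient with
#' the higher predicted risk progresses first. A pair (i, j) is comparable
#' when \code{time[i] < time[j]} and patient i experienced the event; pairs
#' with tied times are not comparable. Tied risk scores receive 0.5 credit.
#'
#' @param time Numeric vector of follow-up times (months).
#' @param event Integer/logical vector; 1 = progression observed, 0 = censored.
#' @param risk Numeric risk scores; higher score = earlier predicted
#'   progression.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' concordance_index(c(5, 10, 15), c(1, 1, 1), c(3, 2, 1)) # 1
concordance_index <- function(time, event, risk) {
  n <- length(time)
  assert_that(length(event) == n && length(risk) == n,
              "time, event and risk must have equal length")
  assert_that(all(is.finite(time)) && all(is.finite(risk)),
              "times and risks must be finite")
  event <- as.integer(event)
  comp <- outer(time, time, "<") & (event == 1L)
  n_comp <- sum(comp)
  if (n_comp == 0) abort("concordance undefined: no comparable pairs")
  conc <- sum(comp & outer(risk, risk, ">")) +
    0.5 * sum(comp & outer(risk, risk, "=="))
  conc / n_comp
}

# Kaplan-Meier censoring-survival function G(t) fitted on a training fold;
# returns a right-continuous step function, floored away from zero.
censoring_survfit <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  if (length(fit$time) == 0) return(function(t) rep(1, length(t)))
  sf <- stats::stepfun(fit$time, c(1, fit$surv))
  function(t) pmax(sf(t), 1e-4)
}

#' Integrated time-dependent AUC with inverse censoring weights
#'
#' Cumulative/dynamic time-dependent AUC, weighted by the inverse probability
#' of censoring estimated on the training fold, evaluated on the grid of test
#' event times inside the 10th-90th percentile of observed test times and
#' integrated with the trapezoid rule (normalized by the grid span).
#'
#' @param train_time,train_event Training-fold outcomes used to estimate the
#'   censoring distribution.
#' @param time,event,risk Test-fold outcomes and risk scores.
#' @return The integrated AUC; if the evaluation grid has fewer than two
#'   points, the single-time AUC is returned with attribute
#'   \code{degenerate_grid = TRUE}.
#' @export
integrated_auc <- function(train_time, train_event, time, event, risk) {
  event <- as.integer(event)
  G <- censoring_survfit(train_time, train_event)
  qs <- quantile(time, c(0.1, 0.9), names = FALSE)
  grid <- sort(unique(time[event == 1L & time >= qs[1] & time <= qs[2]]))
  # large samples: 30 quantile-spaced evaluation times approximate the full
  # event-time grid to well below the metric's sampling noise
  if (length(grid) > 30) {
    grid <- sort(unique(quantile(grid, seq(0, 1, length.out = 30),
                                 names = FALSE, type = 1)))
  }

  auc_at <- function(t) {
    case <- which(time <= t & event == 1L)
    ctrl <- which(time > t)
    if (length(case) == 0 || length(ctrl) == 0) return(NA_real_)
    w <- 1 / G(pmax(time[case] - 1e-8, 0))^2
    gt <- outer(risk[case], risk[ctrl], ">")
    eq <- outer(risk[case], risk[ctrl], "==")
    num <- sum(w * (rowSums(gt) + 0.5 * rowSums(eq)))
    num / (sum(w) * length(ctrl))
  }

  if (length(grid) < 2) {
    t0 <- if (length(grid) == 1) grid else median(time)
    out <- auc_at(t0)
    if (is.na(out)) out <- 0.5
    attr(out, "degenerate_grid") <- TRUE
    return(out)
  }
  aucs <- vapply(grid, auc_at, numeric(1))
  keep <- !is.na(aucs)
  grid <- grid[keep]; aucs <- aucs[keep]
  if (length(grid) < 2) {
    out <- if (length(aucs)) aucs else 0.5
    attr(out, "degenerate_grid") <- TRUE
    return(out)
  }
  span <- grid[length(grid)] - grid[1]
  sum(diff(grid) * (utils::head(aucs, -1) + utils::tail(aucs, -1)) / 2) / span
}

#' Bootstrap summary of a cross-validation score distribution
#'
#' Resamples the per-fold score list with replacement and reports the mean of
#' bootstrap means, their standard deviation as standard error, and the 2.5
#' and 97.5 percent percentiles as a 95 percent confidence interval.
#'
#' @param scores Numeric vector of per-fold scores.
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble with columns \code{mean}, \code{se},
#'   \code{ci_lower}, \code{ci_upper}, \code{n_scores}.
#' @export
bootstrap_summary <- function(scores, n_boot = 1000, seed = 1) {
  scores <- scores[!is.na(scores)]
  assert_that(length(scores) >= 2, "need at least 2 scores")
  means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(sample(scores, length(scores), replace = TRUE))
    }, numeric(1))
  })
  ci <- quantile(means, c(0.025, 0.975), names = FALSE)
  tibble(mean = mean(means), se = sd(means),
         ci_lower = ci[1], ci_upper = ci[2], n_scores = length(scores))
}

#' One-sided Mann-Whitney U comparison of two score lists
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param alternative \code{"a_greater"} (default) or \code{"b_greater"}.
#' @param label Optional comparison label carried through to the result.
#' @return A one-row tibble with the U statistic, the one-sided p-value, the
#'   label and a \code{flagged} column (TRUE when all values are tied and the
#'   exact p = 0.5 convention is applied).
#' @export
compare_models <- function(scores_a, scores_b, alternative = c("a_greater", "b_greater"),
                           label = NA_character_) {
  alternative <- match.arg(alternative)
  assert_that(length(scores_a) > 0 && length(scores_b) > 0,
              "both score lists must be non-empty")
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    u <- length(scores_a) * length(scores_b) / 2
    return(tibble(label = label, u = u, p = 0.5, flagged = TRUE))
  }
  alt <- if (alternative == "a_greater") "greater" else "less"
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b, alternative = alt))
  tibble(label = label, u = unname(wt$statistic), p = wt$p.value, flagged = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions, about 0 for random
#' labelings, negative for discordant clusterings.
#'
#' @param a,b Cluster labelings (named vectors over the same items, or plain
#'   vectors of equal length in the same item order).
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    assert_that(setequal(names(a), names(b)),
                "partitions must cover the same items")
    b <- b[names(a)]
  }
  assert_that(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  n2 <- choose(length(a), 2)
  expected <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
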