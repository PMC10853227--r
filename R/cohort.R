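#' Specification of a synthetic paired-PET cohort
#'
#' Collects the generator's tunable conditions: cohort size, the block
#' structure of the radiomics-like features, the strength of the planted
#' prognostic delta signal, and the survival/censoring calibration targets.
#'
#' Features are drawn as latent-Gaussian blocks: each block shares one latent
#' factor so that any two features of a block have absolute Spearman
#' correlation \code{within_block_abs_spearman}. The second scan equals the
#' first plus a per-patient block-structured delta; only the planted block's
#' latent delta carries prognostic signal, entering the progression hazard as
#' \code{effect_size_beta} per standard deviation.
#'
#' @param n_patients Number of patients.
#' @param n_blocks,block_size Radiomics-like feature structure
#'   (\code{n_blocks * block_size} features in total).
#' @param within_block_abs_spearman Target absolute Spearman correlation of
#'   any two features within a block, in (0, 1].
#' @param effect_size_beta Log-hazard per SD of the planted block's latent
#'   delta.
#' @param planted_block_index Which block carries the signal (1-based).
#' @param event_target_fraction Expected fraction of patients progressing.
#' @param median_pfs_months Target marginal median progression-free survival.
#' @param scan_gap_months_range Range (months) of the PET0-to-PET1 gap.
#' @param n_conventional Number of \code{conv_}-prefixed conventional
#'   features (default 9).
#' @param delta_scale SD of the per-feature change relative to the SD of the
#'   baseline features (default 0.35: between-scan changes are small against
#'   between-patient heterogeneity, so single-time-point tables remain close
#'   to prognosis-free, matching the near-chance single-time-point
#'   performance the generator emulates).
#' @param weibull_shape Shape of the Weibull progression-time law
#'   (default 1.3, mildly increasing hazard).
#' @param baseline_location Location shift of the feature scale, keeping
#'   baseline values positive so that relative deltas are well defined.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_patients = 18, n_blocks = 6, block_size = 5,
                        within_block_abs_spearman = 0.95,
                        effect_size_beta = 1.5, planted_block_index = 1,
                        event_target_fraction = 0.89, median_pfs_months = 11,
                        scan_gap_months_range = c(3, 9),
                        n_conventional = 9, delta_scale = 0.35,
                        weibull_shape = 1.3, baseline_location = 5,
                        seed = 1) {
  assert_that(n_patients >= 2 && n_blocks >= 1 && block_size >= 1,
              "counts must be positive (n_patients >= 2)")
  assert_that(within_block_abs_spearman > 0 && within_block_abs_spearman <= 1,
              "within_block_abs_spearman must lie in (0, 1]")
  assert_that(planted_block_index >= 1 && planted_block_index <= n_blocks,
              "planted_block_index out of range")
  assert_that(event_target_fraction > 0 && event_target_fraction <= 1,
              "event_target_fraction must lie in (0, 1]")
  assert_that(median_pfs_months > 0, "median_pfs_months must be positive")
  assert_that(length(scan_gap_months_range) == 2 &&
                scan_gap_months_range[1] > 0 &&
                diff(scan_gap_months_range) >= 0,
              "scan_gap_months_range must be an increasing positive pair")
  structure(list(
    n_patients = n_patients, n_blocks = n_blocks, block_size = block_size,
    within_block_abs_spearman = within_block_abs_spearman,
    effect_size_beta = effect_size_beta,
    planted_block_index = planted_block_index,
    event_target_fraction = event_target_fraction,
    median_pfs_months = median_pfs_months,
    scan_gap_months_range = scan_gap_months_range,
    n_conventional = n_conventional, delta_scale = delta_scale,
    weibull_shape = weibull_shape, baseline_location = baseline_location,
    seed = seed
  ), class = "cohort_spec")
}

# Spearman -> Pearson conversion for bivariate normal marginals.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Median of log(-log U) - beta*D for U~Unif(0,1), D~N(0,1) independent;
# used to set the Weibull scale so the marginal median PFS hits its target
# for any effect size.
log_time_median_shift <- function(beta) {
  if (beta == 0) return(log(log(2)))
  cdf <- function(m) {
    integrate(function(d) (1 - exp(-exp(m + beta * d))) * dnorm(d),
              lower = -8, upper = 8)$value
  }
  uniroot(function(m) cdf(m) - 0.5, lower = -20, upper = 20)$root
}

#' Generate a synthetic paired-PET cohort
#'
#' Draws block-correlated baseline features, per-patient changes between the
#' two scans (only the planted block's change carries prognostic signal),
#' Weibull progression times whose marginal median matches the requested
#' median PFS, and mixed administrative/uniform censoring calibrated to the
#' requested event fraction. Conventional (\code{conv_}-prefixed) features
#' correlate with the planted block's baseline level, not with its change, so
#' that delta radiomics can outperform delta conventional features.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A \code{ds_cohort} list with tibbles \code{features0},
#'   \code{features1} (patient_id + features), \code{dates} (patient_id,
#'   t0_months, t1_months), \code{outcomes} (patient_id, time, event) and a
#'   \code{truth} record (planted block/features, beta, latent delta, linear
#'   predictor).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 18, seed = 7))
#' dim(coh$features0)
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  with_seed(spec$seed, {
    n <- spec$n_patients
    p_rad <- spec$n_blocks * spec$block_size
    rho_p <- spearman_to_pearson(spec$within_block_abs_spearman)
    a <- sqrt(rho_p)

    block_of <- rep(seq_len(spec$n_blocks), each = spec$block_size)
    rad_names <- sprintf("rad_b%02d_f%02d", block_of,
                         sequence(rep(spec$block_size, spec$n_blocks)))

    draw_block_matrix <- function() {
      L <- matrix(rnorm(n * spec$n_blocks), n, spec$n_blocks)
      eps <- matrix(rnorm(n * p_rad), n, p_rad)
      x <- a * L[, block_of, drop = FALSE] + sqrt(1 - rho_p) * eps
      list(x = x, latent = L)
    }

    base <- draw_block_matrix()
    delta <- draw_block_matrix()
    f0 <- spec$baseline_location + base$x
    f1 <- f0 + spec$delta_scale * delta$x

    # conventional features: tied to the planted block's baseline level only
    pb <- spec$planted_block_index
    conv_names <- c("conv_TBR_mean", "conv_TBR_max", "conv_TBR_peak",
                    "conv_TSR_mean", "conv_TSR_max", "conv_TSR_peak",
                    "conv_MTV", "conv_TTP_region", "conv_slope")
    if (spec$n_conventional != length(conv_names)) {
      conv_names <- sprintf("conv_f%02d", seq_len(spec$n_conventional))
    }
    nc <- spec$n_conventional
    conv0 <- 2 + 0.6 * base$latent[, pb] %o% rep(1, nc) +
      0.8 * matrix(rnorm(n * nc), n, nc)
    conv1 <- conv0 + 0.3 * matrix(rnorm(n * nc), n, nc)

    # survival: Weibull progression times, hazard scaled by exp(beta * D)
    lp <- spec$effect_size_beta * delta$latent[, pb]
    shift <- log_time_median_shift(spec$effect_size_beta)
    scale0 <- spec$median_pfs_months * exp(-shift / spec$weibull_shape)
    u <- runif(n)
    t_event <- scale0 * (-log(u) / exp(lp))^(1 / spec$weibull_shape)

    # censoring: administrative horizon + uniform random mix calibrated so
    # the expected realized event fraction matches the target; the horizon is
    # pushed out to the target quantile of the drawn progression times when a
    # strong effect disperses them beyond 2.5x the median
    admin <- max(2.5 * spec$median_pfs_months,
                 as.numeric(quantile(t_event,
                                     min(1, spec$event_target_fraction + 0.02))))
    p1 <- mean(t_event < admin)
    p2 <- mean(pmax(admin - t_event, 0) / admin)
    q <- if (p1 <= spec$event_target_fraction || p1 == p2) 0 else
      min(1, (p1 - spec$event_target_fraction) / (p1 - p2))
    in_mix <- runif(n) < q
    c_time <- ifelse(in_mix, runif(n, 0, admin), admin)
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    time <- pmax(time, 1e-3)

    t0 <- runif(n, 2, 4)
    gap <- runif(n, spec$scan_gap_months_range[1], spec$scan_gap_months_range[2])

    ids <- sprintf("P%03d", seq_len(n))
    mk <- function(m_rad, m_conv) {
      colnames(m_rad) <- rad_names; colnames(m_conv) <- conv_names
      as_tibble(cbind(data.frame(patient_id = ids), m_rad, m_conv))
    }
    structure(list(
      features0 = mk(f0, conv0),
      features1 = mk(f1, conv1),
      dates = tibble(patient_id = ids, t0_months = t0, t1_months = t0 + gap),
      outcomes = tibble(patient_id = ids, time = time, event = event),
      truth = list(planted_block = pb,
                   planted_features = rad_names[block_of == pb],
                   beta = spec$effect_size_beta,
                   latent_delta = delta$latent[, pb],
                   linear_predictor = lp,
                   event_time = t_event),
      spec = spec
    ), class = "ds_cohort")
  })
}

#' @export
print.ds_cohort <- function(x, ...) {
  p <- ncol(x$features0) - 1
  cat(sprintf("<ds_cohort> %d patients, %d features (%d conventional), %.0f%% events\n",
              nrow(x$features0), p, sum(is_conventional(names(x$features0))),
              100 * mean(x$outcomes$event)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes \code{features_pet0.csv}, \code{features_pet1.csv},
#' \code{outcomes.csv} (patient_id, pfs_months, event) and \code{dates.csv}
#' (patient_id, t0_months, t1_months) into \code{dir}.
#'
#' @param cohort A \code{ds_cohort}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("features_pet0.csv", "features_pet1.csv",
                            "outcomes.csv", "dates.csv"))
  utils::write.csv(cohort$features0, paths[1], row.names = FALSE)
  utils::write.csv(cohort$features1, paths[2], row.names = FALSE)
  out <- data.frame(patient_id = cohort$outcomes$patient_id,
                    pfs_months = cohort$outcomes$time,
                    event = cohort$outcomes$event)
  utils::write.csv(out, paths[3], row.names = FALSE)
  utils::write.csv(cohort$dates, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort previously written with \code{write_cohort}
#'
#' @param dir Directory containing the four CSV files.
#' @return A \code{ds_cohort} (without a truth record).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(dir, f),
                                              check.names = FALSE))
  out <- rd("outcomes.csv")
  structure(list(
    features0 = rd("features_pet0.csv"),
    features1 = rd("features_pet1.csv"),
    dates = rd("dates.csv"),
    outcomes = tibble(patient_id = out$patient_id,
                      time = out$pfs_months, event = out$event),
    truth = NULL, spec = NULL
  ), class = "ds_cohort")
}

#' Single-scan view of a cohort
#'
#' Returns the second-time-point feature table joined to the outcomes,
#' emulating patients with one PET scan at therapy discontinuation.
#'
#' @param cohort A \code{ds_cohort}.
#' @return A list with \code{features} (the PET1 table) and \code{outcomes}.
#' @export
single_scan_cohort <- function(cohort) {
  list(features = cohort$features1, outcomes = cohort$outcomes)
}
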