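#' Construct a parametric image container
#'
#' @param data 3-D numeric array.
#' @param spacing Voxel spacing in mm.
#' @param modality \code{"TBR"} (unitless ratio) or \code{"TTP"} (minutes).
#' @return A \code{ds_image}.
#' @export
ds_image <- function(data, spacing, modality = c("TBR", "TTP")) {
  modality <- match.arg(modality)
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "ds_image")
}

#' @export
print.ds_image <- function(x, ...) {
  cat(sprintf("<ds_image %s> %s @ %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

img_data <- function(x) if (inherits(x, "ds_image")) x$data else x

#' Static tumor-to-background-ratio (TBR) parametric image
#'
#' Normalizes a static image to the mean uptake of the healthy-brain
#' reference region, so the brain-mask mean of the result is exactly 1.
#'
#' @param static 3-D array (or \code{ds_image}) of static uptake.
#' @param brain_mask Logical array, non-empty, with positive mean uptake.
#' @param spacing Voxel spacing in mm.
#' @return A \code{ds_image} with modality \code{"TBR"}.
#' @export
compute_tbr_image <- function(static, brain_mask, spacing = c(1, 1, 1)) {
  static <- img_data(static)
  assert_that(sum(brain_mask) > 0, "brain mask is empty")
  m <- mean(static[brain_mask])
  assert_that(is.finite(m) && m > 0, "brain mean uptake must be positive")
  ds_image(static / m, spacing, "TBR")
}

#' Threshold segmentation of the tumor VOI
#'
#' Selects voxels with TBR at or above 1.6 (i.e. 1.6 times the healthy-brain
#' mean uptake), restricted to a user-supplied search region, and reports the
#' metabolic tumor volume.
#'
#' @param tbr A TBR \code{ds_image}.
#' @param search_mask Logical array bounding the candidate region (manual
#'   delineation stand-in).
#' @param threshold Threshold on the TBR scale (default 1.6).
#' @return A list with \code{mask} (logical array), \code{mtv_ml} (voxel
#'   count times voxel volume, in mL) and \code{empty} flag.
#' @export
segment_tumor <- function(tbr, search_mask = NULL, threshold = 1.6) {
  assert_that(inherits(tbr, "ds_image") && tbr$modality == "TBR",
              "segment_tumor expects a TBR ds_image")
  x <- tbr$data
  if (is.null(search_mask)) search_mask <- array(TRUE, dim = dim(x))
  mask <- (x >= threshold) & search_mask
  vox_ml <- prod(tbr$spacing) / 1000
  mtv <- sum(mask) * vox_ml
  if (mtv == 0) warn("tumor segmentation is empty (MTV = 0 mL)")
  list(mask = mask, mtv_ml = mtv, empty = mtv == 0)
}

#' Threshold segmentation of the striatum VOI
#'
#' Selects voxels at or above 70 percent of the maximum uptake inside the
#' search region.
#'
#' @param static 3-D array (or \code{ds_image}) of static uptake.
#' @param search_mask Non-empty logical search region.
#' @param fraction Fraction of the regional maximum (default 0.7).
#' @return Logical mask array.
#' @export
segment_striatum <- function(static, search_mask, fraction = 0.7) {
  static <- img_data(static)
  assert_that(sum(search_mask) > 0, "striatum search mask is empty")
  thr <- fraction * max(static[search_mask])
  (static >= thr) & search_mask
}

# Fit a cubic smoothing spline to one TAC and evaluate it on the frame grid.
fit_tac <- function(tac, frame_times, spar = 0.5) {
  if (all(tac == 0) || !all(is.finite(tac))) return(NULL)
  fit <- tryCatch(smooth.spline(frame_times, tac, spar = spar),
                  error = function(e) NULL)
  if (is.null(fit)) return(tac)
  predict(fit, frame_times)$y
}

#' Dynamic time-to-peak (TTP) parametric image
#'
#' Each voxel's time-activity curve is fitted with a cubic smoothing spline,
#' normalized by the time-averaged fitted brain-mean curve (a scalar, so the
#' peak time is preserved), and the TTP is the frame time at which the fitted
#' normalized curve is maximal. Voxels with an all-zero TAC get \code{NA}.
#'
#' @param dynamic 4-D array (x, y, z, frame).
#' @param brain_mask Logical array selecting the healthy-brain reference.
#' @param frame_times Frame mid-times in minutes (default 1..30).
#' @param spacing Voxel spacing in mm.
#' @param region_mask Optional logical array; when given, the TTP of the
#'   region-mean TAC is also returned.
#' @param spar Smoothing-spline parameter (fixed default 0.5).
#' @return A list: \code{image} (TTP \code{ds_image}, minutes, \code{NA}
#'   where undefined) and \code{region_ttp} (minutes or \code{NA}).
#' @export
compute_ttp_image <- function(dynamic, brain_mask, frame_times = seq_len(dim(dynamic)[4]),
                              spacing = c(1, 1, 1), region_mask = NULL,
                              spar = 0.5) {
  nf <- dim(dynamic)[4]
  assert_that(length(frame_times) == nf && all(diff(frame_times) > 0),
              "frame_times must be strictly increasing and match the series")
  dims <- dim(dynamic)[1:3]
  flat <- matrix(dynamic, prod(dims), nf)

  brain_tac <- colMeans(flat[as.vector(brain_mask), , drop = FALSE])
  brain_fit <- fit_tac(brain_tac, frame_times, spar)
  norm_const <- mean(brain_fit)
  assert_that(is.finite(norm_const) && norm_const > 0,
              "brain reference TAC must have positive mean")

  ttp_of <- function(tac) {
    f <- fit_tac(tac, frame_times, spar)
    if (is.null(f)) return(NA_real_)
    frame_times[which.max(f / norm_const)]
  }

  active <- which(rowSums(abs(flat)) > 0)
  ttp <- rep(NA_real_, prod(dims))
  ttp[active] <- vapply(active, function(v) ttp_of(flat[v, ]), numeric(1))
  img <- ds_image(array(ttp, dim = dims), spacing, "TTP")

  region_ttp <- NA_real_
  if (!is.null(region_mask) && sum(region_mask) > 0) {
    region_ttp <- ttp_of(colMeans(flat[as.vector(region_mask), , drop = FALSE]))
  }
  list(image = img, region_ttp = region_ttp)
}

#' Late-uptake slope of a regional time-activity curve
#'
#' Ordinary-least-squares slope of (normalized) intensity against time over
#' the frames acquired between the 10th and 30th minute, inclusive.
#'
#' @param tac Regional TAC values.
#' @param frame_times Frame times in minutes.
#' @param window Inclusive time window (default \code{c(10, 30)}).
#' @return Slope in intensity units per minute.
#' @export
compute_slope <- function(tac, frame_times, window = c(10, 30)) {
  keep <- frame_times >= window[1] & frame_times <= window[2]
  assert_that(sum(keep) >= 2, "need at least two frames in the slope window")
  t <- frame_times[keep]; y <- tac[keep]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# World-space sphere offsets (in voxel index steps) of a given volume.
sphere_offsets <- function(spacing, volume_ml = 1) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3) # mm
  rng <- lapply(spacing, function(s) -floor(r / s):floor(r / s))
  off <- as.matrix(expand.grid(rng))
  keep <- sqrt(colSums(t(off)^2 * spacing^2)) <= r
  off[keep, , drop = FALSE]
}

# Mean intensity in a 1 cm^3 sphere centred at voxel `center` (index triplet),
# clipped to the image grid (not the mask).
sphere_mean <- function(data, center, offsets) {
  pts <- sweep(offsets, 2, center, "+")
  d <- dim(data)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] & pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  pts <- pts[ok, , drop = FALSE]
  mean(data[cbind(pts[, 1], pts[, 2], pts[, 3])])
}

#' Conventional region-based features
#'
#' Computes the nine conventional features of the tumor VOI: mean, maximum
#' and peak (1 cm^3 sphere) TBR; the three tumor-to-striatum ratios obtained
#' by dividing those statistics by the striatum mean uptake ratio; the
#' metabolic tumor volume; the regional time-to-peak; and the 10-30 min
#' late-uptake slope of the brain-normalized regional TAC.
#'
#' @param tbr A TBR \code{ds_image}.
#' @param dynamic 4-D dynamic series aligned with \code{tbr} (may be
#'   \code{NULL}: TTP and slope are then \code{NA}).
#' @param tumor_mask,striatum_mask,brain_mask Logical arrays.
#' @param frame_times Frame times in minutes.
#' @return A named numeric vector of length 9 with names
#'   \code{conv_TBR_mean}, \code{conv_TBR_max}, \code{conv_TBR_peak},
#'   \code{conv_TSR_mean}, \code{conv_TSR_max}, \code{conv_TSR_peak},
#'   \code{conv_MTV}, \code{conv_TTP_region}, \code{conv_slope}.
#' @export
conventional_features <- function(tbr, dynamic = NULL, tumor_mask,
                                  striatum_mask = NULL, brain_mask = NULL,
                                  frame_times = NULL) {
  assert_that(sum(tumor_mask) > 0, "tumor mask is empty")
  x <- tbr$data
  tv <- x[tumor_mask]
  off <- sphere_offsets(tbr$spacing)
  idx <- which(tumor_mask, arr.ind = TRUE)
  peak <- max(vapply(seq_len(nrow(idx)),
                     function(r) sphere_mean(x, idx[r, ], off), numeric(1)))
  tbr_mean <- mean(tv); tbr_max <- max(tv)

  tsr <- c(NA_real_, NA_real_, NA_real_)
  if (!is.null(striatum_mask) && sum(striatum_mask) > 0) {
    smean <- mean(x[striatum_mask])
    tsr <- c(tbr_mean, tbr_max, peak) / smean
  } else {
    warn("empty striatum mask: tumor-to-striatum ratios reported missing")
  }

  mtv <- sum(tumor_mask) * prod(tbr$spacing) / 1000

  ttp_region <- NA_real_; slope <- NA_real_
  if (!is.null(dynamic)) {
    if (is.null(frame_times)) frame_times <- seq_len(dim(dynamic)[4])
    tt <- compute_ttp_image(dynamic, brain_mask, frame_times,
                            spacing = tbr$spacing, region_mask = tumor_mask)
    ttp_region <- tt$region_ttp
    flat <- matrix(dynamic, prod(dim(dynamic)[1:3]), dim(dynamic)[4])
    tac <- colMeans(flat[as.vector(tumor_mask), , drop = FALSE])
    brain_tac <- colMeans(flat[as.vector(brain_mask), , drop = FALSE])
    slope <- compute_slope(tac / mean(brain_tac), frame_times)
  }

  c(conv_TBR_mean = tbr_mean, conv_TBR_max = tbr_max, conv_TBR_peak = peak,
    conv_TSR_mean = tsr[1], conv_TSR_max = tsr[2], conv_TSR_peak = tsr[3],
    conv_MTV = mtv, conv_TTP_region = ttp_region, conv_slope = slope)
}

#' Resample an image to an isotropic grid
#'
#' Trilinear interpolation onto a 1 mm isotropic grid sharing the input
#' origin (voxel centres at index times spacing). Masks should be resampled
#' with \code{method = "nearest"}.
#'
#' @param image A \code{ds_image} or 3-D array.
#' @param spacing Input spacing (taken from the \code{ds_image} if given).
#' @param target Target isotropic spacing in mm (default 1).
#' @param method \code{"linear"} or \code{"nearest"}.
#' @return A \code{ds_image} at the target spacing (or an array when the
#'   input was an array).
#' @export
resample_isotropic <- function(image, spacing = NULL, target = 1,
                               method = c("linear", "nearest")) {
  method <- match.arg(method)
  is_img <- inherits(image, "ds_image")
  data <- img_data(image)
  if (is_img) spacing <- image$spacing
  assert_that(all(spacing > 0), "spacing must be positive")
  d <- dim(data)
  if (all(spacing == target)) {
    return(if (is_img) image else data)
  }
  out_axes <- lapply(1:3, function(ax) seq(0, (d[ax] - 1) * spacing[ax], by = target))
  nd <- vapply(out_axes, length, integer(1))
  g <- expand.grid(x = out_axes[[1]], y = out_axes[[2]], z = out_axes[[3]])
  # continuous input-index coordinates (0-based)
  ci <- cbind(g$x / spacing[1], g$y / spacing[2], g$z / spacing[3])
  if (method == "nearest") {
    pi_ <- pmin(pmax(round(ci), 0), matrix(rep(d - 1, each = nrow(ci)), ncol = 3)) + 1
    vals <- data[cbind(pi_[, 1], pi_[, 2], pi_[, 3])]
  } else {
    dmax <- matrix(rep(pmax(d - 2, 0), each = nrow(ci)), ncol = 3)
    f <- pmax(pmin(floor(ci), dmax), 0)
    w <- ci - f
    f1 <- f + 1
    vals <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
        (if (dy) w[, 2] else 1 - w[, 2]) *
        (if (dz) w[, 3] else 1 - w[, 3])
      ix <- cbind(pmin(f1[, 1] + dx, d[1]), pmin(f1[, 2] + dy, d[2]),
                  pmin(f1[, 3] + dz, d[3]))
      vals <- vals + wt * data[ix]
    }
  }
  arr <- array(vals, dim = nd)
  if (is_img) ds_image(arr, rep(target, 3), image$modality) else arr
}
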