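#' Fixed-bin-width discretization of in-mask intensities
#'
#' Levels are anchored at the in-mask minimum:
#' \code{level = floor((value - min) / bin_width) + 1}, so adding a constant
#' to all in-mask values leaves every discretized-domain feature unchanged.
#'
#' @param values Numeric vector of in-mask voxel values.
#' @param bin_width Positive bin width (0.1 for TBR, 1 min for TTP images).
#' @return A list: \code{levels} (integer, >= 1), \code{n_levels},
#'   \code{bin_width}, \code{min_value}.
#' @export
discretize <- function(values, bin_width) {
  assert_that(bin_width > 0, "bin_width must be positive")
  assert_that(length(values) > 0, "empty mask: nothing to discretize")
  assert_that(all(is.finite(values)), "values must be finite")
  lev <- as.integer(floor((values - min(values)) / bin_width + 1e-9)) + 1L
  list(levels = lev, n_levels = max(lev), bin_width = bin_width,
       min_value = min(values))
}

# The 13 unique 3-D direction pairs at Chebyshev distance 1.
glcm_directions <- function() {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  # canonical half: first nonzero component positive
  keep <- apply(dirs, 1, function(d) d[which(d != 0)[1]] > 0)
  dirs[keep, , drop = FALSE]
}

# Features of one symmetric normalized co-occurrence matrix.
glcm_matrix_features <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sdx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pxy <- outer(px, py)
  hxy1 <- -sum(P[nz] * log2(pxy[nz]))
  nzxy <- pxy > 0
  hxy2 <- -sum(pxy[nzxy] * log2(pxy[nzxy]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))

  degenerate <- L == 1 || sdx == 0 || sdy == 0
  corr <- if (degenerate) 0 else sum(P * (i - mux) * (j - muy)) / (sdx * sdy)
  imc1 <- if (degenerate || max(hx, hy) == 0) 0 else (hxy - hxy1) / max(hx, hy)
  imc2 <- if (degenerate) 0 else {
    v <- 1 - exp(-2 * (hxy2 - hxy))
    sqrt(min(max(v, 0), 1))
  }
  c(glcm_Contrast = sum(P * (i - j)^2),
    glcm_Dissimilarity = sum(P * abs(i - j)),
    glcm_Homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_Correlation = corr,
    glcm_JointEntropy = hxy,
    glcm_JointEnergy = sum(P^2),
    glcm_MaxProbability = max(P),
    glcm_JointAverage = mux,
    glcm_Autocorrelation = sum(P * i * j),
    glcm_ClusterShade = sum(P * (i + j - mux - muy)^3),
    glcm_ClusterProminence = sum(P * (i + j - mux - muy)^4),
    glcm_InfoCorr1 = imc1,
    glcm_InfoCorr2 = imc2)
}

#' Grey-level co-occurrence matrix texture features
#'
#' Builds, for each of the 13 unique 3-D directions at distance 1, the
#' symmetric normalized co-occurrence matrix of discretized levels restricted
#' to the mask, computes second-order texture features per matrix and
#' averages them over directions (the reference "averaged" aggregation).
#' Information Correlation 2 is \code{sqrt(1 - exp(-2 (HXY2 - HXY)))}
#' clipped to \[0, 1\]; Cluster Prominence is the fourth joint central
#' moment about the marginal means. Single-level regions are degenerate and
#' yield 0 for both, flagged via the \code{degenerate} attribute.
#'
#' @param levels 3-D integer array of discretized levels (values outside the
#'   mask are ignored), or the result of applying \code{\link{discretize}} to
#'   in-mask values re-embedded with \code{mask}.
#' @param mask Logical array of the same dimensions.
#' @return Named numeric vector of direction-averaged GLCM features.
#' @export
glcm_features <- function(levels, mask) {
  assert_that(sum(mask) >= 2, "need at least two in-mask voxels")
  d <- dim(mask)
  lab <- array(NA_integer_, dim = d)
  lab[mask] <- as.integer(levels[mask])
  L <- max(lab, na.rm = TRUE)
  dirs <- glcm_directions()
  idx <- which(mask, arr.ind = TRUE)

  feats <- NULL
  n_used <- 0
  for (r in seq_len(nrow(dirs))) {
    nb <- sweep(idx, 2, dirs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    a <- lab[idx[ok, , drop = FALSE]]
    b <- lab[nb[ok, , drop = FALSE]]
    pair_ok <- !is.na(b)
    if (!any(pair_ok)) next
    a <- a[pair_ok]; b <- b[pair_ok]
    M <- matrix(0, L, L)
    tab <- table(factor(a, levels = seq_len(L)), factor(b, levels = seq_len(L)))
    M <- M + tab + t(tab)          # symmetric accumulation
    P <- M / sum(M)
    f <- glcm_matrix_features(P)
    feats <- if (is.null(feats)) f else feats + f
    n_used <- n_used + 1
  }
  if (n_used == 0) abort("no co-occurring voxel pairs inside the mask")
  out <- feats / n_used
  attr(out, "degenerate") <- L == 1
  out
}

#' First-order, intensity-histogram and morphological features
#'
#' Statistics over in-mask voxel intensities plus simple shape descriptors:
#' volume (mL), a surface-to-volume proxy (exposed voxel faces times face
#' area over volume) and the shift between the intensity-weighted and
#' geometric centres of mass (mm). Histogram entropy and uniformity use the
#' fixed-bin-width discretization. With fewer than 3 voxels the higher
#' moments are degenerate and returned as \code{NA} with a flag.
#'
#' @param image 3-D array (or \code{ds_image}).
#' @param mask Logical array.
#' @param spacing Voxel spacing in mm.
#' @param bin_width Bin width for the histogram features.
#' @return Named numeric vector.
#' @export
first_order_and_morphology <- function(image, mask, spacing = c(1, 1, 1),
                                       bin_width = 0.1) {
  data <- img_data(image)
  assert_that(sum(mask) > 0, "mask is empty")
  v <- data[mask]
  n <- length(v)
  m <- mean(v); s <- if (n > 1) sd(v) else 0
  degen <- n < 3 || s == 0
  skew <- if (degen) NA_real_ else mean((v - m)^3) / (sqrt(mean((v - m)^2)))^3
  kurt <- if (degen) NA_real_ else mean((v - m)^4) / (mean((v - m)^2))^2 - 3

  disc <- discretize(v, bin_width)
  ptab <- tabulate(disc$levels) / n
  ptab <- ptab[ptab > 0]
  ent <- -sum(ptab * log2(ptab))
  unif <- sum(ptab^2)

  vox_ml <- prod(spacing) / 1000
  idx <- which(mask, arr.ind = TRUE)
  # exposed faces: neighbours outside mask or outside grid, per axis
  d <- dim(mask)
  faces <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (dir in c(-1, 1)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + dir
      inside <- nb[, ax] >= 1 & nb[, ax] <= d[ax]
      covered <- rep(FALSE, nrow(idx))
      covered[inside] <- mask[nb[inside, , drop = FALSE]]
      faces <- faces + sum(!covered) * face_area[ax]
    }
  }
  vol_mm3 <- n * prod(spacing)
  com_geo <- colMeans(sweep(idx, 2, spacing, "*"))
  wts <- abs(v) / sum(abs(v))
  com_int <- colSums(sweep(idx, 2, spacing, "*") * wts)
  out <- c(fo_Mean = m, fo_Sd = s, fo_Min = min(v), fo_Max = max(v),
           fo_Range = max(v) - min(v), fo_Median = median(v),
           fo_P10 = unname(quantile(v, 0.1)), fo_P90 = unname(quantile(v, 0.9)),
           fo_Iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
           fo_Skewness = skew, fo_Kurtosis = kurt,
           fo_Energy = sum(v^2), fo_Rms = sqrt(mean(v^2)),
           hist_Entropy = ent, hist_Uniformity = unif,
           morph_VolumeMl = n * vox_ml,
           morph_SurfaceToVolume = faces / vol_mm3,
           morph_ComShiftMm = sqrt(sum((com_geo - com_int)^2)))
  attr(out, "degenerate") <- degen
  out
}

#' Local intensity peak
#'
#' Mean intensity within a 1 cm^3 world-space sphere centred at the global
#' in-mask maximum voxel; the sphere is clipped to the image grid, not the
#' mask (the usual peak-uptake convention).
#'
#' @param image 3-D array (or \code{ds_image}).
#' @param mask Logical array.
#' @param spacing Voxel spacing in mm.
#' @return The peak value.
#' @export
local_intensity_peak <- function(image, mask, spacing = c(1, 1, 1)) {
  data <- img_data(image)
  assert_that(sum(mask) > 0, "mask is empty")
  vals <- data[mask]
  idx <- which(mask, arr.ind = TRUE)
  center <- idx[which.max(vals), ]
  sphere_mean(data, center, sphere_offsets(spacing))
}

#' Extract the radiomics feature vector of one image + mask
#'
#' Bundles the first-order/histogram/morphology block, the direction-averaged
#' GLCM block and the local intensity peak into one named vector with a
#' deterministic ordering. TTP-derived features are suffixed \code{_TTP}.
#'
#' @param image 3-D array or \code{ds_image} (modality decides the default
#'   bin width: 0.1 for TBR, 1 for TTP).
#' @param mask Logical array.
#' @param spacing Voxel spacing in mm.
#' @param bin_width Discretization bin width; defaults from the modality.
#' @param suffix Name suffix (\code{"_TTP"} for dynamic parametric images).
#' @return Named numeric vector.
#' @export
extract_radiomics <- function(image, mask, spacing = c(1, 1, 1),
                              bin_width = NULL, suffix = "") {
  if (inherits(image, "ds_image")) {
    if (is.null(bin_width)) bin_width <- if (image$modality == "TTP") 1 else 0.1
    if (missing(spacing)) spacing <- image$spacing
  }
  if (is.null(bin_width)) bin_width <- 0.1
  data <- img_data(image)
  keep <- mask & !is.na(data)
  fo <- first_order_and_morphology(data, keep, spacing, bin_width)
  disc <- discretize(data[keep], bin_width)
  lev <- array(NA_integer_, dim = dim(data))
  lev[keep] <- disc$levels
  gl <- glcm_features(lev, keep)
  li <- c(li_GlobalPeak = local_intensity_peak(data, keep, spacing))
  out <- c(fo, gl, li)
  if (nzchar(suffix)) names(out) <- paste0(names(out), suffix)
  out
}
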