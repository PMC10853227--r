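# Smooth gamma-variate-like uptake curve peaking at `tp` minutes, scaled so
# its mean over the late static window (frames 11..30) is 1.
uptake_shape <- function(t, tp, late = 11:30) {
  s <- (t / tp)^2 * exp(2 * (1 - t / tp))
  s / mean(((late / tp)^2 * exp(2 * (1 - late / tp))))
}

ellipsoid_mask <- function(dim, center, radii) {
  idx <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]), k = seq_len(dim[3]))
  d <- ((idx$i - center[1]) / radii[1])^2 + ((idx$j - center[2]) / radii[2])^2 +
    ((idx$k - center[3]) / radii[3])^2
  array(d <= 1, dim = dim)
}

#' Generate a small dynamic-PET phantom
#'
#' Builds a 30-frame dynamic series in which every voxel's time-activity
#' curve (TAC) follows a smooth uptake curve; the tumor's TAC peaks earlier
#' than the background brain's. Region levels are defined as the mean of the
#' late static window (frames 11-30), so the static image (the late-frame
#' average) reproduces them exactly in the noise-free case. Optional
#' voxel-wise multiplicative texture (constant over time, hence preserving
#' each voxel's time-to-peak) and additive frame noise can be added.
#'
#' @param dim Voxel grid dimensions (default \code{c(24, 24, 12)}).
#' @param spacing Voxel spacing in mm (default 2 mm isotropic).
#' @param tumor_center,tumor_radii Tumor ellipsoid in voxel index units; the
#'   ellipsoid must lie inside the grid. Set \code{tumor_level = NULL} for a
#'   background-only phantom.
#' @param brain_level,tumor_level,striatum_level Late-window mean intensity
#'   of each region (arbitrary SUV-like units).
#' @param peak_background,peak_tumor,peak_striatum TAC peak times (minutes).
#' @param texture_sd SD of the log-normal voxel gain inside the tumor.
#' @param noise_sd SD of additive Gaussian noise per voxel-frame.
#' @param n_frames Number of 1-minute frames; the acquisition protocol fixes
#'   30 and other values are rejected unless \code{allow_nonstandard_frames}.
#' @param allow_nonstandard_frames Override the 30-frame contract.
#' @param seed Integer seed; phantoms are bit-reproducible per seed.
#' @return A \code{ds_phantom} list: \code{dynamic} (4-D array
#'   x,y,z,frame), \code{static} (3-D array), \code{frame_times} (minutes),
#'   \code{spacing}, \code{masks} (brain, striatum_search, tumor,
#'   tumor_search logical arrays) and \code{truth} (levels and peak times).
#' @export
generate_dynamic_phantom <- function(dim = c(24, 24, 12), spacing = c(2, 2, 2),
                                     tumor_center = c(8, 8, 6),
                                     tumor_radii = c(4, 4, 3),
                                     brain_level = 4, tumor_level = 8,
                                     striatum_level = 7,
                                     peak_background = 20, peak_tumor = 7,
                                     peak_striatum = 12,
                                     texture_sd = 0, noise_sd = 0,
                                     n_frames = 30,
                                     allow_nonstandard_frames = FALSE,
                                     seed = 1) {
  if (n_frames != 30 && !allow_nonstandard_frames) {
    abort("the acquisition protocol fixes 30 one-minute frames; set allow_nonstandard_frames = TRUE to override")
  }
  has_tumor <- !is.null(tumor_level)
  if (has_tumor) {
    assert_that(all(tumor_center - tumor_radii >= 1) &&
                  all(tumor_center + tumor_radii <= dim),
                "tumor ellipsoid must lie inside the grid")
  }
  with_seed(seed, {
    ft <- seq_len(n_frames)
    head_mask <- ellipsoid_mask(dim, dim / 2 + 0.5, dim / 2 - 0.5)
    tumor <- if (has_tumor) ellipsoid_mask(dim, tumor_center, tumor_radii) else
      array(FALSE, dim = dim)
    stri_center <- c(round(dim[1] * 0.7), round(dim[2] * 0.7), round(dim[3] / 2))
    striatum_search <- ellipsoid_mask(dim, stri_center, c(2.5, 2.5, 2)) & head_mask
    striatum_search <- striatum_search & !tumor
    brain <- head_mask & !tumor & !striatum_search

    shapes <- list(brain = uptake_shape(ft, peak_background, late = 11:n_frames),
                   tumor = uptake_shape(ft, peak_tumor, late = 11:n_frames),
                   striatum = uptake_shape(ft, peak_striatum, late = 11:n_frames))

    gain <- array(1, dim = dim)
    if (texture_sd > 0 && has_tumor) {
      gain[tumor] <- exp(rnorm(sum(tumor), 0, texture_sd))
    }
    level <- array(0, dim = dim)
    level[brain] <- brain_level
    level[striatum_search] <- striatum_level
    if (has_tumor) level[tumor] <- tumor_level
    level <- level * gain

    region <- array("none", dim = dim)
    region[brain] <- "brain"; region[striatum_search] <- "striatum"
    if (has_tumor) region[tumor] <- "tumor"

    dyn <- array(0, dim = c(dim, n_frames))
    for (f in ft) {
      sl <- array(0, dim = dim)
      sl[region == "brain"] <- shapes$brain[f]
      sl[region == "striatum"] <- shapes$striatum[f]
      sl[region == "tumor"] <- shapes$tumor[f]
      dyn[, , , f] <- level * sl
    }
    if (noise_sd > 0) dyn <- dyn + array(rnorm(length(dyn), 0, noise_sd), dim = dim(dyn))

    static <- apply(dyn[, , , 11:n_frames, drop = FALSE], 1:3, mean)

    # generous search region around the tumor for threshold segmentation
    tumor_search <- if (has_tumor) {
      ellipsoid_mask(dim, tumor_center, pmin(tumor_radii + 2, dim / 2))
    } else head_mask

    structure(list(
      dynamic = dyn, static = static, frame_times = ft, spacing = spacing,
      masks = list(brain = brain, striatum_search = striatum_search,
                   tumor = tumor, tumor_search = tumor_search),
      truth = list(brain_level = brain_level, tumor_level = tumor_level,
                   striatum_level = striatum_level, peak_tumor = peak_tumor,
                   peak_background = peak_background)
    ), class = "ds_phantom")
  })
}

#' Write phantom images to NIfTI files
#'
#' @param phantom A \code{ds_phantom}.
#' @param dir Output directory.
#' @return Invisibly, the paths written. Requires the RNifti package.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("RNifti is required to write NIfTI files")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- phantom$spacing
  wr <- function(arr, name, mask = FALSE) {
    p <- file.path(dir, name)
    if (mask) arr <- array(as.integer(arr), dim = dim(arr))
    img <- RNifti::asNifti(arr, pixdim = pd)
    RNifti::writeNifti(img, p)
    p
  }
  paths <- c(wr(phantom$dynamic, "dynamic.nii.gz"),
             wr(phantom$static, "static.nii.gz"),
             wr(phantom$masks$brain, "mask_brain.nii.gz", mask = TRUE),
             wr(phantom$masks$striatum_search, "mask_striatum_search.nii.gz", mask = TRUE),
             wr(phantom$masks$tumor_search, "mask_tumor_search.nii.gz", mask = TRUE))
  invisible(paths)
}
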