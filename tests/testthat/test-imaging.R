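test_that("phantoms are bit-reproducible and enforce the 30-frame protocol", {
  a <- generate_dynamic_phantom(seed = 4)
  b <- generate_dynamic_phantom(seed = 4)
  expect_identical(a$dynamic, b$dynamic)
  expect_identical(a$static, b$static)
  expect_error(generate_dynamic_phantom(n_frames = 20), "30")
  expect_s3_class(generate_dynamic_phantom(n_frames = 20,
                                           allow_nonstandard_frames = TRUE),
                  "ds_phantom")
})

test_that("TBR normalization fixes the brain mean at 1 and scales ratios exactly", {
  img <- array(2, dim = c(3, 3, 3))
  mask <- array(TRUE, dim = c(3, 3, 3))
  tbr <- compute_tbr_image(img, mask)
  expect_equal(unique(as.vector(tbr$data)), 1)

  img2 <- array(1, dim = c(2, 2, 1))
  img2[2, 2, 1] <- 3.2
  brain <- array(c(TRUE, TRUE, TRUE, FALSE), dim = c(2, 2, 1))
  tbr2 <- compute_tbr_image(img2, brain)
  expect_equal(tbr2$data[2, 2, 1], 3.2)

  ph <- generate_dynamic_phantom(brain_level = 4, tumor_level = 8, seed = 1)
  tbr3 <- compute_tbr_image(ph$static, ph$masks$brain, ph$spacing)
  expect_lt(abs(mean(tbr3$data[ph$masks$brain]) - 1), 1e-6)
  # independent recomputation by direct division
  expect_equal(tbr3$data, ph$static / mean(ph$static[ph$masks$brain]))
  expect_equal(unique(round(tbr3$data[ph$masks$tumor], 10)), 2)
  expect_error(compute_tbr_image(img, array(FALSE, dim = c(3, 3, 3))), "empty")
})

test_that("TBR-derived quantities are invariant under global intensity scaling", {
  ph <- generate_dynamic_phantom(texture_sd = 0.1, seed = 9)
  t1 <- compute_tbr_image(ph$static, ph$masks$brain, ph$spacing)
  t2 <- compute_tbr_image(ph$static * 37.5, ph$masks$brain, ph$spacing)
  expect_equal(t1$data, t2$data)
  expect_equal(segment_tumor(t1, ph$masks$tumor_search)$mask,
               segment_tumor(t2, ph$masks$tumor_search)$mask)
})

test_that("tumor segmentation applies the 1.6x brain threshold and reports MTV", {
  x <- array(1, dim = c(3, 1, 1)); x[1:3, 1, 1] <- c(1.5, 1.7, 2.0)
  tbr <- ds_image(x, c(1, 1, 1), "TBR")
  seg <- segment_tumor(tbr)
  expect_equal(sum(seg$mask), 2)
  low <- ds_image(array(1.2, dim = c(2, 2, 2)), c(1, 1, 1), "TBR")
  expect_warning(seg0 <- segment_tumor(low), "empty")
  expect_equal(seg0$mtv_ml, 0)
  # 1000 voxels at 1 mm isotropic -> exactly 1 mL
  big <- ds_image(array(2, dim = c(10, 10, 10)), c(1, 1, 1), "TBR")
  expect_equal(segment_tumor(big)$mtv_ml, 1)
  # background-only phantom: threshold exceeds everything in the head
  ph0 <- generate_dynamic_phantom(tumor_level = NULL, seed = 3)
  tbr0 <- compute_tbr_image(ph0$static, ph0$masks$brain, ph0$spacing)
  seg_bg <- suppressWarnings(segment_tumor(tbr0, ph0$masks$brain))
  expect_equal(seg_bg$mtv_ml, 0)
})

test_that("striatum segmentation keeps voxels above 70% of the regional maximum", {
  x <- array(c(10, 8, 6.9, 0), dim = c(4, 1, 1))
  sm <- array(c(TRUE, TRUE, TRUE, FALSE), dim = c(4, 1, 1))
  out <- segment_striatum(x, sm)
  expect_equal(as.vector(out), c(TRUE, TRUE, FALSE, FALSE))
  const <- array(5, dim = c(2, 2, 1))
  expect_true(all(segment_striatum(const, array(TRUE, dim = c(2, 2, 1)))))
  # brute-force recount on random values
  set.seed(8)
  v <- array(runif(60, 5, 10), dim = c(5, 4, 3))
  m <- array(TRUE, dim = dim(v))
  expect_equal(sum(segment_striatum(v, m)), sum(v >= 0.7 * max(v)))
})

test_that("TTP images recover construction peak times", {
  ph <- generate_dynamic_phantom(peak_tumor = 7, peak_background = 20,
                                 noise_sd = 0.02, seed = 5)
  tt <- compute_ttp_image(ph$dynamic, ph$masks$brain, ph$frame_times,
                          ph$spacing, region_mask = ph$masks$tumor)
  expect_lte(abs(median(tt$image$data[ph$masks$tumor], na.rm = TRUE) - 7), 1)
  expect_lte(abs(median(tt$image$data[ph$masks$brain], na.rm = TRUE) - 20), 2)
  expect_lte(abs(tt$region_ttp - 7), 1)
  # TTP values live on the frame grid; outside-head voxels are undefined
  vals <- tt$image$data[!is.na(tt$image$data)]
  expect_true(all(vals %in% 1:30))
  # all-zero TACs (outside the head of a noiseless phantom) are undefined
  ph0 <- generate_dynamic_phantom(seed = 5)
  tt0 <- compute_ttp_image(ph0$dynamic, ph0$masks$brain, ph0$frame_times, ph0$spacing)
  expect_true(is.na(tt0$image$data[1, 1, 1]))
})

test_that("late-uptake slope is the OLS slope over the 10-30 min window", {
  ft <- 1:30
  expect_equal(compute_slope(0.01 * ft, ft), 0.01)
  expect_equal(compute_slope(rep(2, 30), ft), 0)
  # noisy line: OLS sampling error stays small
  set.seed(12)
  errs <- replicate(40, compute_slope(0.02 * ft + rnorm(30, 0, 0.001), ft) - 0.02)
  expect_lt(quantile(abs(errs), 0.95), 0.003)
})

test_that("conventional features number nine and follow the construction", {
  ph <- generate_dynamic_phantom(seed = 2)
  tbr <- compute_tbr_image(ph$static, ph$masks$brain, ph$spacing)
  seg <- segment_tumor(tbr, ph$masks$tumor_search)
  stri <- segment_striatum(ph$static, ph$masks$striatum_search)
  cf <- conventional_features(tbr, ph$dynamic, seg$mask, stri, ph$masks$brain,
                              ph$frame_times)
  expect_length(cf, 9)
  expect_gte(cf[["conv_TBR_max"]], cf[["conv_TBR_mean"]])
  expect_equal(cf[["conv_MTV"]], sum(seg$mask) * prod(ph$spacing) / 1000)
  expect_equal(cf[["conv_TTP_region"]], 7)
  # single-voxel tumor: mean = max = the voxel's value
  one <- array(FALSE, dim = dim(tbr$data)); one[8, 8, 6] <- TRUE
  cf1 <- suppressWarnings(conventional_features(tbr, NULL, one))
  expect_equal(cf1[["conv_TBR_mean"]], cf1[["conv_TBR_max"]])
  # striatum at twice the brain mean makes TSR_mean = TBR_mean / 2
  x <- array(1, dim = c(6, 6, 3))
  x[1:3, 1:3, 2] <- c(1.8, 2.0, 2.2)
  stri_m <- array(FALSE, dim = dim(x)); stri_m[5:6, 5:6, 2] <- TRUE
  x[stri_m] <- 2
  tum <- array(FALSE, dim = dim(x)); tum[1:3, 1, 2] <- TRUE
  x[tum] <- c(1.8, 2.0, 2.2)
  tbr2 <- ds_image(x, c(1, 1, 1), "TBR")
  cf2 <- conventional_features(tbr2, NULL, tum, stri_m)
  expect_equal(cf2[["conv_TSR_mean"]], 1)
})

test_that("isotropic resampling is exact on identity, constants and linear ramps", {
  img <- ds_image(array(rnorm(27), dim = c(3, 3, 3)), c(1, 1, 1), "TBR")
  expect_identical(resample_isotropic(img)$data, img$data)
  cst <- resample_isotropic(array(2, dim = c(3, 3, 3)), spacing = c(2, 2, 2))
  expect_equal(unique(as.vector(cst)), 2)
  ramp <- array(rep(seq(0, 6, by = 2), 9), dim = c(4, 3, 3))
  out <- resample_isotropic(ramp, spacing = c(2, 2, 2))
  expect_equal(out[, 1, 1], 0:6)
})
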