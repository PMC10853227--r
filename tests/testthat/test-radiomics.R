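test_that("fixed-bin-width discretization follows the floor rule and matches histograms", {
  expect_equal(discretize(c(1.00, 1.05, 1.19), 0.1)$levels, c(1L, 1L, 2L))
  expect_equal(discretize(rep(3.3, 5), 0.1)$levels, rep(1L, 5))
  set.seed(1)
  v <- runif(5000)
  d <- discretize(v, 0.1)
  expect_equal(d$n_levels, 10)
  expect_equal(tabulate(d$levels),
               as.vector(table(cut(v, breaks = seq(min(v), min(v) + 1, by = 0.1),
                                   include.lowest = TRUE, right = FALSE))))
  expect_error(discretize(numeric(0), 0.1), "empty")
  expect_error(discretize(1:3, 0), "positive")
})

test_that("discretized-domain features are invariant under constant intensity shifts", {
  set.seed(2)
  img <- array(runif(4 * 4 * 3, 1, 2), dim = c(4, 4, 3))
  mask <- array(TRUE, dim = dim(img))
  f1 <- extract_radiomics(img, mask, bin_width = 0.1)
  f2 <- extract_radiomics(img + 10, mask, bin_width = 0.1)
  glcm_names <- grep("^glcm_|^hist_", names(f1), value = TRUE)
  expect_equal(f1[glcm_names], f2[glcm_names])
})

test_that("GLCM matrices are symmetric, normalized and degenerate-safe", {
  cst <- array(1L, dim = c(3, 3, 1))
  mask <- array(TRUE, dim = c(3, 3, 1))
  g <- glcm_features(cst, mask)
  expect_equal(g[["glcm_ClusterProminence"]], 0)
  expect_equal(g[["glcm_InfoCorr2"]], 0)
  expect_true(attr(g, "degenerate"))

  set.seed(3)
  lev <- array(sample(1:4, 36, TRUE), dim = c(4, 3, 3))
  g2 <- glcm_features(lev, array(TRUE, dim = dim(lev)))
  expect_gte(g2[["glcm_InfoCorr2"]], 0)
  expect_lte(g2[["glcm_InfoCorr2"]], 1)
  # the oracle-built matrix for one direction is symmetric and sums to 1
  P <- oracle_glcm_matrix(lev, array(TRUE, dim = dim(lev)), c(1, 0, 0))
  expect_equal(P, t(P))
  expect_equal(sum(P), 1)
})

test_that("checkerboard cluster prominence matches the hand-enumerated co-occurrence oracle", {
  cb <- array(((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2) + 1,
              dim = c(4, 4, 1))
  mask <- array(TRUE, dim = c(4, 4, 1))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  cp <- mean(vapply(seq_len(nrow(dirs)), function(r) {
    oracle_cluster_prominence(oracle_glcm_matrix(cb, mask, dirs[r, ]))
  }, numeric(1)))
  g <- glcm_features(cb, mask)
  expect_equal(g[["glcm_ClusterProminence"]], cp)
})

test_that("GLCM contrast and correlation agree with direction-wise brute force on random phantoms", {
  set.seed(4)
  dirs13 <- local({
    d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    d <- d[rowSums(abs(d)) > 0, ]
    d[apply(d, 1, function(v) v[which(v != 0)[1]] > 0), ]
  })
  for (rep in 1:3) {
    lev <- array(sample(1:3, 60, TRUE), dim = c(5, 4, 3))
    mask <- array(runif(60) > 0.2, dim = dim(lev))
    if (sum(mask) < 4) next
    per_dir <- lapply(seq_len(nrow(dirs13)), function(r) {
      P <- oracle_glcm_matrix(lev, mask, dirs13[r, ])
      if (any(!is.finite(P))) return(NULL)
      L <- nrow(P)
      px <- rowSums(P); mux <- sum(seq_len(L) * px)
      sdx <- sqrt(sum((seq_len(L) - mux)^2 * px))
      py <- colSums(P); muy <- sum(seq_len(L) * py)
      sdy <- sqrt(sum((seq_len(L) - muy)^2 * py))
      ii <- matrix(seq_len(L), L, L); jj <- t(ii)
      c(contrast = sum(P * (ii - jj)^2),
        correlation = if (sdx == 0 || sdy == 0) 0 else
          sum(P * (ii - mux) * (jj - muy)) / (sdx * sdy))
    })
    per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
    ref <- colMeans(do.call(rbind, per_dir))
    g <- glcm_features(lev, mask)
    expect_equal(g[["glcm_Contrast"]], ref[["contrast"]], tolerance = 1e-6)
    expect_equal(g[["glcm_Correlation"]], ref[["correlation"]], tolerance = 1e-6)
  }
})

test_that("first-order and morphology features follow their definitions", {
  x <- array(c(1, 2, 3), dim = c(3, 1, 1))
  mask <- array(TRUE, dim = c(3, 1, 1))
  f <- first_order_and_morphology(x, mask, c(1, 1, 1))
  expect_equal(f[["fo_Mean"]], 2)
  expect_equal(f[["fo_Range"]], 2)
  expect_equal(f[["morph_VolumeMl"]], 3 / 1000)
  cst <- first_order_and_morphology(array(4, dim = c(2, 2, 2)),
                                    array(TRUE, dim = c(2, 2, 2)))
  expect_equal(cst[["fo_Sd"]], 0)
  expect_equal(cst[["hist_Entropy"]], 0)
  expect_true(attr(cst, "degenerate"))
  set.seed(5)
  big <- array(rnorm(10000), dim = c(25, 20, 20))
  fb <- first_order_and_morphology(big, array(TRUE, dim = dim(big)))
  expect_lt(abs(fb[["fo_Skewness"]]), 0.1)
})

test_that("local intensity peak averages a 1 cm^3 sphere clipped to the grid", {
  cst <- array(2.5, dim = c(20, 20, 20))
  mask <- array(TRUE, dim = dim(cst))
  expect_equal(local_intensity_peak(cst, mask), 2.5)
  # delta spike on zero background: peak = spike / sphere voxel count
  spike <- array(0, dim = c(21, 21, 21))
  spike[11, 11, 11] <- 100
  m2 <- array(TRUE, dim = dim(spike))
  # brute-force sphere membership at 1 mm spacing
  idx <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  n_in <- sum(sqrt(rowSums(sweep(idx, 2, c(11, 11, 11))^2)) <= r)
  expect_equal(local_intensity_peak(spike, m2), 100 / n_in)
})

test_that("the radiomics vector has deterministic names and a TTP suffix", {
  ph <- generate_dynamic_phantom(texture_sd = 0.2, seed = 6)
  tbr <- compute_tbr_image(ph$static, ph$masks$brain, ph$spacing)
  v <- extract_radiomics(tbr, ph$masks$tumor)
  v_ttp <- extract_radiomics(ph$static, ph$masks$tumor, bin_width = 1,
                             suffix = "_TTP")
  expect_true(all(endsWith(names(v_ttp), "_TTP")))
  expect_identical(names(v), names(extract_radiomics(tbr, ph$masks$tumor)))
  expect_false(any(is.na(v)))
})
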