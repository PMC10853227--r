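test_that("scaling drops zero-variance features and standardizes with train statistics", {
  df <- tibble::tibble(patient_id = c("a", "b", "c"),
                       f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  m <- fit_scaling(df)
  expect_equal(m$kept, "f1")
  expect_equal(m$dropped, "f2")
  z <- apply_scaling(m, df)
  expect_equal(as.vector(z), c(-1, 0, 1))
  # two-point column under the n-1 convention: sd = sqrt(2), z = +/- 1/sqrt(2)
  two <- tibble::tibble(patient_id = c("a", "b"), f = c(1, 3))
  z2 <- apply_scaling(fit_scaling(two), two)
  expect_equal(as.vector(z2), c(-1, 1) / sqrt(2), tolerance = 1e-6)
  expect_error(fit_scaling(tibble::tibble(patient_id = "a", f = 1)), "two")
  expect_error(fit_scaling(tibble::tibble(patient_id = c("a", "b"),
                                          f = c(2, 2))), "zero variance")
})

test_that("held-out rows never influence the fitted transforms", {
  coh <- quiet_cohort(n_patients = 16, seed = 8)
  tab <- build_feature_set(coh, "delta_abs", "radiomics")
  train <- tab[1:12, ]
  m1 <- fit_scaling(train)
  prep1 <- fit_preprocess(train, n_boot = 30, seed = 5)
  # mutate the held-out rows arbitrarily
  tab2 <- tab
  tab2[13:16, -1] <- tab2[13:16, -1] * 1000 + 7
  m2 <- fit_scaling(tab2[1:12, ])
  prep2 <- fit_preprocess(tab2[1:12, ], n_boot = 30, seed = 5)
  expect_identical(m1, m2)
  expect_identical(prep1$partition, prep2$partition)
  expect_identical(prep1$medoids, prep2$medoids)
  expect_identical(prep1$coassociation, prep2$coassociation)
})

test_that("Spearman clustering groups duplicates and isolates independent features", {
  set.seed(9)
  n <- 1000
  a <- rnorm(n)
  x <- cbind(A = a, B = a, C = rnorm(n))
  cl <- spearman_cluster(x)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["C"]] == cl[["A"]])
  # all-independent features stay singletons at n = 1000
  xi <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  expect_length(unique(spearman_cluster(xi)), 6)
  # three exact duplicates form one cluster
  x3 <- cbind(A = a, B = a, C = a)
  expect_length(unique(spearman_cluster(x3)), 1)
})

test_that("clustering is invariant under patient permutations", {
  set.seed(10)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 2] <- x[, 1] + rnorm(40, 0, 0.05)
  cl1 <- spearman_cluster(x)
  cl2 <- spearman_cluster(x[sample(40), ])
  expect_identical(cl1, cl2)
})

test_that("consensus clustering accumulates co-association frequencies deterministically", {
  set.seed(11)
  a <- rnorm(24)
  x <- cbind(A = a, B = a, C = rnorm(24), D = rnorm(24))
  cc1 <- consensus_cluster(x, n_boot = 50, seed = 3)
  cc2 <- consensus_cluster(x, n_boot = 50, seed = 3)
  expect_identical(cc1, cc2)
  # duplicates co-cluster in every bootstrap
  expect_equal(cc1$coassociation["A", "B"], 1)
  expect_true(all(cc1$coassociation >= 0 & cc1$coassociation <= 1))
  expect_equal(diag(cc1$coassociation), setNames(rep(1, 4), colnames(x)))
  expect_equal(cc1$coassociation, t(cc1$coassociation))
  # n_boot = 1: consensus equals that single bootstrap's partition (0/1 entries)
  cc_one <- consensus_cluster(x, n_boot = 1, seed = 7)
  expect_true(all(cc_one$coassociation %in% c(0, 1)))
})

test_that("consensus clustering recovers planted near-duplicate blocks", {
  hits <- vapply(1:5, function(s) {
    coh <- quiet_cohort(n_patients = 18, within_block_abs_spearman = 0.98,
                        seed = 400 + s)
    z <- apply_scaling(fit_scaling(coh$features0[, 1:31]),
                       coh$features0[, 1:31])
    cc <- consensus_cluster(z, n_boot = 100, seed = s)
    truth <- rep(1:6, each = 5)
    adjusted_rand_index(unname(cc$partition), truth) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("medoid selection maximizes within-cluster similarity with lexicographic ties", {
  set.seed(12)
  a <- rnorm(30)
  x <- cbind(A = a, B = a, C = a + rnorm(30, 0, 0.2))
  part <- setNames(c(1L, 1L, 1L), c("A", "B", "C"))
  expect_equal(unname(select_medoids(part, x)), "A")
  # singleton cluster is its own medoid
  part2 <- setNames(c(1L, 2L), c("A", "C"))
  expect_equal(unname(select_medoids(part2, x[, c("A", "C")])), c("A", "C"))
  # brute force over a random 5-feature cluster
  y <- matrix(rnorm(25 * 5), 25, 5, dimnames = list(NULL, paste0("f", 1:5)))
  s <- abs(cor(apply(y, 2, rank)))
  sums <- vapply(1:5, function(i) sum(s[i, -i]), numeric(1))
  best <- colnames(y)[which.max(sums)]
  expect_equal(unname(select_medoids(setNames(rep(1L, 5), colnames(y)), y)), best)
})

test_that("the preprocessing model keeps one medoid per cluster covering all features", {
  coh <- quiet_cohort(n_patients = 18, seed = 13)
  prep <- fit_preprocess(build_feature_set(coh, "delta_abs", "radiomics"),
                         n_boot = 50, seed = 2)
  expect_length(prep$medoids, length(unique(prep$partition)))
  expect_true(all(prep$medoids %in% prep$scaling$kept))
  expect_setequal(names(prep$partition), prep$scaling$kept)
  expect_lte(length(prep$medoids), length(prep$scaling$kept))
})
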