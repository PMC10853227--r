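test_that("concordance index handles perfect, reversed and censored orderings", {
  expect_equal(concordance_index(c(5, 10, 15), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(concordance_index(c(5, 10, 15), c(1, 1, 1), c(1, 2, 3)), 0)
  # comparable pairs (1,2) and (1,3) only; one concordant, one not
  expect_equal(concordance_index(c(5, 10, 15), c(1, 0, 1), c(2, 3, 1)), 0.5)
  expect_error(concordance_index(c(5, 5), c(0, 0), c(1, 2)), "comparable")
})

test_that("concordance index equals the exhaustive pair oracle on random censored instances", {
  set.seed(42)
  for (rep in 1:200) {
    inst <- random_surv_instance(sample(4:20, 1))
    has_pairs <- any(outer(inst$time, inst$time, "<") & inst$event == 1)
    if (!has_pairs) next
    expect_identical(concordance_index(inst$time, inst$event, inst$risk),
                     oracle_cindex(inst$time, inst$event, inst$risk))
  }
})

test_that("concordance index is invariant under positive affine risk maps", {
  set.seed(7)
  inst <- random_surv_instance(15)
  c0 <- concordance_index(inst$time, inst$event, inst$risk)
  expect_equal(concordance_index(inst$time, inst$event, 3.7 * inst$risk - 2), c0)
})

test_that("integrated AUC is 1 for perfect ordering, 0.5 for ties, near 0.5 for noise", {
  set.seed(3)
  tm <- sort(runif(60, 1, 30)); ev <- rep(1L, 60)
  expect_equal(as.numeric(integrated_auc(tm, ev, tm, ev, -tm)), 1)
  expect_equal(as.numeric(integrated_auc(tm, ev, tm, ev, rep(2, 60))), 0.5)
  aucs <- replicate(30, {
    tm <- rexp(80, 0.1); ev <- rbinom(80, 1, 0.8)
    as.numeric(integrated_auc(tm, ev, tm, ev, rnorm(80)))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("bootstrap summary degenerates correctly and is seed-deterministic", {
  s <- bootstrap_summary(rep(0.7, 10), seed = 1)
  expect_equal(s$mean, 0.7)
  expect_equal(s$se, 0)
  expect_equal(c(s$ci_lower, s$ci_upper), c(0.7, 0.7))
  x <- rnorm(15)
  expect_identical(bootstrap_summary(x, seed = 5), bootstrap_summary(x, seed = 5))
})

test_that("Mann-Whitney comparison matches exact enumeration and directional symmetry", {
  # 2 vs 2, clean separation: one-sided exact p = 1/choose(4,2) = 1/6
  r <- compare_models(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(r$p, 1 / 6)
  expect_false(r$flagged)
  # all tied across both lists: p = 0.5 by convention, flagged
  r2 <- compare_models(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(r2$p, 0.5)
  expect_true(r2$flagged)
  # swap identity under the exact test (no ties): p_ab + p_ba = 1 + P(U = u)
  a <- c(0.91, 0.83, 0.72); b <- c(0.65, 0.88, 0.41)
  p_ab <- compare_models(a, b)$p
  p_ba <- compare_models(b, a)$p
  u <- compare_models(a, b)$u
  expect_equal(p_ab + p_ba, 1 + dwilcox(u, 3, 3))
})

test_that("Benjamini-Hochberg adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 4)), rep(0.07, 4))
  p <- runif(10)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("adjusted Rand index matches known values and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # exhaustive: all partition pairs of up to 6 items
  for (n in c(4, 6)) {
    parts <- all_partitions(n)
    set.seed(n)
    picks <- sample(length(parts), 12, replace = TRUE)
    for (i in picks) for (j in sample(length(parts), 3)) {
      expect_equal(adjusted_rand_index(parts[[i]], parts[[j]]),
                   oracle_ari(parts[[i]], parts[[j]]))
    }
  }
  # chance correction: random labelings average near zero
  set.seed(1)
  aris <- replicate(200, adjusted_rand_index(sample(1:4, 100, TRUE),
                                             sample(1:4, 100, TRUE)))
  expect_lt(abs(mean(aris)), 0.05)
})
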