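test_that("map overlap identities and hand counts", {
  r2 <- rep(1, 100)
  # identical maps: 100% overlap both ways
  ov <- map_overlap(1:30, 1:30, r2, r2)
  expect_equal(ov$pct_a, 100)
  expect_equal(ov$pct_b, 100)
  # disjoint maps: 0%
  ov0 <- map_overlap(1:10, 21:40, r2, r2)
  expect_equal(ov0$pct_mean, 0)
  # |A| = 10, |B| = 20, |shared| = 5
  ov5 <- map_overlap(1:10, 6:25, r2, r2)
  expect_equal(ov5$pct_a, 50)
  expect_equal(ov5$pct_b, 25)
  expect_equal(ov5$pct_mean, 37.5)
  # symmetry under swapping maps
  swapped <- map_overlap(6:25, 1:10, r2, r2)
  expect_equal(swapped$pct_a, ov5$pct_b)
  expect_equal(swapped$pct_b, ov5$pct_a)
  expect_equal(swapped$pct_mean, ov5$pct_mean)
  # thresholding removes sub-threshold vertices
  r2b <- r2
  r2b[6:10] <- 0.1
  ovt <- map_overlap(1:10, 6:25, r2, r2b, threshold = 0.3)
  expect_equal(ovt$pct_a, 0)
  expect_error(map_overlap(1:5, 6:10, rep(0, 10), rep(0, 10)), "empty")
})

test_that("shared correlation matches the hand Pearson formula", {
  a <- c(1, 2, 4, 6)
  b <- c(2, 2.5, 5, 9)
  hand_r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  sc <- shared_correlation(a, b, 1:4)
  expect_equal(sc$r, hand_r, tolerance = 1e-12)
  expect_equal(sc$z, atanh(hand_r))
  # identity: r = 1
  expect_error(shared_correlation(a, a, 1:4), NA)
  # atanh closed form at r = 0.5
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
  expect_error(shared_correlation(a, b, 1:2), "at least 3")
  expect_error(shared_correlation(a, rep(1, 4), 1:4), "zero variance")
})

test_that("test-retest on duplicated runs gives r = 1", {
  sp <- simulate_patch(n_rows = 3, n_cols = 8)
  Y <- simulate_voxels(haptic, sp$truth, noise_sd = 0.3, seed = 41)
  tr <- testretest_split(list(Y, Y), haptic, refine = FALSE)
  expect_equal(tr$cor$r, 1, tolerance = 1e-9)
  expect_error(testretest_split(list(Y), haptic), "at least 2")
})

test_that("test-retest is reliable on tuned patches, null on noise", {
  sp <- simulate_patch(n_rows = 3, n_cols = 10)
  rs <- vapply(1:10, function(rep) {
    runs <- lapply(1:4, function(k)
      simulate_voxels(haptic, sp$truth, seed = 500 + rep * 10 + k))
    testretest_split(runs, haptic, refine = FALSE)$cor$r
  }, numeric(1))
  expect_gte(median(rs), 0.8)
  # pure-noise voxels: preferences uncorrelated between halves
  null_truth <- simulate_truth(n_null = 40, seed = 51)
  ps <- vapply(1:10, function(rep) {
    runs <- lapply(1:4, function(k)
      simulate_voxels(haptic, null_truth, noise_sd = 1,
                      seed = 900 + rep * 10 + k))
    runs <- lapply(runs, function(Y) Y)
    odd <- (runs[[1]] + runs[[3]]) / 2
    even <- (runs[[2]] + runs[[4]]) / 2
    f_odd <- fit_prf(odd, haptic, refine = FALSE)
    f_even <- fit_prf(even, haptic, refine = FALSE)
    ok <- which(!is.na(f_odd$pref) & !is.na(f_even$pref))
    shared_correlation(f_odd$pref, f_even$pref, ok)$p
  }, numeric(1))
  expect_lte(sum(ps < 0.05), 3)
})

test_that("group comparison of correlations matches a hand ANOVA oracle", {
  g <- list(a = c(0.1, 0.2, 0.3), b = c(0.4, 0.5, 0.6),
            c = c(0.15, 0.35, 0.55))
  res <- compare_correlation_groups(g)
  z <- lapply(g, atanh)
  gm <- mean(unlist(z))
  ssb <- sum(vapply(z, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(z, function(v) sum((v - mean(v))^2), 1))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova$f, f_hand, tolerance = 1e-9)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 6)
  # Bonferroni: raw p times number of pairs, capped at 1
  expect_equal(res$pairwise$p_adj,
               pmin(res$pairwise$p_raw * 3, 1))
})

test_that("group comparison detects separation and accepts identity", {
  same <- list(a = c(0.1, 0.2, 0.3, 0.25), b = c(0.1, 0.2, 0.3, 0.25))
  res_same <- compare_correlation_groups(same)
  expect_equal(res_same$anova$f, 0, tolerance = 1e-12)
  expect_equal(res_same$pairwise$p_adj, 1)
  shifted <- list(lo = atanh(c(0.05, 0.1, 0.12, 0.08)),
                  hi = atanh(c(0.9, 0.92, 0.95, 0.93)))
  res_sh <- compare_correlation_groups(lapply(shifted, tanh))
  expect_lt(res_sh$pairwise$p_adj, 0.05)
  expect_lt(res_sh$anova$p, 0.05)
  # |r| = 1 is flagged and excluded
  expect_warning(
    compare_correlation_groups(list(a = c(0.2, 1, 0.4, 0.3),
                                    b = c(0.1, 0.2, 0.5))),
    "infinite z")
})

test_that("arcsine transform hits its closed-form anchors", {
  expect_equal(arcsin_proportion(0), 0)
  expect_equal(arcsin_proportion(1), pi / 2)
  expect_equal(arcsin_proportion(0.5), pi / 4)
  expect_error(arcsin_proportion(1.1), "0, 1")
  expect_error(arcsin_proportion(-0.1), "0, 1")
})

test_that("between-modality correlations spread wider than test-retest", {
  # preference maps with independent gradients overlapping on 34% of
  # vertices, versus two noisy measurements of one map
  set.seed(61)
  n <- 120
  shared <- seq_len(round(0.34 * n))
  r_between <- numeric(100)
  r_within <- numeric(100)
  for (i in 1:100) {
    gx <- seq(0, 1, length.out = n)
    mapA <- exp(log(1) + gx * log(7)) * exp(rnorm(n, 0, 0.2))
    mapB <- exp(log(1) + sample(gx) * log(7)) * exp(rnorm(n, 0, 0.2))
    r_between[i] <- shared_correlation(mapA, mapB, shared)$r
    m1 <- mapA * exp(rnorm(n, 0, 0.15))
    m2 <- mapA * exp(rnorm(n, 0, 0.15))
    r_within[i] <- shared_correlation(m1, m2, seq_len(n))$r
  }
  expect_gt(var(r_between), var(r_within))
  expect_gt(mean(r_within), mean(r_between))
})
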