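test_that("geodesic distances match direct geometry on simple meshes", {
  sp <- simulate_patch(n_rows = 2, n_cols = 6, spacing = 2)
  d <- geodesic_distance(sp$patch, sources = 1L)
  expect_equal(d[1], 0)
  # along the first row the strip is a straight line of edges
  expect_equal(d[2:6], 2 * (1:5))
})

test_that("geodesic distances match a brute-force all-paths oracle", {
  sp <- simulate_patch(n_rows = 3, n_cols = 3, spacing = 2)
  f <- sp$patch$faces
  v <- sp$patch$vertices
  edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)]), 1, sort)))
  elen <- sqrt(rowSums((v[edges[, 1], ] - v[edges[, 2], ])^2))
  nbr <- lapply(1:9, function(i) {
    hit <- edges[, 1] == i | edges[, 2] == i
    list(to = ifelse(edges[hit, 1] == i, edges[hit, 2], edges[hit, 1]),
         w = elen[hit])
  })
  # exhaustive simple-path search
  best <- rep(Inf, 9)
  walk <- function(node, dist, seen) {
    if (dist < best[node]) best[node] <<- dist
    nb <- nbr[[node]]
    for (j in seq_along(nb$to)) {
      if (!(nb$to[j] %in% seen)) {
        walk(nb$to[j], dist + nb$w[j], c(seen, nb$to[j]))
      }
    }
  }
  walk(1L, 0, 1L)
  expect_equal(geodesic_distance(sp$patch, 1L), best, tolerance = 1e-12)
})

test_that("normalised progression distance maps borders to 0 and L", {
  sp <- simulate_patch(n_rows = 4, n_cols = 9, spacing = 2)
  nd <- normalized_progression_distance(sp$patch, sp$roi)
  L <- mean(nd$d_low + nd$d_high)
  expect_equal(nd$distance[nd$vertex %in% sp$roi$low_border],
               rep(0, 4))
  expect_equal(nd$distance[nd$vertex %in% sp$roi$high_border],
               rep(L, 4))
  # midline column of a symmetric strip sits at L/2
  mid <- seq_len(4 * 9) %% 9 == 5
  expect_equal(nd$distance[mid], rep(L / 2, 4))
})

test_that("normalised distance is invariant to rigid motion", {
  sp <- simulate_patch(n_rows = 3, n_cols = 7, spacing = 2)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  moved <- surface_patch(sp$patch$vertices %*% t(R) +
                           matrix(c(5, -3, 2), nrow(sp$patch$vertices), 3,
                                  byrow = TRUE),
                         sp$patch$faces)
  d1 <- normalized_progression_distance(sp$patch, sp$roi)$distance
  d2 <- normalized_progression_distance(moved, sp$roi)$distance
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("progression fit recovers an exact logarithmic gradient", {
  centers <- (1:10 - 0.5) * 2
  d <- rep(centers, each = 5)
  y <- 1.2 + 0.8 * log(d + 1)
  pr <- binned_progression_fit(d, y, bin_width = 2, n_boot = 200,
                               n_perm = 500, seed = 1)
  expect_equal(pr$slope, 0.8, tolerance = 1e-6)
  expect_equal(pr$intercept, 1.2, tolerance = 1e-6)
  expect_equal(pr$slope_boot, 0.8, tolerance = 1e-6)
  expect_lte(pr$perm_p, 1 / 100)
  # constant preferences: slope 0, permutation cannot beat it
  pr0 <- binned_progression_fit(d, rep(3, length(d)), bin_width = 2,
                                n_boot = 50, n_perm = 100, seed = 1)
  expect_equal(pr0$slope, 0)
  expect_equal(pr0$perm_p, 1)
  expect_error(binned_progression_fit(d[1:5], y[1:5], bin_width = 50),
               "3 non-empty bins")
})

test_that("permutation p is reproducible bit-for-bit under a fixed seed", {
  set.seed(77)
  d <- runif(120, 0, 24)
  y <- 1 + 0.3 * log(d + 1) + rnorm(120, 0, 0.6)
  a <- binned_progression_fit(d, y, seed = 123, n_boot = 300, n_perm = 300)
  b <- binned_progression_fit(d, y, seed = 123, n_boot = 300, n_perm = 300)
  expect_identical(a$perm_p, b$perm_p)
  expect_identical(a$ci, b$ci)
})

test_that("slope sign flips when the borders are swapped", {
  sp <- simulate_patch(n_rows = 5, n_cols = 12)
  nd <- normalized_progression_distance(sp$patch, sp$roi)
  pr <- binned_progression_fit(nd$distance, sp$truth$pref, n_boot = 100,
                               n_perm = 100, seed = 2)
  swapped <- roi_map(sp$roi$members, sp$roi$high_border, sp$roi$low_border)
  nd2 <- normalized_progression_distance(sp$patch, swapped)
  pr2 <- binned_progression_fit(nd2$distance, sp$truth$pref, n_boot = 100,
                                n_perm = 100, seed = 2)
  expect_gt(pr$slope, 0)
  expect_lt(pr2$slope, 0)
})

test_that("tuning-width progression fits are exact on exact data", {
  pref <- runif(200, 1, 7)
  # constant width: slope 0
  tw0 <- tuning_width_progression(pref, rep(2, 200), n_boot = 50,
                                  n_perm = 50, seed = 1)
  expect_equal(tw0$slope, 0, tolerance = 1e-12)
  # exact linear relation recovered
  tw <- tuning_width_progression(pref, 0.5 + 0.9 * pref, n_boot = 50,
                                 n_perm = 50, seed = 1)
  expect_equal(tw$slope, 0.9, tolerance = 1e-6)
  expect_equal(tw$intercept, 0.5, tolerance = 1e-6)
})

test_that("vertex-unit bootstrap is available as an alternative", {
  set.seed(5)
  d <- runif(150, 0, 28)
  y <- 1 + 0.5 * log(d + 1) + rnorm(150, 0, 0.4)
  pr <- binned_progression_fit(d, y, n_boot = 200, n_perm = 50, seed = 9,
                               boot_unit = "vertices")
  expect_true(pr$ci[1] < pr$slope_boot && pr$slope_boot < pr$ci[2])
})

test_that("cortical magnification percentages are normalised", {
  sp <- simulate_patch(n_rows = 6, n_cols = 15)
  cm <- cortical_magnification(list(sp$truth$pref))
  expect_equal(sum(cm$per_map$pct), 100, tolerance = 1e-9)
  # uniform preferences over bins: all bins ~ 100/7, contrast ~ 0
  set.seed(11)
  unif <- lapply(1:12, function(i) sample(1:7, 700, replace = TRUE) +
                   runif(700, -0.45, 0.45))
  cmu <- cortical_magnification(unif)
  expect_equal(cmu$mean_pct$pct, rep(100 / 7, 7), tolerance = 1.5)
  expect_lt(abs(mean(cmu$scores)), 10)
  expect_gt(cmu$p, 0.05)
  expect_error(cortical_magnification(list(numeric(0))), "empty")
})

test_that("log-spaced preference maps show decreasing magnification", {
  set.seed(12)
  maps <- lapply(1:10, function(i) {
    p <- exp(runif(400, log(1), log(7)))
    pmin(pmax(p * exp(rnorm(400, 0, 0.1)), 1), 7)
  })
  cm <- cortical_magnification(maps)
  expect_lt(cm$p, 0.05)
  grp <- cortical_magnification_groups(list(a = maps[1:5], b = maps[6:10]))
  expect_equal(grp$p_fdr, p.adjust(grp$p, "BH"))
})
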