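# build a toy glove trace by hand: known bumps inside known epochs
toy_glove <- function(bumps_per_epoch, rate = 52, n_epochs = 4,
                      noise_sd = 0) {
  period <- 7.5
  ev <- tibble::tibble(onset = period * (seq_len(n_epochs) - 1),
                       duration = 3,
                       numerosity = rep_len(c(2L, 5L), n_epochs),
                       condition = "haptic_equal_size")
  tl <- run_timeline(ev, tr = 1.5, n_frames_total = n_epochs * 5 + 2,
                     n_frames_discarded = 0, modality = "haptic")
  t <- seq(0, (tl$n_frames_total) * 1.5 - 1 / rate, by = 1 / rate)
  x <- numeric(length(t))
  for (e in seq_len(n_epochs)) {
    k <- bumps_per_epoch[[e]]
    if (k == 0) next
    centers <- ev$onset[e] + (seq_len(k) - 0.5) * ev$duration[e] / k
    for (cc in centers) {
      x <- x + exp(-(t - cc)^2 / (2 * 0.08^2))
    }
  }
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  list(trace = tibble::tibble(time = t, finger_1 = x), timeline = tl)
}

test_that("epoch metrics are zero on flat epochs", {
  g <- toy_glove(rep(0, 4))
  m <- epoch_metrics(g$trace, g$timeline)
  expect_equal(m$n_peaks, rep(0L, 4))
  expect_equal(m$motion_sd, rep(0, 4))
  expect_equal(m$motion_duration, rep(0, 4))
})

test_that("epoch metrics count injected movements exactly", {
  for (k in 1:5) {
    g <- toy_glove(rep(k, 4))
    m <- epoch_metrics(g$trace, g$timeline)
    expect_equal(m$n_peaks, rep(k, 4))
  }
  # a single clean triangular bump (compact support): duration spans its
  # rise-to-fall extent
  g1 <- toy_glove(rep(0, 4))
  tt <- g1$trace$time
  tri <- pmax(0, 1 - abs(tt - 1.5) / 0.5)  # rises 1.0 s -> peak -> 2.0 s
  g1$trace$finger_1 <- tri
  m1 <- epoch_metrics(g1$trace, g1$timeline)
  expect_equal(m1$n_peaks[1], 1)
  expect_equal(m1$motion_duration[1], 1, tolerance = 0.05)
})

test_that("epoch metrics are invariant to a constant offset", {
  set.seed(14)
  g <- toy_glove(c(2, 3, 1, 2), noise_sd = 0.002)
  m0 <- epoch_metrics(g$trace, g$timeline)
  shifted <- g$trace
  shifted$finger_1 <- shifted$finger_1 + 11.5
  m1 <- epoch_metrics(shifted, g$timeline)
  expect_equal(m1$n_peaks, m0$n_peaks)
  expect_equal(m1$motion_sd, m0$motion_sd, tolerance = 1e-9)
  expect_equal(m1$motion_duration, m0$motion_duration)
})

test_that("glove pipeline recovers per-epoch metrics across fingers", {
  g <- simulate_glove(haptic, seed = 3)
  m <- epoch_metrics(g, haptic)
  expect_equal(nrow(m), nrow(haptic$events) * 5)
  avg <- average_fingers(m)
  expect_equal(nrow(avg), nrow(haptic$events))
  expect_true(all(avg$motion_duration <= 3 + 1e-9))
})

test_that("repeated-measures ANOVA matches a hand-computed oracle", {
  # 3 participants x 3 numerosities, one condition
  vals <- matrix(c(1.0, 1.4, 1.1,
                   0.8, 1.3, 1.2,
                   1.1, 1.6, 1.4), nrow = 3, byrow = TRUE)
  dat <- tibble::tibble(
    participant = rep(1:3, each = 3),
    condition = "a",
    numerosity = rep(1:3, times = 3),
    value = as.numeric(t(vals)))
  res <- motion_anova(dat)
  # hand computation: one-way repeated-measures decomposition
  gm <- mean(vals)
  ss_subj <- 3 * sum((rowMeans(vals) - gm)^2)
  ss_cond <- 3 * sum((colMeans(vals) - gm)^2)
  ss_tot <- sum((vals - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  f_hand <- (ss_cond / 2) / (ss_err / 4)
  num <- res$anova[res$anova$effect == "numerosity", ]
  expect_equal(num$f, f_hand, tolerance = 1e-9)
  expect_equal(num$df1, 2)
  expect_equal(num$df2, 4)
})

test_that("ANOVA degenerates correctly and validates cells", {
  dat <- tidyr::expand_grid(participant = 1:4, condition = c("a", "b"),
                            numerosity = 1:3)
  dat$value <- 2                       # identical cell means
  res <- motion_anova(dat)
  expect_equal(res$anova$f, rep(0, 3))
  expect_equal(res$anova$p, rep(1, 3))
  expect_error(motion_anova(dat[-1, ]), "missing cells")
  # two-way layout reports both factors and their interaction
  set.seed(9)
  dat$value <- rnorm(nrow(dat))
  res2 <- motion_anova(dat)
  expect_setequal(res2$anova$effect,
                  c("condition", "numerosity", "condition:numerosity"))
  expect_gt(res2$bf01_numerosity, 0)
})

test_that("motion metrics do not vary with numerosity under the null", {
  cells <- purrr::map_dfr(1:5, function(pp) {
    g <- simulate_glove(haptic, rate = 26, n_fingers = 2,
                        seed = 700 + pp)
    m <- average_fingers(epoch_metrics(g, haptic))
    m |>
      dplyr::filter(.data$numerosity != 20) |>
      dplyr::group_by(.data$numerosity) |>
      dplyr::summarise(value = mean(.data$motion_sd), .groups = "drop") |>
      dplyr::mutate(participant = pp, condition = "a")
  })
  res <- motion_anova(cells)
  num <- res$anova[res$anova$effect == "numerosity", ]
  expect_equal(num$df1, 6)
  expect_equal(num$df2, 24)
  expect_gt(num$p, 0.01)
  expect_gt(res$bf01_numerosity, 1)  # evidence direction favours the null
})

test_that("behaviour summary computes error rates and medians", {
  b0 <- simulate_behavior(error_slope = 0, seed = 2)
  s0 <- behavior_summary(b0)
  expect_true(all(s0$error_rate_pct == 0))
  # 20 trials with 5 errors -> 25%
  tab <- tibble::tibble(participant = 1, numerosity = 5,
                        correct = rep(c(FALSE, TRUE), c(5, 15)),
                        rt_s = seq(0.5, 2.4, length.out = 20))
  s <- behavior_summary(tab)
  expect_equal(s$error_rate_pct, 25)
  expect_equal(s$median_rt_s, median(tab$rt_s))
})

test_that("behavioural error curve matches the generator expectation", {
  b <- simulate_behavior(n_participants = 5, n_trials_per_numerosity = 20,
                         subitizing_limit = 3, error_slope = 0.15,
                         seed = 13)
  s <- behavior_summary(b) |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(err = mean(.data$error_rate_pct) / 100,
                     .groups = "drop")
  for (n in 1:7) {
    expected <- max(0, 0.15 * (n - 3))
    se <- sqrt(max(expected * (1 - expected), 0.002) / 100)
    expect_lt(abs(s$err[s$numerosity == n] - expected), 4 * se)
  }
})

test_that("behavioural tests match hand-computed statistics", {
  b <- simulate_behavior(seed = 17)
  res <- behavior_tests(b)
  expect_equal(res$friedman$df, 6)
  expect_lt(res$friedman$p, 0.05)  # RT increases with numerosity
  # hand chi-square for one pooled 2x2 pair
  pooled <- b |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(errors = sum(!.data$correct), n = dplyr::n(),
                     .groups = "drop")
  a <- pooled[pooled$numerosity == 1, ]
  d <- pooled[pooled$numerosity == 7, ]
  m <- rbind(c(a$errors, a$n - a$errors), c(d$errors, d$n - d$errors))
  nn <- sum(m)
  chi_hand <- nn * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
  row17 <- res$pairwise_error[res$pairwise_error$num1 == 1 &
                                res$pairwise_error$num2 == 7, ]
  expect_equal(row17$chisq, chi_hand, tolerance = 1e-9)
  expect_equal(res$pairwise_error$p_adj,
               pmin(res$pairwise_error$p_raw * 21, 1))
  # identical RT profiles: Friedman statistic collapses to 0
  flat <- b
  flat$rt_s <- rep(1, nrow(flat))
  res_flat <- behavior_tests(flat)
  expect_lt(res_flat$friedman$chisq, 1e-9)
})

test_that("behavioural profiles correlate across modalities", {
  hap <- simulate_behavior(modality = "haptic", seed = 23)
  vis <- simulate_behavior(modality = "visual", rt_base = 0.6, seed = 24)
  sp_rt <- behavior_spearman(hap, vis, "rt")
  expect_gt(sp_rt$rho, 0.3)
  expect_lt(sp_rt$p, 0.05)
  # perfectly monotone paired profiles: rho = 1
  t1 <- tibble::tibble(participant = 1, numerosity = 1:7, correct = TRUE,
                       rt_s = 1:7)
  t2 <- tibble::tibble(participant = 1, numerosity = 1:7, correct = TRUE,
                       rt_s = (1:7)^2)
  expect_equal(behavior_spearman(t1, t2, "rt")$rho, 1)
})
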