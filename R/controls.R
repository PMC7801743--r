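# local maxima of x whose prominence (height above the higher of the two
# flanking minima down to higher terrain) exceeds `min_prom`
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- sign(diff(x))
  # carry slope through flat plateaus so a flat-topped peak counts once
  for (i in seq_along(d)) {
    if (d[i] == 0 && i > 1L) d[i] <- d[i - 1L]
  }
  cand <- which(diff(d) < 0) + 1L
  keep <- vapply(cand, function(i) {
    # walk left/right until terrain rises above the peak; base = min en route
    left <- x[seq_len(i - 1L)]
    right <- x[seq.int(i + 1L, n)]
    higher_l <- which(rev(left) > x[i])
    base_l <- if (length(higher_l)) {
      min(rev(left)[seq_len(higher_l[1])])
    } else {
      min(left)
    }
    higher_r <- which(right > x[i])
    base_r <- if (length(higher_r)) {
      min(right[seq_len(higher_r[1])])
    } else {
      min(right)
    }
    (x[i] - max(base_l, base_r)) > min_prom
  }, logical(1))
  cand[keep]
}

#' Per-epoch finger-motion metrics from a glove trace
#'
#' For every stimulus exploration epoch of the timeline and every sensor
#' channel, quantifies motion by three parameters: the amount of motion
#' (number of distinct movements, counted as signal peaks above a
#' prominence threshold), the variation of motion (STD of the signal in the
#' epoch), and the duration of motion (time between the first and last
#' change in sensor values exceeding a noise threshold, irrespective of the
#' beginning and end positions).
#'
#' The peak prominence threshold is `prominence_frac` times the epoch's
#' signal range; the change threshold is `duration_k` times the median
#' absolute successive difference of the inter-epoch quiescent segments.
#' An optional moving-average smoothing window may be applied first
#' (default none).
#'
#' @param trace Glove tibble from [simulate_glove()] (a `time` column plus
#'   one column per sensor).
#' @param timeline The haptic [run_timeline()] the trace was recorded
#'   under.
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   epoch range (default 0.1).
#' @param duration_k Multiplier of the quiescent-segment noise scale for
#'   the duration threshold (default 3).
#' @param smooth_window Moving-average window in samples (0 disables).
#' @return A tibble with one row per epoch x finger: `epoch`, `onset`,
#'   `numerosity`, `condition`, `finger`, `n_peaks`, `motion_sd`,
#'   `motion_duration`, `excluded` (epochs shorter than 3 samples).
#' @export
epoch_metrics <- function(trace, timeline, prominence_frac = 0.1,
                          duration_k = 3, smooth_window = 0) {
  stopifnot(inherits(timeline, "run_timeline"), "time" %in% names(trace))
  fingers <- setdiff(names(trace), "time")
  t <- trace$time
  ev <- timeline$events
  in_epoch <- rep(FALSE, length(t))
  for (i in seq_len(nrow(ev))) {
    in_epoch <- in_epoch | (t >= ev$onset[i] &
                              t < ev$onset[i] + ev$duration[i])
  }
  epoch_idx <- lapply(seq_len(nrow(ev)), function(i)
    which(t >= ev$onset[i] & t < ev$onset[i] + ev$duration[i]))
  ne <- nrow(ev)
  out <- vector("list", length(fingers))
  for (fi in seq_along(fingers)) {
    f <- fingers[fi]
    x <- trace[[f]]
    if (smooth_window > 1) {
      xs0 <- as.numeric(stats::filter(x, rep(1 / smooth_window,
                                             smooth_window), sides = 2))
      xs0[is.na(xs0)] <- x[is.na(xs0)]
      x <- xs0
    }
    quiet <- x[!in_epoch]
    noise_thr <- duration_k * stats::median(abs(diff(quiet)))
    n_peaks <- integer(ne)
    motion_sd <- numeric(ne)
    dur <- numeric(ne)
    excl <- logical(ne)
    for (i in seq_len(ne)) {
      idx <- epoch_idx[[i]]
      if (length(idx) < 3L) {
        n_peaks[i] <- NA_integer_
        motion_sd[i] <- NA_real_
        dur[i] <- NA_real_
        excl[i] <- TRUE
        next
      }
      xs <- x[idx]
      ts <- t[idx]
      rng <- diff(range(xs))
      n_peaks[i] <- if (rng == 0) 0L else
        length(find_peaks(xs, prominence_frac * rng))
      changes <- which(abs(diff(xs)) > noise_thr)
      dur[i] <- if (length(changes) == 0L) 0 else
        ts[max(changes) + 1L] - ts[min(changes)]
      motion_sd[i] <- stats::sd(xs)
    }
    out[[fi]] <- tibble::tibble(
      epoch = seq_len(ne), onset = ev$onset,
      numerosity = ev$numerosity, condition = ev$condition, finger = f,
      n_peaks = n_peaks, motion_sd = motion_sd, motion_duration = dur,
      excluded = excl)
  }
  dplyr::bind_rows(out)
}

#' Average epoch metrics across fingers
#'
#' Group analyses use metrics averaged across the sensor channels.
#'
#' @param metrics Output of [epoch_metrics()].
#' @return A tibble with one row per epoch: metric means across fingers.
#' @export
average_fingers <- function(metrics) {
  metrics |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$epoch, .data$onset, .data$numerosity,
                    .data$condition) |>
    dplyr::summarise(n_peaks = mean(.data$n_peaks),
                     motion_sd = mean(.data$motion_sd),
                     motion_duration = mean(.data$motion_duration),
                     .groups = "drop")
}

#' Repeated-measures ANOVA on motion metrics
#'
#' Two-way repeated-measures ANOVA (haptic stimulus condition x
#' numerosity, participants as the repeated factor) on per-participant
#' cell means of one motion metric, plus a Bayes-factor approximation for
#' the numerosity effect: `BF01 = exp((BIC_full - BIC_null) / 2)` comparing
#' additive models with and without the numerosity factor. The BF01 is a
#' BIC approximation, not equivalent to default-prior Bayesian ANOVA.
#'
#' @param data A tibble with columns `participant`, `condition`,
#'   `numerosity` and `value` (raw epochs or cell means; averaged to cell
#'   means internally). Every participant must have every
#'   condition x numerosity cell.
#' @return A `motion_anova` list: `anova` (tibble with F, df and p per
#'   effect), `bf01_numerosity`, `cells` (the cell means).
#' @export
motion_anova <- function(data) {
  req <- c("participant", "condition", "numerosity", "value")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns participant, condition, numerosity, value",
         call. = FALSE)
  }
  cells <- data |>
    dplyr::group_by(.data$participant, .data$condition, .data$numerosity) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  full_grid <- tidyr::expand_grid(
    participant = unique(cells$participant),
    condition = unique(cells$condition),
    numerosity = unique(cells$numerosity))
  missing <- dplyr::anti_join(full_grid, cells,
                              by = c("participant", "condition",
                                     "numerosity"))
  if (nrow(missing) > 0L) {
    stop("missing cells: ",
         paste(sprintf("(%s, %s, %s)", missing$participant,
                       missing$condition, missing$numerosity),
               collapse = ", "), call. = FALSE)
  }
  cells <- cells |>
    dplyr::mutate(participant = factor(.data$participant),
                  condition = factor(.data$condition),
                  numerosity = factor(.data$numerosity))
  n_cond <- nlevels(cells$condition)
  if (stats::sd(cells$value) == 0) {
    # all cell means identical: no effect of anything, by convention F = 0
    effects <- if (n_cond > 1L) {
      c("condition", "numerosity", "condition:numerosity")
    } else {
      "numerosity"
    }
    an <- tibble::tibble(effect = effects, df1 = NA_real_, df2 = NA_real_,
                         f = 0, p = 1)
    return(structure(list(anova = an, bf01_numerosity = NA_real_,
                          cells = cells), class = "motion_anova"))
  }
  if (n_cond > 1L) {
    fit <- stats::aov(value ~ condition * numerosity +
                        Error(participant / (condition * numerosity)),
                      data = cells)
    sm <- summary(fit)
    pull_effect <- function(label) {
      for (stratum in sm) {
        tab <- stratum[[1]]
        hit <- which(trimws(rownames(tab)) == label)
        if (length(hit)) {
          return(tibble::tibble(effect = label, df1 = tab$Df[hit],
                                df2 = tab$Df[nrow(tab)],
                                f = tab$`F value`[hit],
                                p = tab$`Pr(>F)`[hit]))
        }
      }
      NULL
    }
    an <- dplyr::bind_rows(pull_effect("condition"),
                           pull_effect("numerosity"),
                           pull_effect("condition:numerosity"))
  } else {
    fit <- stats::aov(value ~ numerosity + Error(participant / numerosity),
                      data = cells)
    tab <- summary(fit)[["Error: participant:numerosity"]][[1]]
    an <- tibble::tibble(effect = "numerosity", df1 = tab$Df[1],
                         df2 = tab$Df[2], f = tab$`F value`[1],
                         p = tab$`Pr(>F)`[1])
  }
  base_terms <- c("participant", if (n_cond > 1L) "condition")
  lm_full <- stats::lm(stats::reformulate(c(base_terms, "numerosity"),
                                          "value"), data = cells)
  lm_null <- stats::lm(stats::reformulate(base_terms, "value"),
                       data = cells)
  bf01 <- exp((stats::BIC(lm_full) - stats::BIC(lm_null)) / 2)
  structure(list(anova = an, bf01_numerosity = bf01, cells = cells),
            class = "motion_anova")
}

#' @export
print.motion_anova <- function(x, ...) {
  cat("<motion_anova> repeated-measures ANOVA on motion cell means\n")
  print(x$anova)
  cat(sprintf("BF01 (numerosity, BIC approximation): %.3g\n",
              x$bf01_numerosity))
  invisible(x)
}

#' @export
tidy.motion_anova <- function(x, ...) x$anova

#' @export
glance.motion_anova <- function(x, ...) {
  num <- x$anova[x$anova$effect == "numerosity", ]
  tibble::tibble(f_numerosity = num$f, p_numerosity = num$p,
                 bf01_numerosity = x$bf01_numerosity)
}

#' Summarise behavioural judgments
#'
#' Per participant and numerosity: error rate (percent incorrect) and the
#' median reaction time, the units on which the group statistics operate.
#'
#' @param table Trial tibble with columns `participant`, `numerosity`,
#'   `correct`, `rt_s` (see [simulate_behavior()]).
#' @return A tibble with one row per participant x numerosity:
#'   `error_rate_pct`, `median_rt_s`, `n_trials`.
#' @export
behavior_summary <- function(table) {
  req <- c("participant", "numerosity", "correct", "rt_s")
  if (!all(req %in% names(table))) {
    stop("`table` needs columns participant, numerosity, correct, rt_s",
         call. = FALSE)
  }
  table |>
    dplyr::group_by(.data$participant, .data$numerosity) |>
    dplyr::summarise(error_rate_pct = 100 * mean(!.data$correct),
                     median_rt_s = stats::median(.data$rt_s),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Behavioural test battery
#'
#' Friedman test of per-participant median reaction times across
#' numerosities, and pairwise chi-square tests of participant-pooled error
#' counts between numerosities with Bonferroni correction (raw p times the
#' number of pairs, capped at 1). Rank ties are handled by average ranks
#' (the [stats::friedman.test()] convention).
#'
#' @param table Trial tibble (one modality/condition), see
#'   [behavior_summary()].
#' @return A list with `friedman` (tibble: `chisq`, `df`, `p`) and
#'   `pairwise_error` (tibble: `num1`, `num2`, `chisq`, `p_raw`, `p_adj`).
#' @export
behavior_tests <- function(table) {
  summ <- behavior_summary(table)
  wide <- summ |>
    dplyr::select("participant", "numerosity", "median_rt_s") |>
    tidyr::pivot_wider(names_from = "numerosity",
                       values_from = "median_rt_s")
  m <- as.matrix(wide[, -1])
  if (nrow(m) < 3L) {
    stop("Friedman test needs at least 3 participants", call. = FALSE)
  }
  fr <- stats::friedman.test(m)
  chisq <- unname(fr$statistic)
  pval <- fr$p.value
  if (!is.finite(chisq)) {
    # complete ties across numerosities: no evidence of any difference
    chisq <- 0
    pval <- 1
  }
  friedman <- tibble::tibble(chisq = chisq,
                             df = unname(fr$parameter), p = pval)
  pooled <- table |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(errors = sum(!.data$correct), n = dplyr::n(),
                     .groups = "drop")
  pairs <- utils::combn(pooled$numerosity, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    a <- pooled[pooled$numerosity == pr[1], ]
    b <- pooled[pooled$numerosity == pr[2], ]
    tab <- rbind(c(a$errors, a$n - a$errors), c(b$errors, b$n - b$errors))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(num1 = pr[1], num2 = pr[2],
                   chisq = unname(ct$statistic), p_raw = ct$p.value)
  })
  pairwise$p_adj <- pmin(pairwise$p_raw * length(pairs), 1)
  list(friedman = friedman, pairwise_error = pairwise)
}

#' Spearman correlation of behavioural profiles between modalities
#'
#' Correlates per-participant per-numerosity reaction-time medians (or
#' error rates) between two experiments, e.g. the visual and one haptic
#' condition, over the concatenated participant x numerosity values.
#'
#' @param table_a,table_b Trial tibbles of the two experiments, same
#'   participants and numerosities.
#' @param measure `"rt"` (median reaction time) or `"error"` (error rate).
#' @return A tibble with `rho`, `p`, `n`.
#' @export
behavior_spearman <- function(table_a, table_b,
                              measure = c("rt", "error")) {
  measure <- match.arg(measure)
  col <- if (measure == "rt") "median_rt_s" else "error_rate_pct"
  a <- behavior_summary(table_a)
  b <- behavior_summary(table_b)
  merged <- dplyr::inner_join(a, b, by = c("participant", "numerosity"),
                              suffix = c("_a", "_b"))
  ct <- suppressWarnings(
    stats::cor.test(merged[[paste0(col, "_a")]],
                    merged[[paste0(col, "_b")]], method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                 n = nrow(merged))
}

#' Plot reaction times by numerosity
#'
#' @param table Trial tibble, see [simulate_behavior()].
#' @return A ggplot box plot of reaction time against numerosity.
#' @export
plot_behavior_rt <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data$numerosity),
                                      y = .data$rt_s)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Numerosity", y = "Reaction time (s)") +
    ggplot2::theme_minimal()
}
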