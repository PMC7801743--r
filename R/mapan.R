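#' Multi-source geodesic distance on a surface patch
#'
#' Shortest-path distance along mesh edges (Dijkstra, edge weight =
#' Euclidean edge length) from the nearest of a set of source vertices.
#' This is the standard graph approximation to the true surface geodesic;
#' it is deterministic and adequate at the 2 mm binning used downstream.
#'
#' @param patch A [surface_patch()].
#' @param sources Non-empty integer vector of source vertex indices.
#' @return Numeric vector of distances (mm), one per vertex; disconnected
#'   vertices get `Inf`.
#' @export
geodesic_distance <- function(patch, sources) {
  stopifnot(inherits(patch, "surface_patch"))
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("`sources` must be non-empty", call. = FALSE)
  f <- patch$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  w <- sqrt(rowSums((patch$vertices[edges[, 1], , drop = FALSE] -
                       patch$vertices[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(patch$vertices)) {
    g <- igraph::add_vertices(g, nrow(patch$vertices) - igraph::vcount(g))
  }
  d <- igraph::distances(g, v = sources, algorithm = "dijkstra")
  apply(d, 2L, min)
}

#' Normalised distance along a topographic map's main axis
#'
#' For each ROI member the geodesic distances to the low- and
#' high-preference end borders are combined into the ratio
#' `d_low / (d_low + d_high)`, a normalised position along the direction of
#' preference change, and rescaled by the mean ROI length
#' `L = mean(d_low + d_high)` so the output is in mm: 0 at the low border
#' and `L` at the high border.
#'
#' @param patch A [surface_patch()].
#' @param roi A [roi_map()].
#' @return A tibble with columns `vertex`, `d_low`, `d_high`, `distance`.
#' @export
normalized_progression_distance <- function(patch, roi) {
  stopifnot(inherits(roi, "roi_map"))
  d_low <- geodesic_distance(patch, roi$low_border)[roi$members]
  d_high <- geodesic_distance(patch, roi$high_border)[roi$members]
  tot <- d_low + d_high
  if (any(tot == 0)) {
    stop("member vertex with zero distance to both borders (border overlap)",
         call. = FALSE)
  }
  if (any(!is.finite(tot))) {
    stop("ROI member disconnected from a border", call. = FALSE)
  }
  L <- mean(tot)
  tibble::tibble(vertex = roi$members, d_low = d_low, d_high = d_high,
                 distance = d_low / tot * L)
}

# closed-form slope/intercept of y ~ a + b x (centred for numerical
# exactness on constant y)
line_fit <- function(x, y) {
  xc <- x - mean(x)
  b <- sum(xc * (y - mean(y))) / sum(xc^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

binned_fit <- function(x_values, y_values, bin_width, n_boot, n_perm, seed,
                       model, eps, what, boot_unit = "bins") {
  stopifnot(length(x_values) == length(y_values), bin_width > 0)
  keep <- is.finite(x_values) & is.finite(y_values)
  x_values <- x_values[keep]
  y_values <- y_values[keep]
  idx <- floor(x_values / bin_width)
  bins <- tibble::tibble(bin = idx, x = x_values, y = y_values) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean = mean(.data$y),
                     sem = stats::sd(.data$y) / sqrt(dplyr::n()),
                     n = dplyr::n(), x_mean = mean(.data$x),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(center = (.data$bin + 0.5) * bin_width)
  if (nrow(bins) < 3L) {
    stop("need at least 3 non-empty bins", call. = FALSE)
  }
  # log model: abscissa at the nominal bin centre (offset by eps);
  # linear model: within-bin mean abscissa, exact on exactly linear data
  xb <- if (model == "log") log(bins$center + eps) else bins$x_mean
  yb <- bins$mean
  obs <- line_fit(xb, yb)
  nb <- nrow(bins)
  seeds <- child_seeds(seed, 2)
  boot <- if (boot_unit == "bins") {
    # resample the bins with replacement, refit (vectorised closed form)
    with_seed(seeds[1], {
      S <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
      X <- matrix(xb[S], nrow = n_boot)
      Y <- matrix(yb[S], nrow = n_boot)
      mx <- rowMeans(X)
      my <- rowMeans(Y)
      sxx <- rowSums(X^2) - nb * mx^2
      sxy <- rowSums(X * Y) - nb * mx * my
      b <- sxy / sxx
      a <- my - b * mx
      res <- cbind(a, b)
      res[is.finite(b) & sxx > 1e-12, , drop = FALSE]
    })
  } else {
    # alternative unit: resample recording sites, re-bin, refit
    with_seed(seeds[1], {
      ns <- length(x_values)
      res <- matrix(NA_real_, nrow = n_boot, ncol = 2)
      for (i in seq_len(n_boot)) {
        s <- sample.int(ns, ns, replace = TRUE)
        bi <- factor(idx[s], levels = bins$bin)
        ym <- tapply(y_values[s], bi, mean)
        ok <- !is.na(ym)
        if (sum(ok) < 2L || length(unique(xb[ok])) < 2L) next
        res[i, ] <- line_fit(xb[ok], ym[ok])
      }
      res[stats::complete.cases(res), , drop = FALSE]
    })
  }
  # permutation: shuffle the assignment of bin means to bin positions
  perm_slopes <- with_seed(seeds[2], {
    xc <- xb - mean(xb)
    ssx <- sum(xc^2)
    ybc <- yb - mean(yb)
    S <- matrix(0L, nrow = n_perm, ncol = nb)
    for (i in seq_len(n_perm)) S[i, ] <- sample.int(nb)
    drop(matrix(ybc[S], nrow = n_perm) %*% xc) / ssx
  })
  perm_p <- mean(perm_slopes >= obs["slope"])
  structure(
    list(bins = bins[, c("center", "mean", "sem", "n")],
         slope = unname(obs["slope"]), intercept = unname(obs["intercept"]),
         slope_boot = stats::median(boot[, 2]),
         intercept_boot = stats::median(boot[, 1]),
         ci = stats::quantile(boot[, 2], c(0.025, 0.975), names = FALSE),
         boot = boot, perm_p = perm_p, model = model,
         bin_width = bin_width, eps = eps, n_boot = n_boot,
         n_perm = n_perm, what = what),
    class = "progression_result")
}

#' Binned progression of preferred numerosity with cortical distance
#'
#' Bins recording sites into half-open distance intervals of `bin_width`
#' mm along the map's main axis, computes per-bin mean preference and SEM,
#' and fits the logarithmic progression
#' `preference = a + b * ln(distance + eps)` to the bin means. Inference:
#' the bins are resampled with replacement `n_boot` times and refit (median
#' slope/intercept as the best-fitting progression, 2.5/97.5 percentiles as
#' the 95% CI), and the assignment of bin means to bin positions is
#' shuffled `n_perm` times, with
#' `p = #(permuted slope >= observed slope) / n_perm`.
#'
#' @param distances Per-site distances along the map (mm), from
#'   [normalized_progression_distance()].
#' @param preferences Per-site preferred numerosities.
#' @param bin_width Bin width in mm (study value 2).
#' @param n_boot,n_perm Bootstrap and permutation iteration counts (study
#'   value 10,000 each).
#' @param seed RNG seed.
#' @param eps Abscissa offset inside the logarithm (default
#'   `0.5 * bin_width`, guarding against `ln(0)`).
#' @param boot_unit Bootstrap resampling unit: `"bins"` (the default,
#'   resampling the bin means) or `"vertices"` (resampling recording sites
#'   and re-binning each draw).
#' @return A `progression_result`: bin table, observed and bootstrap-median
#'   slope/intercept, bootstrap CI, permutation p.
#' @export
binned_progression_fit <- function(distances, preferences, bin_width = 2,
                                   n_boot = 2000, n_perm = 2000, seed = 1,
                                   eps = 0.5 * bin_width,
                                   boot_unit = c("bins", "vertices")) {
  boot_unit <- match.arg(boot_unit)
  binned_fit(distances, preferences, bin_width, n_boot, n_perm, seed,
             model = "log", eps = eps, what = "preference ~ ln(distance)",
             boot_unit = boot_unit)
}

#' Progression of tuning width with preferred numerosity
#'
#' As [binned_progression_fit()], but the abscissa is preferred numerosity
#' (bins of `bin_width` numerosity units, study value 0.25), the ordinate
#' is mean tuning width per bin, and the fitted model is linear.
#'
#' @param preferences Per-site preferred numerosities.
#' @param fwhm Per-site tuning widths (linear-space FWHM).
#' @param bin_width Bin width in numerosity units (study value 0.25).
#' @inheritParams binned_progression_fit
#' @return A `progression_result` with a linear fit.
#' @export
tuning_width_progression <- function(preferences, fwhm, bin_width = 0.25,
                                     n_boot = 2000, n_perm = 2000,
                                     seed = 1) {
  binned_fit(preferences, fwhm, bin_width, n_boot, n_perm, seed,
             model = "linear", eps = 0,
             what = "tuning width ~ preferred numerosity")
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf("<progression_result> %s (%s fit)\n", x$what, x$model))
  cat(sprintf("  %d bins (width %g); slope %.4f [%.4f, %.4f], permutation p = %.4g\n",
              nrow(x$bins), x$bin_width, x$slope, x$ci[1], x$ci[2],
              x$perm_p))
  invisible(x)
}

#' @export
tidy.progression_result <- function(x, ...) x$bins

#' @export
glance.progression_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope_boot_median = x$slope_boot,
                 ci_lower = x$ci[1], ci_upper = x$ci[2],
                 perm_p = x$perm_p, n_bins = nrow(x$bins),
                 model = x$model)
}

#' Plot a progression result
#'
#' Bin means with SEM error bars, the fitted progression and the bootstrap
#' 95% confidence band.
#'
#' @param object A `progression_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progression_result <- function(object, ...) {
  xg <- seq(min(object$bins$center), max(object$bins$center),
            length.out = 100)
  xf <- if (object$model == "log") log(xg + object$eps) else xg
  lines <- object$boot
  band <- apply(lines, 1L, function(ab) ab[1] + ab[2] * xf)
  fit_df <- tibble::tibble(
    x = xg,
    fit = object$intercept_boot + object$slope_boot * xf,
    lo = apply(band, 1L, stats::quantile, 0.025),
    hi = apply(band, 1L, stats::quantile, 0.975))
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$center, y = .data$mean)) +
    ggplot2::geom_ribbon(data = fit_df,
                         ggplot2::aes(x = .data$x, y = .data$fit,
                                      ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(data = fit_df,
                       ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = if (object$model == "log") "Distance (mm)"
                  else "Preferred numerosity",
                  y = if (object$model == "log") "Preferred numerosity"
                  else "Tuning width (FWHM)",
                  subtitle = sprintf("slope %.3f, permutation p = %.3g",
                                     object$slope, object$perm_p)) +
    ggplot2::theme_minimal()
}

#' Cortical magnification across numerosity
#'
#' Computes, for each map, the percentage of map surface (member vertices)
#' preferring each numerosity in unit-width bins centred on 1-7, and tests
#' the group of maps for a linear decrease of coverage with numerosity
#' using a planned-comparison contrast: per-map score
#' `sum(w_k * pct_k)` with centred decreasing linear weights
#' `w = (3, 2, 1, 0, -1, -2, -3)`, followed by a one-sided one-sample
#' t-test of the scores against 0.
#'
#' @param pref_list List of numeric vectors, one per map, of preferred
#'   numerosities masked to `[1, 7]`.
#' @return A list with elements `per_map` (tibble map x bin with `pct`),
#'   `mean_pct` (per-bin mean across maps), `scores`, `t`, `df`, `p`.
#' @export
cortical_magnification <- function(pref_list) {
  if (!is.list(pref_list)) pref_list <- list(pref_list)
  if (any(lengths(pref_list) == 0L)) {
    stop("empty ROI in `pref_list`", call. = FALSE)
  }
  centers <- 1:7
  breaks <- seq(0.5, 7.5, by = 1)
  w <- rev(centers) - mean(centers)      # (3, 2, 1, 0, -1, -2, -3)
  per_map <- purrr::map_dfr(seq_along(pref_list), function(m) {
    p <- pref_list[[m]]
    cnt <- as.integer(table(cut(p, breaks, include.lowest = TRUE)))
    tibble::tibble(map = m, numerosity = centers,
                   pct = 100 * cnt / sum(cnt))
  })
  scores <- per_map |>
    dplyr::group_by(.data$map) |>
    dplyr::summarise(score = sum(.data$pct * w), .groups = "drop")
  if (nrow(scores) >= 2L && stats::sd(scores$score) > 0) {
    tt <- stats::t.test(scores$score, alternative = "greater")
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  } else {
    t_stat <- NA_real_
    df <- NA_real_
    p <- NA_real_
  }
  mean_pct <- per_map |>
    dplyr::group_by(.data$numerosity) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop")
  list(per_map = per_map, mean_pct = mean_pct, scores = scores$score,
       t = t_stat, df = df, p = p)
}

#' Cortical magnification across several map groups with FDR correction
#'
#' Runs [cortical_magnification()] on each group of maps and adjusts the
#' one-sided p-values across groups by the Benjamini-Hochberg false
#' discovery rate.
#'
#' @param groups Named list; each element is a list of per-map preference
#'   vectors.
#' @return A tibble with one row per group: `group`, `t`, `df`, `p`,
#'   `p_fdr`.
#' @export
cortical_magnification_groups <- function(groups) {
  res <- purrr::map(groups, cortical_magnification)
  out <- tibble::tibble(
    group = names(groups) %||% as.character(seq_along(groups)),
    t = purrr::map_dbl(res, "t"),
    df = purrr::map_dbl(res, "df"),
    p = purrr::map_dbl(res, "p"))
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
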