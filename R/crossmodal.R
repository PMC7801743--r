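#' Overlap between two thresholded maps
#'
#' Shared vertices are those present in both maps whose variance explained
#' exceeds the threshold in both modalities. The overlap percentage is
#' reported relative to each map and as their mean (the study averages
#' across participants, hemispheres and modalities).
#'
#' @param maskA,maskB Integer vertex sets of the two maps (same vertex
#'   index space).
#' @param r2A,r2B Per-vertex variance explained for each modality, indexed
#'   by vertex; `NULL` skips thresholding for that map.
#' @param threshold Variance-explained threshold (study value 0.30).
#' @return An `overlap_report`: shared vertex set, `pct_a`, `pct_b`,
#'   `pct_mean`.
#' @export
map_overlap <- function(maskA, maskB, r2A = NULL, r2B = NULL,
                        threshold = 0.3) {
  maskA <- as.integer(maskA)
  maskB <- as.integer(maskB)
  above <- function(mask, r2) {
    if (is.null(r2)) mask else mask[r2[mask] > threshold]
  }
  above_a <- above(maskA, r2A)
  above_b <- above(maskB, r2B)
  if (length(above_a) == 0L || length(above_b) == 0L) {
    stop("a thresholded map is empty", call. = FALSE)
  }
  shared <- intersect(above_a, above_b)
  pct_a <- 100 * length(shared) / length(above_a)
  pct_b <- 100 * length(shared) / length(above_b)
  structure(list(shared = shared, pct_a = pct_a, pct_b = pct_b,
                 pct_mean = (pct_a + pct_b) / 2, threshold = threshold),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %d shared vertices; %.1f%% of A, %.1f%% of B (mean %.1f%%)\n",
    length(x$shared), x$pct_a, x$pct_b, x$pct_mean))
  invisible(x)
}

#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(n_shared = length(x$shared), pct_a = x$pct_a,
                 pct_b = x$pct_b, pct_mean = x$pct_mean,
                 threshold = x$threshold)
}

#' Preference correlation over shared vertices
#'
#' Pearson correlation between the preferred numerosities of two maps,
#' restricted to their shared vertices, with the variance-stabilising
#' Fisher z-transform `z = atanh(r)`.
#'
#' @param prefA,prefB Per-vertex preferred numerosities, indexed by vertex.
#' @param shared Integer vector of shared vertex indices (at least 3).
#' @return A tibble with columns `r`, `p`, `z`, `n`.
#' @export
shared_correlation <- function(prefA, prefB, shared) {
  shared <- as.integer(shared)
  if (length(shared) < 3L) {
    stop("need at least 3 shared vertices", call. = FALSE)
  }
  a <- prefA[shared]
  b <- prefB[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a map over the shared vertices: correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(a, b)
  r <- unname(ct$estimate)
  tibble::tibble(r = r, p = ct$p.value, z = atanh(r), n = length(shared))
}

#' Test-retest split of runs
#'
#' Splits runs into odd- and even-indexed halves (1-based), fits the pRF
#' model independently on each half-average, and correlates the preferred
#' numerosities of the two half-fits over the reference map: the vertices
#' whose full-average fit exceeds the variance-explained threshold.
#'
#' @param runs List of voxels x frames matrices (at least 2).
#' @inheritParams crossval_exclude
#' @param threshold Variance-explained threshold defining the reference
#'   map (study value 0.30).
#' @return A list with `fits_odd`, `fits_even`, `fits_full`, the reference
#'   `mask`, and the test-retest correlation tibble `cor` (`r`, `p`, `z`,
#'   `n`).
#' @export
testretest_split <- function(runs, timeline, hrf = hrf_params(),
                             grid = prf_grid(), dt = 0.1, threshold = 0.3,
                             refine = TRUE) {
  if (!is.list(runs) || length(runs) < 2L) {
    stop("test-retest needs at least 2 runs", call. = FALSE)
  }
  runs <- lapply(runs, function(r) if (is.null(dim(r))) matrix(r, 1L) else r)
  odd <- runs[seq_along(runs) %% 2L == 1L]
  even <- runs[seq_along(runs) %% 2L == 0L]
  Y_odd <- Reduce(`+`, odd) / length(odd)
  Y_even <- Reduce(`+`, even) / length(even)
  Y_full <- Reduce(`+`, runs) / length(runs)
  fit_odd <- fit_prf(Y_odd, timeline, hrf, grid, dt, refine)
  fit_even <- fit_prf(Y_even, timeline, hrf, grid, dt, refine)
  fit_full <- fit_prf(Y_full, timeline, hrf, grid, dt, refine)
  mask <- which(!fit_full$degenerate & fit_full$r2 > threshold)
  cor_tab <- shared_correlation(fit_odd$pref, fit_even$pref, mask)
  list(fits_odd = fit_odd, fits_even = fit_even, fits_full = fit_full,
       mask = mask, cor = cor_tab)
}

#' Compare groups of correlation coefficients
#'
#' Fisher z-transforms each correlation coefficient, runs a one-way ANOVA
#' across groups, all-pairs post hoc t-tests with Bonferroni multiplication
#' (raw p times the number of pairs, capped at 1), and a per-group
#' one-sample t-test of the z-values against 0. Coefficients with
#' `|r| = 1` have infinite z and are excluded with a warning.
#'
#' @param groups Named list of numeric vectors of correlation coefficients
#'   (at least 2 groups of at least 2 values each).
#' @return A list with `anova` (one-row tibble: `f`, `df1`, `df2`, `p`),
#'   `pairwise` (tibble: `group1`, `group2`, `p_raw`, `p_adj`) and
#'   `groups` (tibble: `group`, `n`, `mean_z`, `t`, `df`, `p`).
#' @export
compare_correlation_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- purrr::map(groups, function(r) {
    bad <- abs(r) >= 1
    if (any(bad)) {
      warning("dropping ", sum(bad), " coefficient(s) with |r| = 1 (infinite z)")
    }
    r[!bad]
  })
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  df <- purrr::imap_dfr(groups, function(r, nm)
    tibble::tibble(group = nm, z = atanh(r)))
  df$group <- factor(df$group, levels = names(groups))
  fit <- stats::aov(z ~ group, data = df)
  an <- summary(fit)[[1]]
  anova_tab <- tibble::tibble(f = an$`F value`[1], df1 = an$Df[1],
                              df2 = an$Df[2], p = an$`Pr(>F)`[1])
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    p_raw <- stats::t.test(df$z[df$group == pr[1]],
                           df$z[df$group == pr[2]])$p.value
    tibble::tibble(group1 = pr[1], group2 = pr[2], p_raw = p_raw)
  })
  pairwise$p_adj <- pmin(pairwise$p_raw * length(pairs), 1)
  per_group <- purrr::imap_dfr(groups, function(r, nm) {
    z <- atanh(r)
    tt <- stats::t.test(z, mu = 0)
    tibble::tibble(group = nm, n = length(z), mean_z = mean(z),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  list(anova = anova_tab, pairwise = pairwise, groups = per_group)
}

#' Arcsine transform of a proportion
#'
#' Variance-stabilising transform `asin(sqrt(p))` applied to overlap
#' percentages (as fractions) before group statistics.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Transformed value(s) in `[0, pi/2]`.
#' @examples
#' arcsin_proportion(c(0, 0.5, 1))  # 0, pi/4, pi/2
#' @export
arcsin_proportion <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}
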