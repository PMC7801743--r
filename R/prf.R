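#' Log-Gaussian numerosity tuning function
#'
#' The pRF model of numerosity selectivity: a Gaussian over the natural
#' logarithm of numerosity, `exp(-(ln n - ln pref)^2 / (2 sigma_log^2))`.
#' It equals 1 at the preferred numerosity and `exp(-1/2)` one log-STD
#' away; the half-maximum points sit at `ln pref +/- sigma_log * sqrt(2 ln 2)`,
#' whose back-transformed difference is the linear-space FWHM.
#'
#' @param n Numerosity (positive; vectorised).
#' @param pref Preferred numerosity (positive).
#' @param sigma_log Tuning width, STD of the Gaussian in log-numerosity
#'   units (positive).
#' @return Response values in `(0, 1]`.
#' @examples
#' tuning_response(3, pref = 3, sigma_log = 0.4)  # 1
#' tuning_response(3 * exp(0.4), 3, 0.4)          # exp(-1/2)
#' @export
tuning_response <- function(n, pref, sigma_log) {
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("`n` must be positive", call. = FALSE)
  }
  if (!is.finite(pref) || pref <= 0 || !is.finite(sigma_log) ||
      sigma_log <= 0) {
    stop("`pref` and `sigma_log` must be positive", call. = FALSE)
  }
  exp(-(log(n) - log(pref))^2 / (2 * sigma_log^2))
}

#' Linear-space full width at half maximum of a log-Gaussian tuning curve
#'
#' @param pref Preferred numerosity.
#' @param sigma_log Log-space tuning width.
#' @return FWHM in numerosity units:
#'   `exp(ln pref + c sigma) - exp(ln pref - c sigma)` with `c = sqrt(2 ln 2)`.
#' @export
fwhm_linear <- function(pref, sigma_log) {
  cc <- sqrt(2 * log(2))
  exp(log(pref) + cc * sigma_log) - exp(log(pref) - cc * sigma_log)
}

# Convolved regressor basis for a timeline: one column per unique presented
# numerosity plus their sum as the "presence" regressor. Any candidate pRF
# prediction is then B %*% tuning_response(unique numerosities), which makes
# grid search a single matrix product.
prf_basis <- function(timeline, hrf = hrf_params(), dt = 0.1) {
  design <- design_vector(timeline, dt)
  kernel <- two_gamma_hrf(hrf, dt)
  u <- sort(unique(design$numerosity[!is.na(design$numerosity)]))
  n <- nrow(design)
  step <- round(timeline$tr / dt)
  frame_idx <- seq(1L, n, by = step)
  B <- matrix(0, nrow = length(frame_idx), ncol = length(u))
  for (j in seq_along(u)) {
    ind <- as.numeric(!is.na(design$numerosity) & design$numerosity == u[j])
    conv <- stats::convolve(ind, rev(kernel), type = "open")[seq_len(n)]
    B[, j] <- conv[frame_idx]
  }
  list(B = B, numerosities = u, frame_times = design$time[frame_idx])
}

#' Predicted BOLD time course of a candidate pRF
#'
#' Evaluates the tuning function on the stimulus trace (0 where no stimulus
#' is present), convolves with the double-gamma HRF and samples at frame
#' times. The result is on unit scale: amplitude and baseline are fitted
#' separately by least squares.
#'
#' @param timeline A [run_timeline()].
#' @param pref,sigma_log Candidate tuning parameters.
#' @param hrf An [hrf_params()] object.
#' @param dt Convolution resolution in seconds; must divide the TR and be
#'   finer than the shortest stimulus event.
#' @return Numeric vector, one value per retained frame.
#' @export
predict_bold <- function(timeline, pref, sigma_log, hrf = hrf_params(),
                         dt = 0.1) {
  if (nrow(timeline$events) > 0L && dt > min(timeline$events$duration)) {
    stop("`dt` is coarser than the shortest stimulus event", call. = FALSE)
  }
  bas <- prf_basis(timeline, hrf, dt)
  if (length(bas$numerosities) == 0L) {
    return(rep(0, nrow(bas$B)))
  }
  drop(bas$B %*% tuning_response(bas$numerosities, pref, sigma_log))
}

#' Candidate grid for the pRF search
#'
#' Log-spaced candidates spanning well beyond the presented 1-7 range, so
#' that estimates inside the range are not merely the best of a truncated
#' set and out-of-range preferences can be detected and masked.
#'
#' @param pref_range,n_pref Range and number of preferred-numerosity
#'   candidates (log-spaced).
#' @param sigma_range,n_sigma Range and number of log-width candidates
#'   (log-spaced).
#' @return A tibble with columns `pref` and `sigma_log`, one row per
#'   candidate pair.
#' @export
prf_grid <- function(pref_range = c(0.5, 40), n_pref = 60,
                     sigma_range = c(0.05, 3), n_sigma = 40) {
  stopifnot(pref_range[1] > 0, sigma_range[1] > 0,
            n_pref >= 1, n_sigma >= 1)
  prefs <- exp(seq(log(pref_range[1]), log(pref_range[2]),
                   length.out = n_pref))
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_sigma))
  tidyr::expand_grid(pref = prefs, sigma_log = sigmas)
}

# correlation of every row of Yc (row-centred) with every column of Pc
# (column-centred); returns V x C matrix, 0 where either side is constant
corr_matrix <- function(Yc, sy, Pc, sp) {
  num <- Yc %*% Pc
  den <- outer(sy, sp)
  out <- num / den
  out[!is.finite(out)] <- 0
  out
}

#' Fit the numerosity pRF model to many voxels
#'
#' Exhaustive grid search over `(pref, sigma_log)` candidates shared across
#' voxels, with amplitude and baseline per candidate fitted by ordinary
#' least squares of the series on (prediction, constant). With OLS scaling
#' the training variance explained equals the squared correlation between
#' series and prediction, so the best candidate is the one with the highest
#' positive correlation; negative-amplitude candidates are rejected (tuned
#' responses are modelled as positive-going). The winning candidate is then
#' refined by bounded quasi-Newton optimisation of the correlation in
#' `(ln pref, ln sigma_log)`.
#'
#' @param Y Numeric matrix, voxels x retained frames (a single series may be
#'   passed as a vector).
#' @param timeline A [run_timeline()].
#' @param hrf An [hrf_params()] object.
#' @param grid Candidate tibble from [prf_grid()].
#' @param dt Convolution resolution (s).
#' @param refine Run local refinement of the best grid candidate
#'   (default `TRUE`; turn off for large calibration batches where grid
#'   resolution suffices).
#' @return A tibble with one row per voxel: `voxel`, `pref`, `sigma_log`,
#'   `fwhm_lin`, `amplitude`, `baseline`, `r2`, `degenerate`.
#' @export
fit_prf <- function(Y, timeline, hrf = hrf_params(), grid = prf_grid(),
                    dt = 0.1, refine = TRUE) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  if (nrow(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  n_fr <- n_frames_retained(timeline)
  if (ncol(Y) != n_fr) {
    stop(sprintf("series length %d != retained frames %d", ncol(Y), n_fr),
         call. = FALSE)
  }
  bas <- prf_basis(timeline, hrf, dt)
  u <- bas$numerosities
  Tm <- vapply(seq_len(nrow(grid)),
               function(i) tuning_response(u, grid$pref[i],
                                           grid$sigma_log[i]),
               numeric(length(u)))
  P <- bas$B %*% Tm
  Pc <- sweep(P, 2L, colMeans(P))
  sp <- sqrt(colSums(Pc^2))
  Yc <- sweep(Y, 1L, rowMeans(Y))
  sy <- sqrt(rowSums(Yc^2))
  cors <- corr_matrix(Yc, sy, Pc, sp)
  best <- max.col(cors, ties.method = "first")

  fit_one <- function(v) {
    y <- Y[v, ]
    if (sy[v] == 0) {
      return(list(pref = NA_real_, sigma_log = NA_real_, amplitude = 0,
                  baseline = mean(y), r2 = 0, degenerate = TRUE))
    }
    b <- best[v]
    pref <- grid$pref[b]
    sig <- grid$sigma_log[b]
    r <- cors[v, b]
    if (refine) {
      obj <- function(par) {
        w <- tuning_response(u, exp(par[1]), exp(par[2]))
        p <- drop(bas$B %*% w)
        spv <- stats::sd(p)
        if (!is.finite(spv) || spv == 0) return(0)
        -stats::cor(y, p)
      }
      opt <- stats::optim(c(log(pref), log(sig)), obj, method = "L-BFGS-B",
                          lower = c(log(0.1), log(0.01)),
                          upper = c(log(80), log(6)),
                          control = list(factr = 1e4, pgtol = 1e-10))
      if (is.finite(opt$value) && -opt$value >= r) {
        pref <- exp(opt$par[1])
        sig <- exp(opt$par[2])
        r <- -opt$value
      }
    }
    if (r <= 0) {
      # no positive-amplitude candidate captures this series
      return(list(pref = pref, sigma_log = sig, amplitude = 0,
                  baseline = mean(y), r2 = 0, degenerate = TRUE))
    }
    p <- drop(bas$B %*% tuning_response(u, pref, sig))
    amp <- stats::cov(y, p) / stats::var(p)
    base <- mean(y) - amp * mean(p)
    list(pref = pref, sigma_log = sig, amplitude = amp, baseline = base,
         r2 = r^2, degenerate = FALSE)
  }

  res <- purrr::map(seq_len(nrow(Y)), fit_one)
  out <- tibble::tibble(
    voxel = seq_len(nrow(Y)),
    pref = purrr::map_dbl(res, "pref"),
    sigma_log = purrr::map_dbl(res, "sigma_log"),
    amplitude = purrr::map_dbl(res, "amplitude"),
    baseline = purrr::map_dbl(res, "baseline"),
    r2 = purrr::map_dbl(res, "r2"),
    degenerate = purrr::map_lgl(res, "degenerate")
  )
  out$fwhm_lin <- ifelse(is.na(out$pref), NA_real_,
                         fwhm_linear(out$pref, out$sigma_log))
  out[, c("voxel", "pref", "sigma_log", "fwhm_lin", "amplitude",
          "baseline", "r2", "degenerate")]
}

#' Re-estimate participant-level HRF parameters from fitted voxels
#'
#' Holding each voxel's tuning parameters fixed, optimises the shared HRF
#' peak delay and undershoot ratio to maximise the summed variance
#' explained over well-fitting voxels (initial `r2 > r2_min`), then refits
#' all pRFs with the new HRF (one outer iteration).
#'
#' @param Y Voxels x frames matrix of the series used for the initial fits.
#' @param fits Initial fit table from [fit_prf()].
#' @param timeline A [run_timeline()].
#' @param hrf Starting [hrf_params()] (canonical by default).
#' @param r2_min Minimum initial variance explained for a voxel to inform
#'   the HRF fit (default 0.3).
#' @param dt Convolution resolution (s).
#' @param refine Passed to the final [fit_prf()] refit.
#' @return A list with elements `hrf` (the re-estimated [hrf_params()]) and
#'   `fits` (the refit table). If no voxel exceeds `r2_min` the canonical
#'   HRF is returned unchanged with a warning.
#' @export
estimate_subject_hrf <- function(Y, fits, timeline, hrf = hrf_params(),
                                 r2_min = 0.3, dt = 0.1, refine = TRUE) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  keep <- which(!fits$degenerate & fits$r2 > r2_min)
  if (length(keep) == 0L) {
    warning("no voxel above r2_min; returning the canonical HRF unchanged")
    return(list(hrf = hrf, fits = fits))
  }
  Yk <- Y[keep, , drop = FALSE]
  prefs <- fits$pref[keep]
  sigs <- fits$sigma_log[keep]
  Ykc <- sweep(Yk, 1L, rowMeans(Yk))
  syk <- sqrt(rowSums(Ykc^2))
  obj <- function(par) {
    h <- hrf_params(peak_delay = par[1],
                    undershoot_delay = hrf$undershoot_delay,
                    peak_dispersion = hrf$peak_dispersion,
                    undershoot_dispersion = hrf$undershoot_dispersion,
                    undershoot_ratio = par[2])
    bas <- prf_basis(timeline, h, dt)
    u <- bas$numerosities
    P <- vapply(seq_along(keep),
                function(i) drop(bas$B %*% tuning_response(u, prefs[i],
                                                           sigs[i])),
                numeric(nrow(bas$B)))
    Pc <- sweep(P, 2L, colMeans(P))
    sp <- sqrt(colSums(Pc^2))
    r <- rowSums(Ykc * t(Pc)) / (syk * sp)
    r[!is.finite(r)] <- 0
    -sum(r^2)
  }
  opt <- stats::optim(c(hrf$peak_delay, hrf$undershoot_ratio), obj,
                      method = "L-BFGS-B",
                      lower = c(2, 0), upper = c(12, 0.9),
                      control = list(factr = 1e7))
  new_hrf <- hrf_params(peak_delay = opt$par[1],
                        undershoot_delay = hrf$undershoot_delay,
                        peak_dispersion = hrf$peak_dispersion,
                        undershoot_dispersion = hrf$undershoot_dispersion,
                        undershoot_ratio = opt$par[2])
  list(hrf = new_hrf,
       fits = fit_prf(Y, timeline, new_hrf, dt = dt, refine = refine))
}

#' Mask fits by presented numerosity range
#'
#' Recording sites whose preferred numerosity falls outside the presented
#' range are excluded from map analyses. The interval is closed at both
#' ends (study values 1 and 7).
#'
#' @param fits Fit table from [fit_prf()].
#' @param low,high Range bounds in numerosity units.
#' @return Logical vector, `TRUE` where `low <= pref <= high`.
#' @export
range_mask <- function(fits, low = 1, high = 7) {
  stopifnot(low < high)
  !is.na(fits$pref) & fits$pref >= low & fits$pref <= high
}

#' Plot fitted numerosity tuning curves
#'
#' @param fits Fit table from [fit_prf()] (one curve per row).
#' @param n_grid Resolution of the numerosity axis.
#' @return A ggplot object: response against numerosity on a log axis.
#' @export
plot_tuning <- function(fits, n_grid = 200) {
  fits <- fits[!fits$degenerate & !is.na(fits$pref), , drop = FALSE]
  curves <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    n <- exp(seq(log(0.5), log(20), length.out = n_grid))
    tibble::tibble(voxel = fits$voxel[i], numerosity = n,
                   response = tuning_response(n, fits$pref[i],
                                              fits$sigma_log[i]))
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$numerosity, y = .data$response,
                               group = .data$voxel,
                               colour = factor(.data$voxel))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Numerosity", y = "Normalised response",
                  colour = "Voxel") +
    ggplot2::theme_minimal()
}

#' Write and read pRF fit tables
#'
#' @param fits Fit table from [fit_prf()].
#' @param path File path (tab-separated, header row).
#' @return `write_fits()` returns `path` invisibly; `read_fits()` the tibble.
#' @export
write_fits <- function(fits, path) {
  readr::write_tsv(fits, path)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
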