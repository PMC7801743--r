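#' Ground-truth table for synthetic voxels
#'
#' Draws per-voxel ground-truth parameters for the three voxel classes used
#' throughout calibration: `tuned` voxels following the log-Gaussian pRF
#' model, `on_off` voxels responding to stimulus presence irrespective of
#' numerosity, and `null` voxels carrying noise only.
#'
#' @param n_tuned,n_onoff,n_null Number of voxels of each class.
#' @param pref_range Preferred numerosities are drawn log-uniformly over
#'   this range.
#' @param sigma_range Log tuning widths are drawn uniformly over this range.
#' @param amplitude,baseline Response amplitude and baseline (signal units).
#' @param seed RNG seed.
#' @return A tibble with columns `voxel`, `class`, `pref`, `sigma_log`,
#'   `amplitude`, `baseline`.
#' @export
simulate_truth <- function(n_tuned = 0, n_onoff = 0, n_null = 0,
                           pref_range = c(1, 7), sigma_range = c(0.3, 0.8),
                           amplitude = 1, baseline = 0, seed = 1) {
  n <- n_tuned + n_onoff + n_null
  stopifnot(n >= 1)
  with_seed(seed, {
    cls <- rep(c("tuned", "on_off", "null"), c(n_tuned, n_onoff, n_null))
    pref <- rep(NA_real_, n)
    sig <- rep(NA_real_, n)
    tuned <- cls == "tuned"
    pref[tuned] <- exp(stats::runif(sum(tuned), log(pref_range[1]),
                                    log(pref_range[2])))
    sig[tuned] <- stats::runif(sum(tuned), sigma_range[1], sigma_range[2])
    tibble::tibble(voxel = seq_len(n), class = cls, pref = pref,
                   sigma_log = sig, amplitude = amplitude,
                   baseline = baseline)
  })
}

# noiseless predictions for a ground-truth table, voxels x frames
truth_predictions <- function(timeline, truth, hrf, dt = 0.1) {
  bas <- prf_basis(timeline, hrf, dt)
  u <- bas$numerosities
  n_fr <- nrow(bas$B)
  presence <- drop(bas$B %*% rep(1, length(u)))
  P <- matrix(0, nrow = nrow(truth), ncol = n_fr)
  for (i in seq_len(nrow(truth))) {
    shape <- switch(truth$class[i],
      tuned = drop(bas$B %*% tuning_response(u, truth$pref[i],
                                             truth$sigma_log[i])),
      on_off = presence,
      null = rep(0, n_fr),
      stop("unknown voxel class: ", truth$class[i], call. = FALSE))
    P[i, ] <- truth$baseline[i] + truth$amplitude[i] * shape
  }
  P
}

#' Simulate voxel time series from ground truth
#'
#' Forward model: each voxel's tuning response to the stimulus trace is
#' convolved with the HRF, sampled at frame times, scaled by amplitude over
#' baseline, and corrupted with (optionally AR(1)-correlated) Gaussian
#' noise. `on_off` voxels use a constant-amplitude presence trace instead of
#' a tuning curve; `null` voxels are baseline plus noise.
#'
#' The default `noise_sd = "matched"` sets each voxel's noise STD equal to
#' the STD of its own noiseless signal, so the noiseless model explains
#' about half of the variance (R^2 ~ 0.5) — the regime the analysis is
#' calibrated for. Null voxels use the mean signal STD of the responsive
#' voxels.
#'
#' @param timeline A [run_timeline()].
#' @param truth Ground-truth tibble from [simulate_truth()].
#' @param hrf An [hrf_params()] object.
#' @param noise_sd `"matched"`, or a non-negative number (signal units).
#' @param ar1_rho AR(1) coefficient of the noise, `|rho| < 1`.
#' @param seed RNG seed; identical seed gives identical output.
#' @param dt Convolution resolution (s).
#' @return Numeric matrix, voxels x retained frames.
#' @export
simulate_voxels <- function(timeline, truth, hrf = hrf_params(),
                            noise_sd = "matched", ar1_rho = 0, seed = 1,
                            dt = 0.1) {
  stopifnot(abs(ar1_rho) < 1)
  P <- truth_predictions(timeline, truth, hrf, dt)
  sig_sd <- apply(P, 1L, stats::sd)
  if (identical(noise_sd, "matched")) {
    pos <- sig_sd[sig_sd > 0]
    fill <- if (length(pos)) mean(pos) else 1
    nsd <- ifelse(sig_sd > 0, sig_sd, fill)
  } else {
    stopifnot(is.numeric(noise_sd), all(noise_sd >= 0))
    nsd <- rep_len(noise_sd, nrow(P))
  }
  with_seed(seed, {
    W <- matrix(stats::rnorm(length(P)), nrow = nrow(P))
    if (ar1_rho != 0) {
      W <- t(apply(W * sqrt(1 - ar1_rho^2), 1L, function(w)
        as.numeric(stats::filter(w, ar1_rho, method = "recursive"))))
    }
    P + W * nsd
  })
}

#' Simulate a single voxel time series
#'
#' Convenience wrapper around [simulate_voxels()] for one voxel.
#'
#' @inheritParams simulate_voxels
#' @param pref,sigma_log Tuning parameters (ignored for non-tuned classes).
#' @param amplitude,baseline Signal scaling.
#' @param class Voxel class: `"tuned"`, `"on_off"` or `"null"`.
#' @return Numeric vector, one value per retained frame.
#' @export
simulate_voxel <- function(timeline, pref = 3, sigma_log = 0.4,
                           amplitude = 1, baseline = 0,
                           class = c("tuned", "on_off", "null"),
                           hrf = hrf_params(), noise_sd = "matched",
                           ar1_rho = 0, seed = 1, dt = 0.1) {
  class <- match.arg(class)
  truth <- tibble::tibble(voxel = 1L, class = class, pref = pref,
                          sigma_log = sigma_log, amplitude = amplitude,
                          baseline = baseline)
  drop(simulate_voxels(timeline, truth, hrf, noise_sd, ar1_rho, seed, dt))
}

#' Simulate a topographic surface patch with known gradient
#'
#' Builds a regular triangulated grid strip whose preferred numerosity is
#' log-spaced along the column axis between the two ends of `pref_range`,
#' emulating the systematic low-to-high progression of a topographic map.
#' Tuning width grows with preference as
#' `sigma_log = sigma_base + width_slope * ln(pref)`. The first column is
#' the low-preference border, the last column the high-preference border.
#'
#' @param n_rows,n_cols Grid dimensions (both at least 2).
#' @param spacing Vertex spacing in mm.
#' @param pref_range Preference at the low and high borders
#'   (`0 < low < high`).
#' @param sigma_base Intercept of the width-vs-log-preference relation.
#' @param width_slope Slope of the width relation (0 gives constant width).
#' @param amplitude,baseline Signal scaling for downstream simulation.
#' @param pref_jitter_sd Log-normal jitter STD applied per vertex (0 gives
#'   the exact column-wise gradient).
#' @param seed RNG seed (used only when `pref_jitter_sd > 0`).
#' @return A list with elements `patch` ([surface_patch()]), `roi`
#'   ([roi_map()]) and `truth` (per-vertex ground-truth tibble).
#' @export
simulate_patch <- function(n_rows = 6, n_cols = 15, spacing = 2,
                           pref_range = c(1, 7), sigma_base = 0.3,
                           width_slope = 0.3, amplitude = 1, baseline = 0,
                           pref_jitter_sd = 0, seed = 1) {
  if (n_rows < 2 || n_cols < 2) {
    stop("`n_rows` and `n_cols` must be at least 2", call. = FALSE)
  }
  if (pref_range[1] <= 0 || pref_range[1] >= pref_range[2]) {
    stop("`pref_range` must satisfy 0 < low < high", call. = FALSE)
  }
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  vx <- cbind(x = (grid$col - 1) * spacing, y = (grid$row - 1) * spacing,
              z = 0)
  vid <- function(r, c) (r - 1L) * n_cols + c
  faces <- do.call(rbind, lapply(seq_len(n_rows - 1L), function(r) {
    do.call(rbind, lapply(seq_len(n_cols - 1L), function(c) {
      v00 <- vid(r, c); v01 <- vid(r, c + 1L)
      v10 <- vid(r + 1L, c); v11 <- vid(r + 1L, c + 1L)
      rbind(c(v00, v01, v11), c(v00, v11, v10))
    }))
  }))
  patch <- surface_patch(vx, faces)
  col_pref <- exp(seq(log(pref_range[1]), log(pref_range[2]),
                      length.out = n_cols))
  pref <- col_pref[grid$col]
  if (pref_jitter_sd > 0) {
    pref <- with_seed(seed,
      pref * exp(stats::rnorm(length(pref), 0, pref_jitter_sd)))
  }
  sigma <- sigma_base + width_slope * log(pref)
  truth <- tibble::tibble(voxel = seq_len(nrow(vx)), class = "tuned",
                          pref = pref, sigma_log = sigma,
                          amplitude = amplitude, baseline = baseline)
  roi <- roi_map(members = seq_len(nrow(vx)),
                 low_border = vid(seq_len(n_rows), 1L),
                 high_border = vid(seq_len(n_rows), n_cols))
  list(patch = patch, roi = roi, truth = truth)
}

resolve_profile <- function(motion_profile) {
  if (is.function(motion_profile)) return(motion_profile)
  if (is.numeric(motion_profile) && length(motion_profile) == 1L) {
    lam <- motion_profile
    return(function(n) rep_len(lam, length(n)))
  }
  if (is.numeric(motion_profile) && !is.null(names(motion_profile))) {
    return(function(n) unname(motion_profile[as.character(n)]))
  }
  stop("`motion_profile` must be a scalar, named vector or function",
       call. = FALSE)
}

#' Simulate data-glove finger-motion traces
#'
#' Emulates a 5-sensor flexure glove sampled at about 52 Hz during the
#' haptic protocol: within each 3 s exploration epoch, each finger performs
#' a Poisson-distributed number of discrete movements (smooth bumps spread
#' over the epoch), and is quiescent between epochs. Under a constant
#' `motion_profile`, expected epoch metrics are independent of numerosity —
#' the null the motion control analysis is calibrated against.
#'
#' @param timeline A haptic [run_timeline()].
#' @param rate Sampling rate in Hz (study hardware ~52 Hz).
#' @param motion_profile Mean movement count per epoch: a scalar, a named
#'   vector indexed by numerosity, or `function(numerosity)`.
#' @param n_fingers Number of sensor channels.
#' @param bump_sd Temporal width (Gaussian STD, s) of one movement bump.
#' @param sensor_noise_sd STD of additive sensor noise (sensor units; 0 for
#'   noiseless traces).
#' @param seed RNG seed.
#' @return A tibble with a `time` column (s) and one column per sensor
#'   (`finger_1`, ...).
#' @export
simulate_glove <- function(timeline, rate = 52, motion_profile = 3,
                           n_fingers = 5, bump_sd = 0.12,
                           sensor_noise_sd = 0.005, seed = 1) {
  stopifnot(inherits(timeline, "run_timeline"), rate > 0)
  prof <- resolve_profile(motion_profile)
  dur <- n_frames_retained(timeline) * timeline$tr
  time <- seq(0, dur - 1 / rate, by = 1 / rate)
  ev <- timeline$events
  with_seed(seed, {
    traces <- matrix(0, nrow = length(time), ncol = n_fingers)
    for (f in seq_len(n_fingers)) {
      for (i in seq_len(nrow(ev))) {
        lam <- prof(ev$numerosity[i])
        k <- stats::rpois(1L, lam)
        if (k == 0L) next
        # one movement per equal slot of the epoch, jittered, so that
        # individual movements stay separable
        slot <- ev$duration[i] / k
        centers <- ev$onset[i] + (seq_len(k) - 0.5) * slot +
          stats::runif(k, -0.15, 0.15) * slot
        amps <- stats::runif(k, 0.5, 1)
        for (j in seq_len(k)) {
          lo <- max(1L, ceiling((centers[j] - 4 * bump_sd) * rate))
          hi <- min(length(time), floor((centers[j] + 4 * bump_sd) * rate))
          idx <- lo:hi
          traces[idx, f] <- traces[idx, f] +
            amps[j] * exp(-(time[idx] - centers[j])^2 / (2 * bump_sd^2))
        }
      }
    }
    if (sensor_noise_sd > 0) {
      traces <- traces + stats::rnorm(length(traces), 0, sensor_noise_sd)
    }
    out <- tibble::as_tibble(as.data.frame(traces))
    names(out) <- paste0("finger_", seq_len(n_fingers))
    dplyr::bind_cols(tibble::tibble(time = time), out)
  })
}

#' Simulate behavioural numerosity judgments
#'
#' Emulates the structure of numerosity judgment behaviour: error-free and
#' fast responses within the subitizing range, with error probability
#' rising linearly and reaction time rising with numerosity beyond it.
#' Reaction-time noise is log-normal.
#'
#' @param n_participants Number of participants.
#' @param n_trials_per_numerosity Trials per numerosity per participant.
#' @param numerosities Presented numerosities.
#' @param subitizing_limit Largest numerosity judged without error.
#' @param error_slope Increase in error probability per unit numerosity
#'   above the subitizing limit.
#' @param rt_base,rt_slope Median reaction time at numerosity 1 (s) and its
#'   increase per unit numerosity.
#' @param rt_sdlog Log-normal STD of reaction-time noise.
#' @param modality,condition Labels copied into the table.
#' @param seed RNG seed.
#' @return A tibble with columns `participant`, `modality`, `condition`,
#'   `numerosity`, `response`, `correct`, `rt_s`.
#' @export
simulate_behavior <- function(n_participants = 5,
                              n_trials_per_numerosity = 20,
                              numerosities = 1:7, subitizing_limit = 3,
                              error_slope = 0.15, rt_base = 0.8,
                              rt_slope = 0.15, rt_sdlog = 0.25,
                              modality = "haptic", condition = "equal_size",
                              seed = 1) {
  stopifnot(n_trials_per_numerosity >= 1, n_participants >= 1)
  with_seed(seed, {
    tab <- tidyr::expand_grid(
      participant = seq_len(n_participants),
      numerosity = as.integer(numerosities),
      trial = seq_len(n_trials_per_numerosity))
    p_err <- pmin(pmax(error_slope * (tab$numerosity - subitizing_limit), 0),
                  0.95)
    err <- stats::runif(nrow(tab)) < p_err
    resp <- tab$numerosity
    off <- sample(c(-1L, 1L), nrow(tab), replace = TRUE)
    resp[err] <- pmax(1L, tab$numerosity[err] + off[err])
    resp[err & resp == tab$numerosity] <- tab$numerosity[err & resp ==
                                                           tab$numerosity] + 1L
    rt <- (rt_base + rt_slope * (tab$numerosity - 1)) *
      stats::rlnorm(nrow(tab), -rt_sdlog^2 / 2, rt_sdlog)
    tibble::tibble(participant = tab$participant, modality = modality,
                   condition = condition, numerosity = tab$numerosity,
                   response = as.integer(resp), correct = !err, rt_s = rt)
  })
}

#' Write a voxel matrix with its ground truth
#'
#' Voxel-by-frame matrices are written as tab-separated text (one row per
#' voxel) with the ground-truth table as a JSON sidecar.
#'
#' @param Y Voxels x frames matrix.
#' @param truth Ground-truth tibble.
#' @param path Path of the matrix file; the sidecar gets extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_voxels <- function(Y, truth, path) {
  utils::write.table(Y, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       ".json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
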