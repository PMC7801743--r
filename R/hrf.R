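#' Haemodynamic response function parameters
#'
#' Parameter set for the canonical double-gamma HRF: the difference of two
#' gamma densities, a positive response peak and a delayed undershoot. The
#' defaults (peak at ~5 s, undershoot around 15 s, undershoot one sixth of
#' the peak) are the field-standard canonical values; per-participant
#' refitting adjusts `peak_delay` and `undershoot_ratio`
#' (see [estimate_subject_hrf()]).
#'
#' @param peak_delay Gamma shape parameter of the peak (s, with unit
#'   dispersion the density peaks at `peak_delay - 1`).
#' @param undershoot_delay Shape parameter of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Gamma scale parameters (s).
#' @param undershoot_ratio Relative weight of the undershoot, in `[0, 1)`.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("HRF delays and dispersions must be positive", call. = FALSE)
  }
  if (!is.finite(undershoot_ratio) || undershoot_ratio < 0 ||
      undershoot_ratio >= 1) {
    stop("`undershoot_ratio` must be in [0, 1)", call. = FALSE)
  }
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "<hrf_params> peak %g s (disp %g), undershoot %g s (disp %g), ratio %.3f\n",
    x$peak_delay, x$undershoot_delay, x$peak_dispersion,
    x$undershoot_dispersion, x$undershoot_ratio))
  invisible(x)
}

#' Sample a double-gamma HRF kernel
#'
#' Evaluates the difference-of-gamma-densities impulse response over 32 s at
#' step `dt` and scales it to unit peak, so that response amplitude is
#' carried entirely by the pRF amplitude parameter.
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling step in seconds.
#' @param duration Kernel support in seconds (default 32).
#' @return Numeric vector of kernel weights starting at t = 0.
#' @examples
#' k <- two_gamma_hrf(hrf_params(), dt = 0.1)
#' (which.max(k) - 1) * 0.1  # peak close to 5 s
#' @export
two_gamma_hrf <- function(params = hrf_params(), dt = 0.1, duration = 32) {
  stopifnot(inherits(params, "hrf_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = params$undershoot_delay /
                      params$undershoot_dispersion,
                    scale = params$undershoot_dispersion)
  h / max(h)
}
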