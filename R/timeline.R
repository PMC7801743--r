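#' Construct a run timeline
#'
#' A `run_timeline` bundles an ordered stimulus event table with the scan
#' parameters needed to interpret it: repetition time, total frame count and
#' the number of initial frames discarded to reach steady-state
#' magnetisation. Time zero is the first *retained* frame; discarded frames
#' are represented only by their count.
#'
#' @param events A data frame with columns `onset` (s), `duration` (s),
#'   `numerosity` (positive integer) and `condition` (character). Events must
#'   be non-overlapping and sorted by onset.
#' @param tr Repetition time in seconds.
#' @param n_frames_total Total number of frames acquired, including
#'   discarded ones.
#' @param n_frames_discarded Number of initial frames discarded.
#' @param modality `"haptic"` or `"visual"`.
#' @return An object of class `run_timeline`.
#' @seealso [build_haptic_run()], [build_visual_run()], [design_vector()]
#' @export
run_timeline <- function(events, tr, n_frames_total, n_frames_discarded,
                         modality = c("haptic", "visual")) {
  modality <- match.arg(modality)
  stopifnot(is.data.frame(events))
  events <- tibble::as_tibble(events)
  req <- c("onset", "duration", "numerosity", "condition")
  if (!all(req %in% names(events))) {
    stop("`events` must have columns onset, duration, numerosity, condition",
         call. = FALSE)
  }
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop("`tr` must be a single positive number", call. = FALSE)
  }
  if (n_frames_discarded >= n_frames_total) {
    stop("`n_frames_discarded` must be smaller than `n_frames_total`",
         call. = FALSE)
  }
  if (nrow(events) > 0L) {
    stopifnot(all(events$onset >= 0), all(events$duration > 0))
    if (is.unsorted(events$onset, strictly = FALSE)) {
      stop("events must be sorted by onset", call. = FALSE)
    }
    offs <- events$onset + events$duration
    if (nrow(events) > 1L &&
        any(events$onset[-1L] < offs[-nrow(events)] - 1e-9)) {
      stop("events must be non-overlapping", call. = FALSE)
    }
    if ((n_frames_total - n_frames_discarded) * tr < max(offs) - 1e-9) {
      stop("retained frames do not span the last event offset", call. = FALSE)
    }
  }
  structure(
    list(events = events, tr = tr,
         n_frames_total = as.integer(n_frames_total),
         n_frames_discarded = as.integer(n_frames_discarded),
         modality = modality),
    class = "run_timeline"
  )
}

#' @export
print.run_timeline <- function(x, ...) {
  cat(sprintf(
    "<run_timeline> %s: %d events, TR %g s, %d frames (%d discarded), %g s total\n",
    x$modality, nrow(x$events), x$tr, x$n_frames_total,
    x$n_frames_discarded, x$n_frames_total * x$tr))
  print(x$events, n = 5)
  invisible(x)
}

#' Number of retained frames of a run timeline
#' @param timeline A [run_timeline()].
#' @return Integer frame count after discarding initial frames.
#' @export
n_frames_retained <- function(timeline) {
  timeline$n_frames_total - timeline$n_frames_discarded
}

#' @rdname tidy.run_timeline
#' @export
tidy.run_timeline <- function(x, ...) x$events

#' Tidy a run timeline into its event table
#'
#' @param x A [run_timeline()].
#' @param ... Unused.
#' @return The event tibble (onset, duration, numerosity, condition).
#' @name tidy.run_timeline
NULL

# one exploration event per presentation: `period` s slot, `stim_dur` s of
# stimulus at its start, remainder is inter-stimulus absence
presentation_block <- function(numerosities, t0, period, stim_dur, condition) {
  tibble::tibble(
    onset = t0 + period * (seq_along(numerosities) - 1L),
    duration = stim_dur,
    numerosity = as.integer(numerosities),
    condition = condition
  )
}

#' Build the haptic numerosity run protocol
#'
#' One functional run presents sets of 1-7 spheres plus a 20-sphere
#' baseline: numerosities 1-7 in ascending order, three presentations of 20,
#' 7-1 descending, three more of 20, the whole pattern repeated twice. Each
#' presentation is a 3 s exploration period followed by a 4.5 s
#' inter-stimulus interval (7.5 s slot). Eight initial frames are discarded.
#' At the study TR of 1.5 s this yields 208 frames and 312 s in total, with
#' each numerosity 1-7 presented 4 times and the baseline 12 times.
#'
#' @param tr Repetition time in seconds (study value 1.5).
#' @param condition Condition label for the event table; one of
#'   `"haptic_equal_size"` or `"haptic_equal_volume"`. Numerosity timing is
#'   identical in the two sphere conditions.
#' @return A [run_timeline()].
#' @examples
#' run <- build_haptic_run()
#' run$n_frames_total      # 208
#' run$n_frames_total * run$tr  # 312 s
#' @export
build_haptic_run <- function(tr = 1.5,
                             condition = c("haptic_equal_size",
                                           "haptic_equal_volume")) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("`tr` must be a single positive number", call. = FALSE)
  }
  condition <- match.arg(condition)
  period <- 7.5
  stim_dur <- 3
  pattern <- c(1:7, rep(20L, 3), 7:1, rep(20L, 3))
  seqn <- rep(pattern, 2)
  events <- presentation_block(seqn, 0, period, stim_dur, condition)
  n_discard <- 8L
  total_s <- n_discard * tr + length(seqn) * period
  n_total <- as.integer(round(total_s / tr))
  run_timeline(events, tr, n_total, n_discard, "haptic")
}

#' Build the visual numerosity run protocol
#'
#' Random dot patterns are flashed for 300 ms with 350 ms of grey background
#' in between (650 ms rhythm). Each numerosity step shows 6 patterns over
#' 3.9 s; a cycle is 7 ascending steps (1-7), a 15.6 s baseline block of 20
#' dots, 7 descending steps and a second 15.6 s baseline block, repeated 4
#' times per run. Six initial frames are discarded. At the study TR of
#' 1.95 s this yields 182 frames and 354.9 s. The baseline blocks are
#' modelled as 24 flashed presentations at the same 650 ms rhythm.
#'
#' @param tr Repetition time in seconds (study value 1.95).
#' @return A [run_timeline()].
#' @examples
#' run <- build_visual_run()
#' run$n_frames_total           # 182
#' run$n_frames_total * run$tr  # 354.9 s
#' @export
build_visual_run <- function(tr = 1.95) {
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("`tr` must be a single positive number", call. = FALSE)
  }
  period <- 0.65
  stim_dur <- 0.3
  step <- function(n) rep(n, 6)           # 6 flashes, 3.9 s
  baseline <- rep(20L, 24)                # 24 flashes, 15.6 s
  cycle <- c(unlist(lapply(1:7, step)), baseline,
             unlist(lapply(7:1, step)), baseline)
  seqn <- rep(cycle, 4)
  events <- presentation_block(seqn, 0, period, stim_dur, "visual")
  n_discard <- 6L
  total_s <- n_discard * tr + length(seqn) * period
  n_total <- as.integer(round(total_s / tr))
  run_timeline(events, tr, n_total, n_discard, "visual")
}

#' Sphere set specification for the haptic stimuli
#'
#' The two haptic conditions control the covariates of numerosity: in the
#' equal-size condition every sphere has the same individual volume
#' (21 mm^3), so total volume grows with numerosity; in the equal-volume
#' condition the total volume is fixed at 420 mm^3, so individual sphere
#' size shrinks as numerosity grows.
#'
#' @param numerosity Integer number of spheres, 1-20.
#' @param condition `"equal_size"` or `"equal_volume"`.
#' @return A one-row tibble with columns `numerosity`, `condition`,
#'   `individual_volume` and `total_volume` (mm^3).
#' @examples
#' sphere_spec(5, "equal_size")
#' sphere_spec(1, "equal_volume")
#' @export
sphere_spec <- function(numerosity, condition = c("equal_size", "equal_volume")) {
  condition <- match.arg(condition)
  if (!is.numeric(numerosity) || length(numerosity) != 1L ||
      numerosity != round(numerosity) || numerosity < 1 || numerosity > 20) {
    stop("`numerosity` must be an integer between 1 and 20", call. = FALSE)
  }
  numerosity <- as.integer(numerosity)
  if (condition == "equal_size") {
    indiv <- 21
    total <- 21 * numerosity
  } else {
    total <- 420
    indiv <- 420 / numerosity
  }
  tibble::tibble(numerosity = numerosity, condition = condition,
                 individual_volume = indiv, total_volume = total)
}

#' Sample a timeline as a high-resolution numerosity trace
#'
#' Produces the piecewise-constant stimulus trace used as input to the
#' forward model: the presented numerosity at each time step, `NA` during
#' inter-stimulus gaps. Stimulus intervals are half-open
#' `[onset, onset + duration)`. The trace spans the retained frames only.
#'
#' @param timeline A [run_timeline()].
#' @param dt Sampling step in seconds; must divide the TR.
#' @return A tibble with columns `time` (s from first retained frame) and
#'   `numerosity` (integer or `NA` when no stimulus is present).
#' @export
design_vector <- function(timeline, dt = 0.1) {
  stopifnot(inherits(timeline, "run_timeline"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  ratio <- timeline$tr / dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`dt` must divide the TR", call. = FALSE)
  }
  n <- n_frames_retained(timeline) * round(ratio)
  time <- (seq_len(n) - 1L) * dt
  num <- rep(NA_integer_, n)
  ev <- timeline$events
  for (i in seq_len(nrow(ev))) {
    sel <- time >= ev$onset[i] - 1e-9 &
      time < ev$onset[i] + ev$duration[i] - 1e-9
    num[sel] <- ev$numerosity[i]
  }
  tibble::tibble(time = time, numerosity = num)
}

#' Read and write BIDS-style event tables
#'
#' Timelines are serialised as tab-separated tables with a header row and
#' columns `onset`, `duration`, `numerosity`, `condition`.
#'
#' @param timeline A [run_timeline()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event tibble.
#' @export
write_events <- function(timeline, path) {
  readr::write_tsv(tidy(timeline), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    onset = readr::col_double(),
                    duration = readr::col_double(),
                    numerosity = readr::col_integer(),
                    condition = readr::col_character()))
}

#' Plot a run timeline
#'
#' Shows presented numerosity against time as a step trace, one point per
#' presentation.
#'
#' @param object A [run_timeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.run_timeline <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$onset, y = .data$numerosity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$onset + .data$duration,
                                       yend = .data$numerosity),
                          linewidth = 1.2) +
    ggplot2::labs(x = "Time from first retained frame (s)",
                  y = "Numerosity",
                  title = sprintf("%s run protocol", object$modality)) +
    ggplot2::theme_minimal()
}
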