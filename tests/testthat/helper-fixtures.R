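# shared fixtures: protocol timelines are deterministic, build once
haptic <- build_haptic_run()
visual <- build_visual_run()

# a toy timeline with a single 3 s event, used by convolution oracles
toy_timeline <- function(n_frames = 28, tr = 1.5) {
  run_timeline(
    tibble::tibble(onset = 0, duration = 3, numerosity = 3L,
                   condition = "haptic_equal_size"),
    tr = tr, n_frames_total = n_frames, n_frames_discarded = 0,
    modality = "haptic")
}

# brute-force discrete convolution: y[n] = sum_j x[j] k[n - j + 1]
conv_oracle <- function(x, k) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq_len(i)
    ki <- i - js + 1L
    ok <- ki <= length(k)
    y[i] <- sum(x[js[ok]] * k[ki[ok]])
  }
  y
}
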