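#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# run code under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream of child seeds from one parent seed, staying inside the
# 32-bit integer range
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
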