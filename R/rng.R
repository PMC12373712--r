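#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one top-level integer seed.
#' Each operation draws from a named sub-stream so that, e.g., regenerating
#' the trial order of run 2 never perturbs the noise of run 1. The
#' sub-stream seed is a deterministic hash of the parent seed and a name.
#'
#' @param seed Parent integer seed.
#' @param name Character tag of the sub-stream (e.g. "design/run1").
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(42, "design") != substream_seed(42, "noise")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  # polynomial rolling hash over the name bytes, folded with the parent
  # seed; all intermediates stay below 2^53 so double arithmetic is exact
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in utf8ToInt(name)) {
    h <- (h * 31 + b) %% m
  }
  s <- as.numeric(seed) %% m
  as.integer(((s * 69069) %% m + h * 40503) %% m)
}

# Evaluate `expr` under the RNG sub-stream `name` of `seed`, restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, expr) {
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
  set.seed(substream_seed(seed, name))
  expr
}
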