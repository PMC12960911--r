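# Deterministic substream derivation: a single user-facing seed is fanned out
# into named substreams (truth sampling, clustering sampling, projections, ...)
# so that no stage shares or perturbs another stage's RNG state.

#' Derive a named substream seed from a master seed
#'
#' Hashes `(seed, name)` into a reproducible integer in `[0, 2^31 - 2]`,
#' suitable for `set.seed()`. Distinct names give (with overwhelming
#' probability) distinct streams; the same `(seed, name)` pair always gives
#' the same value.
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the substream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1L, "truth-sampling")
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(name)) {
    # 31-bit multiplicative hash kept in double-safe range
    h <- (h * 31 + code) %% m
  }
  h <- (h * 48271) %% m
  as.integer(h)
}

# Run `expr` under a given seed without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
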