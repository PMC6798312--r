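# Internal helpers shared across modules.

#' Clamp values to a range
#' @param x numeric vector
#' @param lo,hi range bounds
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit integer range R requires.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
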