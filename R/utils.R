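#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so seeded package operations never disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a per-purpose child seed from one global seed. A fixed odd
# multiplier per purpose index keeps streams distinct and reproducible
# across partial re-runs; result stays inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
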