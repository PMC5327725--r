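#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so that seeded operations inside the
#' package never perturb user-level randomness.
#'
#' @param seed integer seed (must be representable as a 32-bit integer).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  if (abs(seed) >= 2^31) stop("'seed' must fit in a 32-bit integer")
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
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and an offset, kept inside 32 bits.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable ordering of samples: numeric score descending, ties by id.
order_by_score_desc <- function(score, ids) {
  order(-score, ids, method = "radix")
}
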