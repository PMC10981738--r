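#' Evaluate an expression under a fixed RNG state
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, restoring
#' the caller's RNG state afterwards so library code never perturbs user
#' simulations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

# Derive a reproducible child seed from a base seed and a string tag,
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
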