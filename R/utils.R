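# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Used so per-subject seeds depend on subject identity, not list position.
#' Result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed
#' @param key character scalar (e.g. a subject id)
#' @return an integer in `[0, 2^31 - 2]`
#' @keywords internal
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# run expr with a locally-set RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
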