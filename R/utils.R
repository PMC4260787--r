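#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates `expr`, then restores the
#' state, so seeded internals never perturb user-level randomness.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage child seed from a master seed; keeps every derived
# seed a valid 32-bit R integer
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
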