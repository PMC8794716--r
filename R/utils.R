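# Internal helpers: seeded evaluation and seed derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded operations do not perturb unrelated
#' randomness in the session. A `NULL` seed evaluates `expr` as-is.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation (Lehmer-style mix, kept < 2^31 so the
# result is a valid 32-bit integer seed). Any single (size, replicate) cell of
# an experiment can be reproduced in isolation from the master seed and its
# counter, independent of scheduling order.
derive_seed <- function(master_seed, counter) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(master_seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + 1 + as.numeric(counter) * 2246822519) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
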