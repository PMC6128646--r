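## Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed))
    return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop("'", name, "' out of range [",
         if (strict_lower) paste0(lower, " (exclusive)") else lower,
         ", ", upper, "]")
  invisible(x)
}
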