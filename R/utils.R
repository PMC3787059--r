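## Internal helpers shared across the package.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random-number stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## stop() with a consistent error class so callers/tests can match on it.
scStop <- function(msg, class) {
  stop(structure(
    class = c(class, "spikeCircuits_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

configError <- function(msg) scStop(msg, "configError")
validationError <- function(msg) scStop(msg, "validationError")
parseError <- function(msg) scStop(msg, "parseError")
degenerateNetworkError <- function(msg) scStop(msg, "degenerateNetworkError")

## Check a square symmetric weight matrix with zero diagonal, entries in [0,1].
checkWeightMatrix <- function(R, what = "weight matrix", tol = 1e-8) {
  if (!is.matrix(R) || !is.numeric(R) || nrow(R) != ncol(R))
    validationError(sprintf("%s must be a square numeric matrix", what))
  if (any(!is.finite(R)))
    validationError(sprintf("%s contains non-finite entries", what))
  if (max(abs(R - t(R))) > tol)
    validationError(sprintf("%s is not symmetric", what))
  if (min(R) < -tol || max(R) > 1 + tol)
    validationError(sprintf("%s has entries outside [0, 1]", what))
  if (any(abs(diag(R)) > tol))
    validationError(sprintf("%s has a nonzero diagonal", what))
  invisible(TRUE)
}
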