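#' @include AllClasses.R
NULL

# Evaluate expr with a temporarily-set RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user simulations.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Condition helpers used by the CLI to map failures onto exit codes:
# input problems -> 2, computational problems -> 3.
.inputError <- function(...) {
  stop(structure(class = c("mplmInputError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.fitError <- function(...) {
  stop(structure(class = c("mplmFitError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Mesh points lower, lower+step, ... capped at upper (fuzz for fp round-off).
.meshPoints <- function(lower, upper, step) {
  n <- floor((upper - lower) / step + 1e-9)
  lower + step * (0:n)
}
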