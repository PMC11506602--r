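# internal helpers

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# population variance (divide by n), matching the ensemble-average
# definitions <(x - <x>)^2> used for the fluctuation observables
var_pop <- function(x) {
  if (length(x) < 2) stop("at least two samples are needed")
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
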