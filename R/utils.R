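# Internal helpers: seeded randomness that never disturbs the caller's RNG
# stream, and tiny shared utilities.

# Evaluate `expr` under an optional local seed; the global .Random.seed is
# restored afterwards so simulators are reproducible without hidden coupling.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

local_runif <- function(seed, n, min = 0, max = 1) {
  with_local_seed(seed, stats::runif(n, min, max))
}

local_sample_bits <- function(seed, n) {
  with_local_seed(seed, sample(c(0L, 1L), n, replace = TRUE))
}

# classed error constructors: data errors (bad input content) vs config errors
stop_data <- function(..., class = "oligostore_data_error") {
  stop(structure(class = c(class, "oligostore_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop_data(..., class = "oligostore_config_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
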