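# Internal helpers: seeded evaluation and seed spawning.

#' @useDynLib massresponse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under `seed` (if non-NULL) and restore the caller's RNG
# state afterwards, so library calls never perturb a user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive `n` independent substream seeds from a master seed. Keeps every
# derived seed strictly below 2^31 so it remains a valid R integer.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
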