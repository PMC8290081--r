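#' @useDynLib cueloop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.onLoad <- function(libname, pkgname) {
  # One BLAS thread: the permutation engine issues many medium GEMMs and
  # oversubscribed OpenBLAS threading slows them down badly on small hosts.
  try(cpp_set_blas_threads(1L), silent = TRUE)
  invisible()
}

# --- private RNG streams -------------------------------------------------
# Stateful objects (virtual subjects, window sources) carry their own RNG
# stream so that simulations are reproducible without trampling the
# caller's global .Random.seed.

rng_new <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  globalenv()$.Random.seed
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

rng_draw <- function(state, fn) {
  old <- globalenv()$.Random.seed
  assign(".Random.seed", state, envir = globalenv())
  value <- fn()
  state <- globalenv()$.Random.seed
  restore_rng(old)
  list(value = value, state = state)
}

clip01 <- function(x) pmin(1, pmax(0, x))
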