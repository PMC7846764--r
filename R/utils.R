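#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

#' Derive a stage-specific random seed from a global seed
#'
#' All stochastic sub-steps of the pipeline draw their seed from a single
#' integer seed through this deterministic scheme, so one `seed` reproduces
#' an entire run while stages stay decoupled (re-running one stage does not
#' perturb another's stream).
#'
#' The scheme hashes the tag with a Horner scan modulo the Mersenne prime
#' 2^31 - 1, mixes in the seed, and applies two Lehmer multiplication
#' rounds (exact in double precision).
#'
#' @param seed integer global seed.
#' @param tag character stage tag, e.g. `"simulate"`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(tag))) h <- (h * 31 + c) %% m
  x <- (h + (abs(seed) %% m)) %% m
  if (x == 0) x <- 1
  x <- (x * 48271) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
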