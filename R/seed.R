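#' Derive a reproducible sub-seed from a master seed
#'
#' Replicated experiments need one independent, individually reproducible
#' random stream per (stage, replication). Sub-seeds are derived from the
#' master seed and a stream index by a fixed multiplicative hash modulo
#' 2^31 - 1, so every stream is a deterministic function of
#' `(master_seed, stream)` and stays inside the 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param stream Integer stream index (>= 0); vectors allowed.
#' @return Integer vector of sub-seeds in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(master_seed)) %% m)
  # two rounds of a Lehmer-style mix keep nearby (seed, stream) pairs apart
  x <- (s * 48271 + as.double(stream) * 16807 + 1) %% m
  x <- (x * 69621) %% m
  as.integer(ifelse(x < 1, x + 1, x))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
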