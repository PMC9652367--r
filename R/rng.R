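# Deterministic stream splitting: every exported stochastic operation takes
# one integer master seed and derives an independent sub-seed per draw type,
# so adding a new stream never perturbs existing ones.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' A small multiplicative hash (LCG constants, arithmetic kept below 2^53 so
#' it is exact in doubles) maps `(seed, key)` to an integer in `[0, 2^31)`.
#' Used internally to give each draw type (covariate, outcome, field) its own
#' RNG stream.
#'
#' @param seed integer master seed.
#' @param key character stream label.
#' @return integer sub-seed suitable for [set.seed()].
#' @export
#' @examples
#' split_seed(42, "age") != split_seed(42, "outcome")
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  s <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(key)) {
    s <- (s * 69069 + code) %% 2147483647
  }
  as.integer(s)
}

# evaluate expr under a given seed, restoring the caller's RNG state
with_stream <- function(seed, key, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(split_seed(seed, key))
  expr
}
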