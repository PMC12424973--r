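#' @importFrom stats rnorm runif rgamma rbinom qnorm pnorm dnorm sd var
#'   median quantile cor cov ks.test wilcox.test ecdf setNames
#' @import methods
NULL

ln2 <- log(2)

## Numerically stable log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a reproducible child seed from a master seed and a stream label
#'
#' Every stochastic component (frequency draws, latent Gaussians, thinning,
#' concentrations, noise, critic initialization) consumes its own sub-stream
#' derived from one master seed, so components are independently
#' reproducible.
#'
#' @param seed Integer master seed.
#' @param tag Character label of the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647                      # 2^31 - 1, keeps seeds in int range
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h * 16807 + 12345) %% m)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Row-wise softmax with max-subtraction for overflow safety.
rowSoftmax <- function(u) {
  m <- apply(u, 1L, max)
  e <- exp(u - m)
  e / rowSums(e)
}

## Add a bias (row) vector to every row of a matrix.
addBias <- function(a, b) a + matrix(b, nrow(a), length(b), byrow = TRUE)

## Short digest of an R object (for provenance fields); stable across
## sessions because it hashes the serialized representation.
objectDigest <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  idx <- seq(1L, length(raw), by = max(1L, length(raw) %/% 4096))
  h <- 0
  for (b in as.integer(raw[idx])) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}
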