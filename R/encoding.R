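#' Encoding parameters
#'
#' @param hillCoeff Hill coefficient n of the receptor dose-response curve
#'   (default 1.46, the value fitted to larval receptor recordings).
#' @param neuralNoiseSD SD sigma_0 of the additive Gaussian neural noise
#'   (default 0.1, on the order of the mean activity).
#' @return A validated list of encoding parameters.
#' @export
encodingParams <- function(hillCoeff = 1.46, neuralNoiseSD = 0.1) {
  if (hillCoeff <= 0) stop("hillCoeff must be positive", call. = FALSE)
  if (neuralNoiseSD < 0) stop("neuralNoiseSD must be nonnegative",
                              call. = FALSE)
  list(hillCoeff = hillCoeff, neuralNoiseSD = neuralNoiseSD)
}

#' Hill activation function
#'
#' `phi(x) = 1 / (1 + x^-n)`, evaluated in the overflow-safe form
#' `x^n / (x^n + 1)` so that `phi(0) = 0` (the limit value).
#'
#' @param x Nonnegative drive (scalar or array).
#' @param n Hill coefficient.
#' @return Values in `[0, 1)`, same shape as `x`.
#' @examples
#' hillActivation(1, 1.46)  # 0.5 for every n
#' @export
hillActivation <- function(x, n = 1.46) {
  if (any(x < 0)) stop("Hill activation needs nonnegative drive",
                       call. = FALSE)
  if (n <= 0) stop("Hill coefficient must be positive", call. = FALSE)
  xn <- x^n
  out <- xn / (1 + xn)
  out[is.infinite(xn)] <- 1
  out
}

## d phi / d x, same stable parametrization. Zero drive maps to zero slope
## for n > 1 (and is clamped to 0 for n <= 1 where the limit diverges).
hillGrad <- function(x, n) {
  xn <- x^n
  g <- n * x^(n - 1) / (1 + xn)^2
  g[!is.finite(g)] <- 0
  g
}

## Validators for the plain-matrix circuit layers.
checkSensing <- function(W) {
  if (!is.matrix(W) || any(W <= 0) || any(!is.finite(W)))
    stop("sensing matrix W must be a finite, strictly positive matrix",
         call. = FALSE)
  invisible(W)
}

checkRowStochastic <- function(A, what, tol = 1e-9) {
  if (!is.matrix(A) || any(A < 0))
    stop(what, " must be a nonnegative matrix", call. = FALSE)
  if (max(abs(rowSums(A) - 1)) > tol)
    stop(what, " rows must sum to 1 (tolerance ", tol, ")", call. = FALSE)
  invisible(A)
}

#' Canonical (one neuron-one receptor) expression matrix
#'
#' Each row is one-hot; receptors are allocated to contiguous neuron groups
#' of size `floor(L/M)` with the remainder spread one neuron per receptor
#' starting from receptor 1, so every receptor is expressed by at least one
#' neuron.
#'
#' @param M Number of receptors.
#' @param L Number of neurons (`L >= M`).
#' @return An L x M one-hot row-stochastic matrix.
#' @examples
#' makeCanonicalExpression(3, 4)  # allocation (2, 1, 1)
#' @export
makeCanonicalExpression <- function(M, L) {
  M <- as.integer(M); L <- as.integer(L)
  if (M < 1L || L < M)
    stop("need L >= M >= 1 (every receptor needs a neuron)", call. = FALSE)
  alloc <- blockSizes(L, M)            # same remainder rule as odor blocks
  E <- matrix(0, L, M)
  E[cbind(seq_len(L), rep.int(seq_len(M), alloc))] <- 1
  E
}

#' Neural response of the receptor-expression circuit
#'
#' `r = phi(E W c) + xi` with element-wise Hill activation and i.i.d.
#' Gaussian noise of SD `neuralNoiseSD`. The expression matrix sits inside
#' the nonlinearity: the Hill curve is an empirical fit to neuron activity
#' under mixtures, not a mechanistic receptor model.
#'
#' @param W M x N sensing matrix (positive).
#' @param E L x M expression matrix (row-stochastic).
#' @param batch A [StimulusBatch-class] (or a samples x N concentration
#'   matrix).
#' @param params [encodingParams()] list.
#' @param seed Seed for the noise draw.
#' @return A samples x L matrix of firing rates.
#' @export
neuralResponse <- function(W, E, batch, params = encodingParams(),
                           seed = 1L) {
  checkSensing(W); checkRowStochastic(E, "E")
  conc <- if (is(batch, "StimulusBatch")) batch@conc else batch
  if (ncol(conc) != ncol(W))
    stop("stimulus has ", ncol(conc), " odorants but W has ", ncol(W),
         call. = FALSE)
  if (ncol(E) != nrow(W))
    stop("E has ", ncol(E), " receptors but W has ", nrow(W), call. = FALSE)
  drive <- tcrossprod(conc, W)         # samples x M receptor drive
  z <- tcrossprod(drive, E)            # samples x L
  stopIfNotFinite(z, "neural drive E W c")
  r <- hillActivation(z, params$hillCoeff)
  if (params$neuralNoiseSD > 0) {
    r <- r + withSeed(deriveSeed(seed, "neural-noise"),
                      matrix(rnorm(length(r), sd = params$neuralNoiseSD),
                             nrow(r), ncol(r)))
  }
  r
}

#' Glomerular response
#'
#' `g = G tanh(alpha * r)` per sample; with row-stochastic `G` the output is
#' bounded in (-1, 1).
#'
#' @param G M x L glomerular map (row-stochastic).
#' @param r Samples x L activity matrix.
#' @param alpha Positive transfer gain.
#' @return A samples x M glomerular activity matrix.
#' @export
glomerularResponse <- function(G, r, alpha = 1) {
  checkRowStochastic(G, "G")
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (ncol(G) != ncol(r))
    stop("G has ", ncol(G), " neuron inputs but r has ", ncol(r),
         call. = FALSE)
  tcrossprod(tanh(alpha * r), G)
}
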