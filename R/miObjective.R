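#' Fenchel conjugate of the Jensen-Shannon generator
#'
#' `f*(t) = -log(2 - exp(t))`, defined for `t < log(2)`. Strictly increasing
#' and convex; the variational Jensen-Shannon bound pairs it with critic
#' outputs squashed below `log(2)`.
#'
#' @param t Numeric values strictly below `log(2)`.
#' @return `-log(2 - exp(t))`.
#' @examples
#' jsdConjugate(0)          # 0
#' jsdConjugate(log(1.5))   # log(2)
#' @export
jsdConjugate <- function(t) {
  if (any(t >= ln2)) stop("jsdConjugate is defined for t < log(2)",
                          call. = FALSE)
  -log(2 - exp(t))
}

#' Initialize an inner-product critic
#'
#' The critic is `T(g, c) = squash(chi(g)' psi(c))` where `chi` and `psi`
#' are separate two-hidden-layer ReLU networks and
#' `squash(v) = log(2) - softplus(-v)` maps the raw inner product into
#' `(-infinity, log(2))`, the domain of the Jensen-Shannon conjugate. The
#' stimulus branch applies a fixed `log1p` transform first, because
#' concentrations span several decades. A joint concatenation architecture
#' (`chi` on `[g, c]` against a trainable weight vector) is available as a
#' spot-check via `architecture = "joint"`.
#'
#' @param dimActivity Input dimension of the activity branch.
#' @param dimStimulus Input dimension of the stimulus branch.
#' @param hidden Hidden width of both networks (two hidden layers each).
#' @param embedDim Output embedding dimension of each branch.
#' @param architecture `"innerProduct"` (default) or `"joint"`.
#' @param stimTransform `"log1p"` (default) or `"identity"`.
#' @param seed Seed for the weight initialization.
#' @return A critic parameter list.
#' @export
initCritic <- function(dimActivity, dimStimulus, hidden = 128L,
                       embedDim = 128L,
                       architecture = c("innerProduct", "joint"),
                       stimTransform = c("log1p", "identity"), seed = 1L) {
  architecture <- match.arg(architecture)
  stimTransform <- match.arg(stimTransform)
  if (architecture == "joint") {
    chi <- mlpInit(dimActivity + dimStimulus, hidden, 1L,
                   deriveSeed(seed, "chi"))
    psi <- NULL
  } else {
    chi <- mlpInit(dimActivity, hidden, embedDim, deriveSeed(seed, "chi"))
    psi <- mlpInit(dimStimulus, hidden, embedDim, deriveSeed(seed, "psi"))
  }
  structure(list(chi = chi, psi = psi, architecture = architecture,
                 stimTransform = stimTransform,
                 dimActivity = dimActivity, dimStimulus = dimStimulus),
            class = "olfecCritic")
}

## Two-hidden-layer ReLU MLP: He-initialized hidden layers, small final
## layer so the initial critic is near-constant (raw score near 0, bound
## near its maximizer for independent inputs).
mlpInit <- function(dIn, hidden, dOut, seed) {
  withSeed(seed, {
    list(
      W1 = matrix(rnorm(dIn * hidden, sd = sqrt(2 / dIn)), dIn, hidden),
      b1 = rep(0, hidden),
      W2 = matrix(rnorm(hidden * hidden, sd = sqrt(2 / hidden)),
                  hidden, hidden),
      b2 = rep(0, hidden),
      W3 = matrix(rnorm(hidden * dOut, sd = 0.01 / sqrt(hidden)),
                  hidden, dOut),
      b3 = rep(0, dOut))
  })
}

mlpForward <- function(p, x) {
  z1 <- addBias(x %*% p$W1, p$b1); h1 <- pmax(z1, 0)
  z2 <- addBias(h1 %*% p$W2, p$b2); h2 <- pmax(z2, 0)
  out <- addBias(h2 %*% p$W3, p$b3)
  list(out = out, x = x, h1 = h1, h2 = h2)
}

## Returns parameter gradients and the gradient w.r.t. the input.
mlpBackward <- function(p, cache, dOut) {
  dH2 <- tcrossprod(dOut, p$W3) * (cache$h2 > 0)
  dH1 <- tcrossprod(dH2, p$W2) * (cache$h1 > 0)
  list(grads = list(W1 = crossprod(cache$x, dH1), b1 = colSums(dH1),
                    W2 = crossprod(cache$h1, dH2), b2 = colSums(dH2),
                    W3 = crossprod(cache$h2, dOut), b3 = colSums(dOut)),
       dX = tcrossprod(dH1, p$W1))
}

## Signed log1p: compresses the decades-spanning concentration axis while
## remaining monotone and finite for any real input.
stimInput <- function(critic, c) {
  if (critic$stimTransform == "log1p") sign(c) * log1p(abs(c)) else c
}

#' Squashed critic score
#'
#' Evaluates `squash(chi(g)' psi(c))` row-wise for matching batches; the
#' result is strictly below `log(2)`.
#'
#' @param critic A critic from [initCritic()].
#' @param g Activity batch (matrix, samples in rows) or vector.
#' @param c Stimulus batch or vector.
#' @return A numeric vector of per-pair scores in `(-Inf, log(2))`.
#' @export
criticScore <- function(critic, g, c) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  if (is.null(dim(c))) c <- matrix(c, nrow = 1L)
  if (ncol(g) != critic$dimActivity || ncol(c) != critic$dimStimulus)
    stop("input dimensions do not match the critic", call. = FALSE)
  v <- rawCriticScore(critic, g, stimInput(critic, c))$v
  stopIfNotFinite(v, "critic score")
  ## the floor keeps the score strictly below log(2) in floating point,
  ## so the conjugate domain can never be violated downstream
  ln2 - pmax(softplus(-v), 1e-12)
}

## Raw (pre-squash) inner-product scores plus forward caches.
rawCriticScore <- function(critic, g, cx) {
  if (critic$architecture == "joint") {
    fw <- mlpForward(critic$chi, cbind(g, cx))
    list(v = drop(fw$out), chi = fw, psi = NULL)
  } else {
    fc <- mlpForward(critic$chi, g)
    fp <- mlpForward(critic$psi, cx)
    list(v = rowSums(fc$out * fp$out), chi = fc, psi = fp)
  }
}

#' Shuffle activity against stimuli
#'
#' Pairs `g[perm, ]` with `c` for a uniform random permutation, producing
#' samples from the product of marginals while preserving each marginal
#' exactly.
#'
#' @param g Activity batch.
#' @param c Stimulus batch with the same number of rows.
#' @param seed Integer seed.
#' @return A list with the mismatched `g`, the original `c`, and the
#'   permutation used.
#' @export
shufflePairs <- function(g, c, seed = 1L) {
  if (nrow(g) != nrow(c)) stop("batch sizes differ", call. = FALSE)
  if (nrow(g) < 2L) stop("need at least 2 samples to shuffle",
                         call. = FALSE)
  perm <- withSeed(deriveSeed(seed, "shuffle"), sample.int(nrow(g)))
  list(g = g[perm, , drop = FALSE], c = c, perm = perm)
}

#' Variational Jensen-Shannon lower bound
#'
#' `(mean(T(joint)) - mean(f*(T(shuffled)))) / 2` in nats. The variational
#' objective built from the conjugate `f*(t) = -log(2 - exp(t))` has
#' supremum twice the standard Jensen-Shannon divergence (the generator
#' `u log u - (u+1) log((u+1)/2)` integrates to `KL(P||M) + KL(Q||M)`), so
#' the reported value is half the raw objective: a lower bound on the
#' standard JSD between the joint distribution and the product of
#' marginals, and therefore never above `log(2)`.
#'
#' @param critic A critic from [initCritic()].
#' @param jointG,jointC Matching activity/stimulus batches (joint samples).
#' @param shuffledG,shuffledC Mismatched batches (product-of-marginals
#'   samples), e.g. from [shufflePairs()].
#' @return A list with `value` (nats), `nJoint`, `nMarginal`.
#' @export
jsdLowerBound <- function(critic, jointG, jointC, shuffledG, shuffledC) {
  if (!nrow(jointG) || !nrow(shuffledG))
    stop("both batches must be non-empty", call. = FALSE)
  tj <- criticScore(critic, jointG, jointC)
  ts <- criticScore(critic, shuffledG, shuffledC)
  ## f*(squash(v)) = softplus(v) - log 2, computed stably
  vShuf <- qsquashInverse(ts)
  value <- (mean(tj) - mean(softplus(vShuf) - ln2)) / 2
  list(value = value, nJoint = length(tj), nMarginal = length(ts))
}

## Inverse of the squash t = ln2 - softplus(-v): v = -softplusInv(ln2 - t).
qsquashInverse <- function(t) {
  s <- ln2 - t                         # softplus(-v) > 0
  -ifelse(s > 30, s, log(expm1(s)))
}
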