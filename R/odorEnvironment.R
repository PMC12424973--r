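#' Construct an EnvironmentSpec
#'
#' Defaults describe the reference environment used throughout the package:
#' 1000 odorants organised into 32 correlated sources, Gamma-distributed
#' activation probabilities calibrated so that a typical sample contains
#' about 10 active odorants (range within 1-100), and log-normal
#' concentrations.
#'
#' @param nOdorants Number of odorants N.
#' @param nBlocks Number of sources k (latent covariance blocks).
#' @param withinBlockCorr Latent within-block correlation in `[0, 1)`.
#' @param gammaShape,gammaRate Gamma parameters of the frequency
#'   distribution (mean frequency = shape/rate).
#' @param thinningProb Probability of zeroing an active entry post hoc;
#'   defaults to the per-k schedule of [defaultThinning()].
#' @param concLogSD Log-scale SD of concentration, sigma_c.
#' @param flatFrequency Use a constant activation probability instead of
#'   Gamma draws.
#' @param flatMean The constant activation probability when `flatFrequency`.
#' @param seed Master seed.
#' @return An [EnvironmentSpec-class] object.
#' @examples
#' spec <- environmentSpec(nOdorants = 100, nBlocks = 4, seed = 1)
#' @export
environmentSpec <- function(nOdorants = 1000L, nBlocks = 32L,
                            withinBlockCorr = 0.5,
                            gammaShape = 0.3, gammaRate = 27,
                            thinningProb = defaultThinning(nBlocks),
                            concLogSD = 2, flatFrequency = FALSE,
                            flatMean = 0.01, seed = 1L) {
  new("EnvironmentSpec",
      nOdorants = as.integer(nOdorants), nBlocks = as.integer(nBlocks),
      withinBlockCorr = withinBlockCorr, gammaShape = gammaShape,
      gammaRate = gammaRate, thinningProb = thinningProb,
      concLogSD = concLogSD, flatFrequency = flatFrequency,
      flatMean = flatMean, seed = as.integer(seed))
}

#' Default thinning probability per number of sources
#'
#' Strongly correlated environments (few sources) overshoot the target
#' sparsity, so active entries are independently zeroed with a small
#' probability that grows as the number of sources shrinks; no thinning is
#' applied from 32 sources upward.
#'
#' @param nBlocks Number of sources k.
#' @return A thinning probability in `[0, 1)`.
#' @export
defaultThinning <- function(nBlocks) {
  if (nBlocks >= 32L) 0 else if (nBlocks >= 16L) 0.05 else
    if (nBlocks >= 8L) 0.1 else 0.2
}

#' Block-structured latent covariance
#'
#' Builds the N x N latent copula covariance: unit diagonal, `rho` for
#' off-diagonal pairs within the same source block, 0 across blocks. Block
#' sizes are `floor(N/k)` with the remainder distributed one odorant per
#' block starting from the first block.
#'
#' @param N Number of odorants.
#' @param k Number of blocks (sources).
#' @param rho Within-block correlation in `[0, 1)`.
#' @return An N x N positive-semidefinite matrix.
#' @examples
#' buildBlockCovariance(4, 2, 0.5)
#' @export
buildBlockCovariance <- function(N, k, rho) {
  N <- as.integer(N); k <- as.integer(k)
  if (k < 1L || k > N) stop("need 1 <= k <= N", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  sizes <- blockSizes(N, k)
  blockId <- rep.int(seq_len(k), sizes)
  sigma <- matrix(0, N, N)
  same <- outer(blockId, blockId, "==")
  sigma[same] <- rho
  diag(sigma) <- 1
  sigma
}

## Deterministic block partition: floor(N/k) per block, remainder one each
## from block 1.
blockSizes <- function(N, k) {
  base <- N %/% k
  rem <- N %% k
  base + as.integer(seq_len(k) <= rem)
}

## Block index of each odorant under blockSizes().
blockIds <- function(N, k) rep.int(seq_len(k), blockSizes(N, k))

#' Draw per-odorant activation probabilities
#'
#' Gamma(shape, rate) draws truncated into (0, 1) by remapping values at or
#' above 1 to `1 - 1e-6`; with `flatFrequency` all entries equal `flatMean`.
#'
#' @param spec An [EnvironmentSpec-class].
#' @return A length-N vector of probabilities in (0, 1).
#' @export
drawOdorantFrequencies <- function(spec) {
  validObject(spec)
  n <- spec@nOdorants
  if (spec@flatFrequency) return(rep(spec@flatMean, n))
  mu <- withSeed(deriveSeed(spec@seed, "frequencies"),
                 rgamma(n, shape = spec@gammaShape, rate = spec@gammaRate))
  mu[mu >= 1 - 1e-6] <- 1 - 1e-6
  mu[mu <= 1e-300] <- 1e-300           # rgamma can underflow to 0
  mu
}

#' Build an OdorPanel from an EnvironmentSpec
#'
#' Combines the frequency draw, the block covariance, and the copula
#' thresholds `t = qnorm(1 - mu)`.
#'
#' @param spec An [EnvironmentSpec-class].
#' @return An [OdorPanel-class].
#' @export
odorPanel <- function(spec) {
  validObject(spec)
  mu <- drawOdorantFrequencies(spec)
  sigma <- buildBlockCovariance(spec@nOdorants, spec@nBlocks,
                                spec@withinBlockCorr)
  ## upper-tail form stays finite for very rare odorants
  new("OdorPanel", mu = mu, sigma = sigma,
      thresholds = qnorm(mu, lower.tail = FALSE))
}

## Square-root factor of a PSD covariance: Cholesky when possible, symmetric
## eigen square root otherwise (handles the comonotone/singular limit).
covFactor <- function(sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  es <- eigen(sigma, symmetric = TRUE)
  if (min(es$values) < -1e-8 * max(abs(es$values)))
    stop("latent covariance is not positive semidefinite (min eigenvalue ",
         signif(min(es$values), 3), ")", call. = FALSE)
  vals <- pmax(es$values, 0)
  t(es$vectors %*% (t(es$vectors) * sqrt(vals)))
}

#' Sample correlated binary mixtures through a Gaussian copula
#'
#' Each row is `1[Z > t]` for `Z ~ N(0, Sigma)`; active entries are then
#' independently zeroed with probability `thinningProb`. With unit diagonal
#' Sigma the column means converge to `mu` (times `1 - thinningProb`).
#'
#' @param panel An [OdorPanel-class].
#' @param nSamples Number of samples (rows).
#' @param thinningProb Post-hoc zeroing probability.
#' @param seed Integer seed.
#' @return An `nSamples x N` binary matrix.
#' @export
sampleBinaryMixtures <- function(panel, nSamples, thinningProb = 0,
                                 seed = 1L) {
  validObject(panel)
  if (nSamples < 0) stop("nSamples must be nonnegative", call. = FALSE)
  if (thinningProb < 0 || thinningProb >= 1)
    stop("thinningProb must lie in [0, 1)", call. = FALSE)
  n <- nOdorants(panel)
  if (nSamples == 0L) return(matrix(0L, 0L, n))
  fac <- covFactor(panel@sigma)
  z <- withSeed(deriveSeed(seed, "latent"),
                matrix(rnorm(nSamples * n), nSamples, n)) %*% fac
  cbin <- (z > matrix(panel@thresholds, nSamples, n, byrow = TRUE)) * 1L
  if (thinningProb > 0) {
    keep <- withSeed(deriveSeed(seed, "thinning"),
                     matrix(runif(nSamples * n) >= thinningProb,
                            nSamples, n))
    cbin <- cbin * keep
  }
  storage.mode(cbin) <- "integer"
  cbin
}

#' Assign log-normal concentrations to active odorants
#'
#' Active entries receive `exp(sigmaC * z)` with standard-normal `z`
#' (log-median 0, so the median concentration is 1: only relative
#' sensitivity and concentration matter in the encoding model); absent
#' entries are exactly 0.
#'
#' @param cbin Binary presence matrix.
#' @param sigmaC Log-scale SD of concentration.
#' @param seed Integer seed.
#' @return A nonnegative concentration matrix of the same shape.
#' @export
assignConcentrations <- function(cbin, sigmaC, seed = 1L) {
  if (sigmaC <= 0) stop("sigmaC must be positive", call. = FALSE)
  if (length(cbin) && !all(cbin %in% c(0, 1)))
    stop("cbin must be binary", call. = FALSE)
  conc <- matrix(0, nrow(cbin), ncol(cbin))
  act <- which(cbin == 1)
  if (length(act)) {
    conc[act] <- withSeed(deriveSeed(seed, "concentrations"),
                          exp(sigmaC * rnorm(length(act))))
  }
  conc
}

#' Generate a stimulus batch from an environment specification
#'
#' Composes the frequency draw, block covariance, copula sampling, thinning
#' and concentration assignment into a [StimulusBatch-class]. Samples are
#' conditioned on containing at least one odorant (an empty mixture is not
#' an odor stimulus): rows that come out all-zero after thinning are
#' redrawn. Under the default environment this affects of order one sample
#' in a thousand, so marginal frequencies are essentially unchanged.
#'
#' @param spec An [EnvironmentSpec-class].
#' @param nSamples Number of samples.
#' @param seed Seed for the batch; defaults to the spec's master seed.
#' @return A [StimulusBatch-class].
#' @examples
#' spec <- environmentSpec(nOdorants = 50, nBlocks = 5, seed = 7)
#' batch <- generateStimuli(spec, 20)
#' @export
generateStimuli <- function(spec, nSamples, seed = spec@seed) {
  validObject(spec)
  panel <- odorPanel(spec)
  cbin <- sampleBinaryMixtures(panel, nSamples,
                               thinningProb = spec@thinningProb, seed = seed)
  for (iter in seq_len(100L)) {
    empty <- which(rowSums(cbin) == 0L)
    if (!length(empty)) break
    redraw <- sampleBinaryMixtures(panel, length(empty),
                                   thinningProb = spec@thinningProb,
                                   seed = deriveSeed(seed,
                                                     paste0("redraw", iter)))
    cbin[empty, ] <- redraw
  }
  conc <- assignConcentrations(cbin, spec@concLogSD, seed = seed)
  new("StimulusBatch", cbin = cbin, conc = conc, seed = as.integer(seed),
      specDigest = objectDigest(spec))
}

#' Summarize a stimulus batch
#'
#' Per-odorant empirical frequency, the distribution of active odorants per
#' sample, and the empirical binary correlation matrix.
#'
#' @param batch A non-empty [StimulusBatch-class].
#' @return A list with `frequency`, `activeCount` (min/median/max), and
#'   `binaryCorrelation`.
#' @export
environmentSummary <- function(batch) {
  if (nSamples(batch) == 0L) stop("empty batch", call. = FALSE)
  cbin <- batch@cbin
  counts <- rowSums(cbin)
  sds <- apply(cbin, 2L, sd)
  cc <- matrix(NA_real_, ncol(cbin), ncol(cbin))
  ok <- sds > 0
  if (any(ok)) cc[ok, ok] <- cor(cbin[, ok, drop = FALSE])
  diag(cc) <- 1
  list(frequency = colMeans(cbin),
       activeCount = c(min = min(counts), median = median(counts),
                       max = max(counts)),
       binaryCorrelation = cc)
}
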