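#' Fraction of effectively-zero sensing entries
#'
#' @param W Sensing matrix.
#' @param zeroThreshold Entries below this are counted as zero; defaults to
#'   `1e-6` times the median entry (reported alongside every metric so the
#'   cutoff is auditable).
#' @return Fraction in `[0, 1]`.
#' @export
sparsityFraction <- function(W, zeroThreshold = defaultZeroThreshold(W)) {
  if (zeroThreshold <= 0) stop("zeroThreshold must be positive",
                               call. = FALSE)
  mean(W < zeroThreshold)
}

#' @rdname sparsityFraction
#' @export
defaultZeroThreshold <- function(W) {
  med <- median(W[W > 0])
  1e-6 * med
}

#' Log-normal fit to the supra-threshold sensing entries
#'
#' Maximum-likelihood normal fit to the log of the non-zero entries, plus a
#' Kolmogorov-Smirnov statistic of the log-entries against the fit.
#'
#' @param W Sensing matrix.
#' @param zeroThreshold Cutoff below which entries are treated as zero.
#' @return A list with `logMean`, `logSD`, `ks` (KS statistic), `n`.
#' @export
fitLognormalNonzero <- function(W, zeroThreshold = defaultZeroThreshold(W)) {
  lw <- log(W[W >= zeroThreshold])
  if (length(lw) < 10L)
    stop("need at least 10 supra-threshold entries", call. = FALSE)
  m <- mean(lw); s <- sqrt(mean((lw - m)^2))
  ks <- if (s == 0) 0 else {
    z <- sort((lw - m) / s)
    nn <- length(z)
    max(abs(pnorm(z) - (seq_len(nn) - 0.5) / nn)) + 0.5 / nn
  }
  list(logMean = m, logSD = s, ks = ks, n = length(lw))
}

#' Count specialist receptors
#'
#' A receptor is a specialist if its maximum sensitivity is at least two
#' orders of magnitude greater than its own 99th-percentile sensitivity
#' (the criterion corresponds to testing a 100-odorant panel and finding
#' one odorant detected 100x more sensitively than all the rest). Counts
#' receptors, not receptor-odorant pairs; the target odorant of each
#' specialist is reported.
#'
#' @param W Sensing matrix (rows = receptors).
#' @return A list with `count` and a data frame `pairs` (receptor, odorant,
#'   ratio).
#' @export
countSpecialists <- function(W) {
  if (ncol(W) < 100L)
    warning("fewer than 100 odorants; 99th percentile is interpolated",
            call. = FALSE)
  mx <- apply(W, 1L, max)
  p99 <- apply(W, 1L, quantile, probs = 0.99, names = FALSE, type = 7)
  ratio <- mx / p99
  hit <- which(ratio >= 100)
  list(count = length(hit),
       pairs = data.frame(receptor = hit,
                          odorant = apply(W[hit, , drop = FALSE], 1L,
                                          which.max),
                          ratio = ratio[hit]))
}

#' Dynamic range of each odorant (decades of log10 concentration)
#'
#' For odorant j, the measure of log10 concentration over which at least
#' one receptor's Hill response lies inside the responsive window
#' `[loResp, hiResp]`. Each receptor contributes an interval of closed-form
#' width `(1/n) log10((hi/(1-hi)) ((1-lo)/lo))` centered at
#' `-log10(W_ij) + (1/n) log10(...)` midpoint; the union length is computed
#' exactly by interval arithmetic.
#'
#' @param W Sensing matrix.
#' @param n Hill coefficient.
#' @param loResp,hiResp Response window bounds, `0 < lo < hi < 1`.
#' @return Numeric vector of union widths per odorant.
#' @export
odorantDynamicRange <- function(W, n = 1.46, loResp = 0.1, hiResp = 0.9) {
  if (!(loResp > 0 && loResp < hiResp && hiResp < 1))
    stop("need 0 < loResp < hiResp < 1", call. = FALSE)
  ## phi(w c) = resp at c = (resp/(1-resp))^(1/n) / w
  xLo <- (loResp / (1 - loResp))^(1 / n)
  xHi <- (hiResp / (1 - hiResp))^(1 / n)
  vapply(seq_len(ncol(W)), function(j) {
    w <- W[, j]
    w <- w[w > 0]
    if (!length(w)) return(0)
    lo <- log10(xLo / w)
    hi <- log10(xHi / w)
    unionLength(lo, hi)
  }, numeric(1))
}

## Total length of the union of intervals [lo_i, hi_i].
unionLength <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  curLo <- lo[1]; curHi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > curHi) {
      total <- total + (curHi - curLo)
      curLo <- lo[i]; curHi <- hi[i]
    } else {
      curHi <- max(curHi, hi[i])
    }
  }
  total + (curHi - curLo)
}

#' Canonical expression score
#'
#' `1 - mean_i H(E_i) / log(M)` where `H(E_i)` is the Shannon entropy of
#' row i viewed as a distribution over receptors. One-hot rows score 1,
#' uniform rows score 0, and a row uniform over exactly kappa receptors
#' scores `1 - log(kappa)/log(M)`.
#'
#' @param E Row-stochastic expression matrix.
#' @param tol Row-sum tolerance.
#' @return A scalar in `[0, 1]`.
#' @export
canonicalScore <- function(E, tol = 1e-6) {
  if (max(abs(rowSums(E) - 1)) > tol || any(E < 0))
    stop("E rows must lie on the simplex", call. = FALSE)
  M <- ncol(E)
  if (M == 1L) return(1)
  p <- pmax(E, 0)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  1 - mean(h) / log(M)
}

#' Principal-component variance spectrum of activity
#'
#' Eigenvalues of the sample covariance, normalized to sum to one,
#' descending. Constant activity degenerates to `(1, 0, ...)` with a
#' warning.
#'
#' @param r Samples x units activity matrix (at least 2 samples).
#' @return Numeric vector of variance fractions.
#' @export
pcVarianceSpectrum <- function(r) {
  if (nrow(r) < 2L) stop("need at least 2 samples", call. = FALSE)
  cv <- cov(r)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  if (sum(ev) == 0) {
    warning("constant activity: degenerate spectrum", call. = FALSE)
    return(c(1, rep(0, ncol(r) - 1L)))
  }
  ev / sum(ev)
}

#' Robust coexpression statistics
#'
#' A receptor pair is robustly coexpressed when at least `minNeurons`
#' neurons express both receptors above `exprThreshold`. For every pair the
#' covariance of the two receptors' log-sensitivity profiles (rows of W) is
#' computed; distributions for robust pairs and singly-expressed pairs are
#' compared with a two-sided Mann-Whitney U test.
#'
#' @param E Expression matrix.
#' @param W Sensing matrix.
#' @param exprThreshold Expression level above which a neuron "expresses" a
#'   receptor (fraction of the expression budget).
#' @param minNeurons Minimum number of co-expressing neurons.
#' @return A list with `pairs` (data frame: i, j, nNeurons, covariance,
#'   robust), `pValue` (NA when either group is empty), and the thresholds.
#' @export
robustCoexpressionStats <- function(E, W, exprThreshold = 0.1,
                                    minNeurons = 3L) {
  checkRowStochastic(E, "E", tol = 1e-6)
  M <- ncol(E)
  expressed <- E >= exprThreshold      # L x M
  logW <- log(pmax(W, .Machine$double.xmin))
  coN <- crossprod(expressed * 1)      # M x M co-expressing neuron counts
  pairsIdx <- which(upper.tri(coN), arr.ind = TRUE)
  covW <- cov(t(logW))                 # receptor-by-receptor covariance
  singlyExpressed <- colSums(expressed) >= 1L
  tab <- data.frame(i = pairsIdx[, 1], j = pairsIdx[, 2],
                    nNeurons = coN[pairsIdx],
                    covariance = covW[pairsIdx])
  tab$robust <- tab$nNeurons >= minNeurons
  ## "singly expressed" pairs: both receptors used somewhere, never
  ## coexpressed together
  tab$single <- !tab$robust & tab$nNeurons == 0L &
    singlyExpressed[tab$i] & singlyExpressed[tab$j]
  pValue <- if (any(tab$robust) && any(tab$single)) {
    suppressWarnings(wilcox.test(tab$covariance[tab$robust],
                                 tab$covariance[tab$single],
                                 alternative = "two.sided")$p.value)
  } else NA_real_
  list(pairs = tab, pValue = pValue, exprThreshold = exprThreshold,
       minNeurons = as.integer(minNeurons))
}

#' Null and control models for the sensing matrix
#'
#' `shuffleGlobal` permutes all entries (preserving the full multiset);
#' `shuffleRows` permutes within each row (preserving per-receptor
#' multisets); `lognormalFit` draws i.i.d. from the log-normal fitted to W;
#' `lognormalBlock` and `lognormalToeplitz` draw log-sensitivities with
#' inter-receptor correlation (block receptor families, or correlation
#' decaying with receptor index distance) and marginals matched to the fit.
#'
#' @param W Sensing matrix to model.
#' @param mode One of `"shuffleGlobal"`, `"shuffleRows"`, `"lognormalFit"`,
#'   `"lognormalBlock"`, `"lognormalToeplitz"`.
#' @param seed Integer seed.
#' @param rho Inter-receptor correlation (block) or decay base (Toeplitz:
#'   correlation `rho^|i-j|`).
#' @param nFamilies Number of receptor families for the block mode.
#' @return A matrix of the same shape as W.
#' @export
makeNullSensing <- function(W, mode = c("shuffleGlobal", "shuffleRows",
                                        "lognormalFit", "lognormalBlock",
                                        "lognormalToeplitz"),
                            seed = 1L, rho = 0.7, nFamilies = NULL) {
  mode <- match.arg(mode)
  M <- nrow(W); N <- ncol(W)
  withSeed(deriveSeed(seed, paste0("null-", mode)), {
    switch(mode,
      shuffleGlobal = matrix(sample(W), M, N),
      shuffleRows = t(apply(W, 1L, sample)),
      lognormalFit = {
        f <- fitLognormalNonzero(W, zeroThreshold = .Machine$double.xmin)
        matrix(exp(rnorm(M * N, f$logMean, f$logSD)), M, N)
      },
      lognormalBlock = {
        f <- fitLognormalNonzero(W, zeroThreshold = .Machine$double.xmin)
        nf <- nFamilies %||% max(1L, M %/% 5L)
        fam <- blockIds(M, nf)
        z <- sqrt(1 - rho) * matrix(rnorm(M * N), M, N) +
          sqrt(rho) * matrix(rnorm(nf * N), nf, N)[fam, , drop = FALSE]
        exp(f$logMean + f$logSD * z)
      },
      lognormalToeplitz = {
        f <- fitLognormalNonzero(W, zeroThreshold = .Machine$double.xmin)
        corr <- rho^abs(outer(seq_len(M), seq_len(M), "-"))
        fac <- covFactor(corr)
        z <- t(matrix(rnorm(M * N), N, M) %*% fac)
        exp(f$logMean + f$logSD * z)
      })
  })
}

#' Glomerular purity
#'
#' Each neuron is labelled by its argmax receptor in E; each glomerulus is
#' assigned the receptor whose neurons carry the most of its input weight
#' (lowest index wins ties); purity is the mean, over glomeruli, of the
#' weight fraction arriving from that dominant receptor's neurons. Perfect
#' same-receptor convergence gives 1; uniform pooling gives about 1/M.
#'
#' @param G Glomerular map (rows = glomeruli).
#' @param E Expression matrix (rows = neurons).
#' @return A scalar in `[0, 1]`.
#' @export
glomerularPurity <- function(G, E) {
  checkRowStochastic(G, "G", tol = 1e-6)
  if (ncol(G) != nrow(E))
    stop("G has ", ncol(G), " neuron inputs but E has ", nrow(E), " rows",
         call. = FALSE)
  neuronType <- apply(E, 1L, which.max)         # ties: lowest index
  M <- ncol(E)
  ## weight each glomerulus receives from neurons of each receptor type
  typeWeight <- sapply(seq_len(M), function(m)
    rowSums(G[, neuronType == m, drop = FALSE]))
  if (is.null(dim(typeWeight))) typeWeight <- matrix(typeWeight, nrow = 1L)
  mean(apply(typeWeight, 1L, max))
}

#' Shannon entropy of an equal-width activity histogram
#'
#' Used to quantify histogram equalization at the glomerular transfer
#' stage: entropy (nats) of an equal-width histogram over the observed
#' support. Degenerate support yields 0.
#'
#' @param values Numeric vector (at least 100 values).
#' @param nBins Number of histogram bins.
#' @return Entropy in nats, at most `log(nBins)`.
#' @export
activityHistogramEntropy <- function(values, nBins = 30L) {
  if (length(values) < 100L) stop("need at least 100 values", call. = FALSE)
  if (nBins < 2L) stop("need at least 2 bins", call. = FALSE)
  rng <- range(values)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = nBins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Effective rank of a matrix
#'
#' `exp` of the Shannon entropy of the normalized singular-value
#' distribution; 1 for rank-one matrices, M for the M x M identity.
#'
#' @param W A non-zero matrix.
#' @return A real number `>= 1`.
#' @export
effectiveRank <- function(W) {
  sv <- svd(W, nu = 0, nv = 0)$d
  if (sum(sv) == 0) stop("all-zero matrix has no effective rank",
                         call. = FALSE)
  p <- sv / sum(sv)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Assemble a metrics report for an optimized circuit
#'
#' Computes the scalar diagnostics (sensing sparsity, specialist count,
#' canonical score, effective rank, and optionally glomerular purity and
#' pre/post-glomerular histogram entropies) plus the per-odorant dynamic
#' range table and PC variance spectrum.
#'
#' @param W Sensing matrix.
#' @param E Expression matrix (optional).
#' @param G Glomerular map (optional; requires E).
#' @param alpha Glomerular gain.
#' @param batch A [StimulusBatch-class] for activity-based statistics
#'   (optional).
#' @param encoding [encodingParams()].
#' @param frequency Per-odorant frequency vector for the dynamic-range
#'   table (optional).
#' @param zeroThreshold Effective-zero cutoff for W.
#' @param seed Seed for the noise in activity statistics.
#' @return A [MetricsReport-class].
#' @export
circuitMetrics <- function(W, E = NULL, G = NULL, alpha = 1, batch = NULL,
                           encoding = encodingParams(), frequency = NULL,
                           zeroThreshold = defaultZeroThreshold(W),
                           seed = 1L) {
  scalars <- list(
    sparsityFraction = sparsityFraction(W, zeroThreshold),
    effectiveRank = effectiveRank(W),
    specialistCount = countSpecialists(W)$count)
  tables <- list()
  dr <- odorantDynamicRange(W, n = encoding$hillCoeff)
  tables$perOdorant <- data.frame(odorant = seq_len(ncol(W)),
                                  dynamicRange = dr)
  if (!is.null(frequency)) tables$perOdorant$frequency <- frequency
  if (!is.null(E)) {
    scalars$canonicalScore <- canonicalScore(E)
    if (!is.null(batch)) {
      r <- neuralResponse(W, E, batch, encoding, seed = seed)
      tables$pcVarianceSpectrum <- data.frame(
        component = seq_len(ncol(r)), fraction = pcVarianceSpectrum(r))
      if (!is.null(G)) {
        g <- glomerularResponse(G, r, alpha)
        scalars$glomerularPurity <- glomerularPurity(G, E)
        scalars$activityEntropyPre <- activityHistogramEntropy(as.vector(r))
        scalars$activityEntropyPost <-
          activityHistogramEntropy(as.vector(g))
      }
    }
  }
  new("MetricsReport", scalars = scalars, tables = tables,
      provenance = list(zeroThreshold = zeroThreshold,
                        inputDigest = objectDigest(list(W, E, G, alpha)),
                        hillCoeff = encoding$hillCoeff))
}
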