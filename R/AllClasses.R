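#' EnvironmentSpec: parameters of the synthetic odor environment
#'
#' Describes the statistical model of the olfactory stimulus: `N` odorants
#' whose per-sample presence is a correlated Bernoulli vector generated by a
#' Gaussian copula with block latent covariance (`nBlocks` sources,
#' within-block latent correlation `withinBlockCorr`), per-odorant activation
#' probabilities drawn from a Gamma distribution (or held flat at
#' `flatMean`), optional post-hoc thinning, and i.i.d. log-normal
#' concentrations with log-scale standard deviation `concLogSD` on active
#' odorants.
#'
#' @slot nOdorants Number of odorants N.
#' @slot nBlocks Number of latent sources k (covariance blocks).
#' @slot withinBlockCorr Latent within-block correlation rho, in `[0, 1)`.
#' @slot gammaShape,gammaRate Shape and rate of the Gamma distribution the
#'   per-odorant activation probabilities are drawn from.
#' @slot thinningProb Probability that an active entry is zeroed post hoc.
#' @slot concLogSD Standard deviation of log concentration (sigma_c).
#' @slot flatFrequency If `TRUE`, all activation probabilities equal
#'   `flatMean` instead of Gamma draws.
#' @slot flatMean Constant activation probability used when `flatFrequency`.
#' @slot seed Master seed; all sub-streams are derived from it.
#' @export
setClass("EnvironmentSpec", representation(
  nOdorants = "integer",
  nBlocks = "integer",
  withinBlockCorr = "numeric",
  gammaShape = "numeric",
  gammaRate = "numeric",
  thinningProb = "numeric",
  concLogSD = "numeric",
  flatFrequency = "logical",
  flatMean = "numeric",
  seed = "integer"
))

setValidity("EnvironmentSpec", function(object) {
  msg <- character()
  if (object@nOdorants < 1L) msg <- c(msg, "nOdorants must be >= 1")
  if (object@nBlocks < 1L || object@nBlocks > object@nOdorants)
    msg <- c(msg, "need 1 <= nBlocks <= nOdorants")
  if (object@withinBlockCorr < 0 || object@withinBlockCorr >= 1)
    msg <- c(msg, "withinBlockCorr must lie in [0, 1)")
  if (object@gammaShape <= 0 || object@gammaRate <= 0)
    msg <- c(msg, "gammaShape and gammaRate must be positive")
  if (object@thinningProb < 0 || object@thinningProb >= 1)
    msg <- c(msg, "thinningProb must lie in [0, 1)")
  if (object@concLogSD <= 0) msg <- c(msg, "concLogSD must be positive")
  if (object@flatMean <= 0 || object@flatMean >= 1)
    msg <- c(msg, "flatMean must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' OdorPanel: derived quantities of the stimulus distribution
#'
#' Holds the activation probabilities `mu`, the latent copula covariance
#' `sigma` (unit diagonal), and the per-odorant Gaussian thresholds
#' `thresholds` with `t_i = qnorm(1 - mu_i)`.
#'
#' @slot mu Numeric vector of activation probabilities in (0, 1).
#' @slot sigma Latent covariance matrix (symmetric, unit diagonal, PSD).
#' @slot thresholds Numeric vector of copula thresholds.
#' @export
setClass("OdorPanel", representation(
  mu = "numeric", sigma = "matrix", thresholds = "numeric"
))

setValidity("OdorPanel", function(object) {
  msg <- character()
  n <- length(object@mu)
  if (any(object@mu <= 0) || any(object@mu >= 1))
    msg <- c(msg, "mu entries must lie in (0, 1)")
  if (!all(dim(object@sigma) == c(n, n)))
    msg <- c(msg, "sigma must be N x N")
  else {
    if (max(abs(diag(object@sigma) - 1)) > 1e-12)
      msg <- c(msg, "sigma must have unit diagonal")
    if (max(abs(object@sigma - t(object@sigma))) > 1e-12)
      msg <- c(msg, "sigma must be symmetric")
  }
  if (length(object@thresholds) != n || any(!is.finite(object@thresholds)))
    msg <- c(msg, "thresholds must be finite and length N")
  if (length(msg)) msg else TRUE
})

#' StimulusBatch: sampled odor stimuli
#'
#' @slot cbin Samples-by-odorants binary presence matrix.
#' @slot conc Samples-by-odorants nonnegative concentration matrix; an entry
#'   is strictly positive exactly where `cbin` is 1.
#' @slot seed Seed used to generate the batch.
#' @slot specDigest Digest of the generating [EnvironmentSpec-class].
#' @export
setClass("StimulusBatch", representation(
  cbin = "matrix", conc = "matrix", seed = "integer", specDigest = "character"
))

setValidity("StimulusBatch", function(object) {
  msg <- character()
  if (!all(dim(object@cbin) == dim(object@conc)))
    msg <- c(msg, "cbin and conc must have identical dimensions")
  if (length(object@cbin) && !all(object@cbin %in% c(0, 1)))
    msg <- c(msg, "cbin must be binary")
  if (length(object@conc)) {
    if (any(object@conc < 0) || any(!is.finite(object@conc)))
      msg <- c(msg, "conc must be finite and nonnegative")
    if (!identical(unname(object@conc > 0), unname(object@cbin == 1)))
      msg <- c(msg, "conc must be positive exactly where cbin is 1")
  }
  if (length(msg)) msg else TRUE
})

#' LayerFit: result of one layer-wise optimization
#'
#' @slot layer Which layer was optimized: `"W"`, `"E"` or `"G"`.
#' @slot params Named list of final parameters (`W`, or `E`, or `G` plus
#'   `alpha`).
#' @slot trace Named list with `boundValues` (Jensen-Shannon bound per step,
#'   nats), `constraintResiduals` (max row-sum deviation / min-entry record
#'   per step), and timing metadata.
#' @slot config The optimizer configuration list used for the run.
#' @export
setClass("LayerFit", representation(
  layer = "character", params = "list", trace = "list", config = "list"
))

#' MetricsReport: named diagnostic statistics with provenance
#'
#' @slot scalars Named list of scalar statistics.
#' @slot tables Named list of data frames (per-odorant tables, spectra,
#'   coexpression pairs).
#' @slot provenance Named list recording thresholds and input digests.
#' @export
setClass("MetricsReport", representation(
  scalars = "list", tables = "list", provenance = "list"
))

setMethod("show", "EnvironmentSpec", function(object) {
  cat("EnvironmentSpec:", object@nOdorants, "odorants,",
      object@nBlocks, "sources\n")
  cat("  latent rho =", object@withinBlockCorr,
      " thinning =", object@thinningProb, "\n")
  if (object@flatFrequency) {
    cat("  flat frequencies, mu0 =", object@flatMean, "\n")
  } else {
    cat("  Gamma(", object@gammaShape, ",", object@gammaRate,
        ") frequencies\n")
  }
  cat("  sigma_c =", object@concLogSD, " seed =", object@seed, "\n")
})

setMethod("show", "StimulusBatch", function(object) {
  cat("StimulusBatch:", nrow(object@cbin), "samples x",
      ncol(object@cbin), "odorants\n")
  if (nrow(object@cbin)) {
    cat("  active odorants/sample: median",
        stats::median(rowSums(object@cbin)), "\n")
  }
})

setMethod("show", "LayerFit", function(object) {
  cat("LayerFit over layer", object@layer, "-",
      length(object@trace$boundValues), "steps\n")
  bv <- object@trace$boundValues
  if (length(bv)) {
    k <- min(100L, length(bv))
    cat("  final bound (last", k, "step mean):",
        signif(mean(utils::tail(bv, k)), 4), "nats\n")
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport with", length(object@scalars), "scalars,",
      length(object@tables), "tables\n")
  for (nm in names(object@scalars)) {
    cat(" ", nm, "=", signif(object@scalars[[nm]], 4), "\n")
  }
})
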