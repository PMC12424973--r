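#' Optimizer configuration
#'
#' Defaults are the package's reduced working scale (a run of a few
#' thousand steps); full-scale runs raise `nSteps` to 2e4 via the
#' experiment configs.
#'
#' @param circuitStepSize Step size for the circuit duals (the Adam-
#'   preconditioned gradient is fed to the mirror map).
#' @param criticStepSize Adam step size for the critic networks.
#' @param batchSize Samples per step.
#' @param nSteps Number of joint ascent steps.
#' @param seed Master seed (splits into init / batches / noise / critic).
#' @param initW Sensing initialization: `"scaledLogNormal"` or
#'   `"minSensitivityLogNormal"`.
#' @param initE Expression initialization: `"random"`, `"canonical"`,
#'   `"noncanonical"` or `"noncanonicalBlock"`.
#' @param kMin,kMax Receptors per neuron for the noncanonical inits.
#' @param nFamilies Number of receptor families for the block-structured
#'   noncanonical init and null models.
#' @param minSensitivity Scale constant for the minimum-sensitivity
#'   initialization (configuration value; below it a sensitivity is
#'   effectively zero).
#' @param freshBatchPerStep Draw a fresh stimulus batch every step
#'   (otherwise one fixed batch is reused).
#' @param hidden,embedDim Critic architecture.
#' @param criticArchitecture `"innerProduct"` or `"joint"`.
#' @return A validated configuration list.
#' @export
optimizerConfig <- function(circuitStepSize = 0.05, criticStepSize = 2e-3,
                            batchSize = 512L, nSteps = 2000L, seed = 1L,
                            initW = "scaledLogNormal", initE = "random",
                            kMin = 3L, kMax = 7L, nFamilies = NULL,
                            minSensitivity = 1e-4,
                            freshBatchPerStep = TRUE, hidden = 128L,
                            embedDim = 128L,
                            criticArchitecture = "innerProduct") {
  if (circuitStepSize <= 0 || criticStepSize <= 0)
    stop("step sizes must be positive", call. = FALSE)
  if (nSteps < 1L || batchSize < 2L)
    stop("need nSteps >= 1 and batchSize >= 2", call. = FALSE)
  list(circuitStepSize = circuitStepSize, criticStepSize = criticStepSize,
       batchSize = as.integer(batchSize), nSteps = as.integer(nSteps),
       seed = as.integer(seed), initW = initW, initE = initE,
       kMin = as.integer(kMin), kMax = as.integer(kMax),
       nFamilies = nFamilies, minSensitivity = minSensitivity,
       freshBatchPerStep = freshBatchPerStep, hidden = as.integer(hidden),
       embedDim = as.integer(embedDim),
       criticArchitecture = criticArchitecture)
}

#' Initialize a sensing matrix
#'
#' `scaledLogNormal` draws `W = exp(Z) / mean(||c||)` with standard-normal
#' `Z`, scaling typical sensitivities to the typical stimulus magnitude;
#' `minSensitivityLogNormal` scales the same log-normal shape to a
#' configurable minimum-sensitivity constant instead.
#'
#' @param M,N Receptors and odorants.
#' @param mode Initialization mode.
#' @param batchForScale A [StimulusBatch-class] used to estimate the mean
#'   stimulus norm (required for `scaledLogNormal`).
#' @param seed Integer seed.
#' @param minSensitivity Scale for the minimum-sensitivity mode.
#' @return An M x N positive matrix.
#' @export
initSensing <- function(M, N, mode = c("scaledLogNormal",
                                       "minSensitivityLogNormal"),
                        batchForScale = NULL, seed = 1L,
                        minSensitivity = 1e-4) {
  mode <- match.arg(mode)
  z <- withSeed(deriveSeed(seed, "w-init"), matrix(rnorm(M * N), M, N))
  scale <- if (mode == "scaledLogNormal") {
    if (is.null(batchForScale) || nSamples(batchForScale) == 0L)
      stop("scaledLogNormal initialization needs a non-empty scale batch",
           call. = FALSE)
    1 / mean(sqrt(rowSums(batchForScale@conc^2)))
  } else {
    minSensitivity
  }
  exp(z) * scale
}

#' Initialize an expression matrix
#'
#' `random`: rows drawn from a flat Dirichlet. `canonical`: delegates to
#' [makeCanonicalExpression()]. `noncanonical`: each neuron expresses
#' `kappa ~ Uniform{kMin..kMax}` receptors chosen uniformly without
#' replacement, at near-equal levels with small multiplicative jitter.
#' `noncanonicalBlock`: the kappa receptors are drawn from one randomly
#' chosen receptor family (coexpression of correlated, related receptors).
#'
#' @param M,L Receptors and neurons.
#' @param mode Initialization mode.
#' @param seed Integer seed.
#' @param kMin,kMax Range of receptors per neuron.
#' @param nFamilies Number of receptor families for the block mode.
#' @param jitterSD SD of the multiplicative log-jitter on expression levels.
#' @return An L x M row-stochastic matrix.
#' @export
initExpression <- function(M, L, mode = c("random", "canonical",
                                          "noncanonical",
                                          "noncanonicalBlock"),
                           seed = 1L, kMin = 3L, kMax = 7L,
                           nFamilies = NULL, jitterSD = 0.05) {
  mode <- match.arg(mode)
  M <- as.integer(M); L <- as.integer(L)
  if (mode == "canonical") return(makeCanonicalExpression(M, L))
  if (mode %in% c("noncanonical", "noncanonicalBlock") && kMax > M)
    stop("kMax cannot exceed the number of receptors", call. = FALSE)
  withSeed(deriveSeed(seed, paste0("e-init-", mode)), {
    if (mode == "random") {
      e <- matrix(rgamma(L * M, shape = 1), L, M)
      return(e / rowSums(e))
    }
    fam <- if (mode == "noncanonicalBlock") {
      nf <- nFamilies %||% max(1L, M %/% max(kMax, 5L))
      blockIds(M, nf)
    } else NULL
    E <- matrix(0, L, M)
    for (i in seq_len(L)) {
      kappa <- sample(seq.int(kMin, kMax), 1L)
      pool <- if (is.null(fam)) seq_len(M) else {
        which(fam == sample.int(max(fam), 1L))
      }
      kappa <- min(kappa, length(pool))
      cols <- if (length(pool) == 1L) pool else sample(pool, kappa)
      w <- exp(jitterSD * rnorm(length(cols)))
      E[i, cols] <- w / sum(w)
    }
    E
  })
}

## Internal stimulus sampler bound to an environment: precomputes the panel
## and the covariance factor, then draws batches from the ambient RNG
## stream (callers control seeding).
makeStimulusSampler <- function(spec) {
  panel <- odorPanel(spec)
  fac <- covFactor(panel@sigma)
  thr <- panel@thresholds
  n <- length(thr)
  pThin <- spec@thinningProb
  sigC <- spec@concLogSD
  function(b) {
    z <- matrix(rnorm(b * n), b, n) %*% fac
    cbin <- (z > matrix(thr, b, n, byrow = TRUE)) * 1
    if (pThin > 0) cbin <- cbin * (matrix(runif(b * n), b, n) >= pThin)
    conc <- matrix(0, b, n)
    act <- which(cbin == 1)
    if (length(act)) conc[act] <- exp(sigC * rnorm(length(act)))
    conc
  }
}

## Joint ascent engine shared by the three layer optimizations. Maximizes
## the Jensen-Shannon bound simultaneously over the free layer's duals
## (Adam-preconditioned mirror ascent) and the critic parameters (Adam).
optimizeLayer <- function(layer, spec, W, E, encoding, cfg,
                          Ginit = NULL, alphaInit = 1) {
  sampler <- makeStimulusSampler(spec)
  N <- spec@nOdorants
  M <- nrow(W); L <- nrow(E)
  n <- encoding$hillCoeff; sig0 <- encoding$neuralNoiseSD
  actDim <- if (layer == "G") M else L
  critic <- initCritic(actDim, N, hidden = cfg$hidden,
                       embedDim = cfg$embedDim,
                       architecture = cfg$criticArchitecture,
                       stimTransform = "log1p",
                       seed = deriveSeed(cfg$seed, "critic"))
  cStates <- criticStatesInit(critic)
  ## duals for the free layer
  if (layer == "W") {
    dual <- pmin(pmax(log(W), -80), 80)
    pre <- adamPrecondInit(dim(W))
  } else if (layer == "E") {
    dual <- log(pmax(E, 1e-12))
    pre <- adamPrecondInit(dim(E))
  } else {
    G <- Ginit; alpha <- alphaInit
    dual <- log(pmax(G, 1e-12))
    pre <- adamPrecondInit(dim(G))
    dualA <- log(alphaInit)
    preA <- adamPrecondInit(1L)
  }
  nSteps <- cfg$nSteps
  bound <- numeric(nSteps)
  maxRowDev <- numeric(nSteps)
  minEntry <- numeric(nSteps)
  fixedConc <- NULL
  withSeed(deriveSeed(cfg$seed, "train"), {
    if (!cfg$freshBatchPerStep) fixedConc <- sampler(cfg$batchSize)
    for (s in seq_len(nSteps)) {
      conc <- if (cfg$freshBatchPerStep) sampler(cfg$batchSize)
              else fixedConc
      b <- nrow(conc)
      drive <- tcrossprod(conc, W)               # b x M
      z <- tcrossprod(drive, E)                  # b x L
      rPre <- hillActivation(z, n)
      r <- if (sig0 > 0) rPre + matrix(rnorm(b * L, sd = sig0), b, L)
           else rPre
      if (layer == "G") {
        u <- tanh(alpha * r)
        act <- tcrossprod(u, G)                  # b x M
      } else {
        act <- r
      }
      perm <- sample.int(b)
      gr <- boundStepGrads(critic, act, conc, perm)
      if (!is.finite(gr$value))
        stop("bound diverged (non-finite) at step ", s, call. = FALSE)
      bound[s] <- gr$value
      ## circuit gradient and mirror step
      if (layer == "W") {
        dZ <- gr$dAct * hillGrad(z, n)
        dDrive <- dZ %*% E
        gLayer <- crossprod(dDrive, conc)        # M x N
        st <- adamPrecond(gLayer, pre); pre <- st$state
        ms <- mirrorStepPositive(dual, st$dir, cfg$circuitStepSize)
        dual <- ms$dual; W <- ms$primal
        minEntry[s] <- min(W); maxRowDev[s] <- 0
      } else if (layer == "E") {
        dZ <- gr$dAct * hillGrad(z, n)
        gLayer <- crossprod(dZ, drive)           # L x M
        st <- adamPrecond(gLayer, pre); pre <- st$state
        ms <- mirrorStepSimplex(dual, st$dir, cfg$circuitStepSize)
        dual <- ms$dual; E <- ms$primal
        minEntry[s] <- min(E); maxRowDev[s] <- max(abs(rowSums(E) - 1))
      } else {
        gG <- crossprod(gr$dAct, u)              # M x L
        dU <- gr$dAct %*% G                      # b x L
        gAlpha <- sum(dU * (1 - u^2) * r)
        st <- adamPrecond(gG, pre); pre <- st$state
        ms <- mirrorStepSimplex(dual, st$dir, cfg$circuitStepSize)
        dual <- ms$dual; G <- ms$primal
        stA <- adamPrecond(gAlpha, preA); preA <- stA$state
        msA <- mirrorStepPositive(matrix(dualA, 1, 1),
                                  matrix(stA$dir, 1, 1),
                                  cfg$circuitStepSize)
        dualA <- msA$dual[1, 1]; alpha <- msA$primal[1, 1]
        minEntry[s] <- min(G); maxRowDev[s] <- max(abs(rowSums(G) - 1))
      }
      up <- criticAscend(critic, gr, cStates, cfg$criticStepSize)
      critic <- up$critic; cStates <- up$states
    }
  })
  params <- switch(layer,
                   W = list(W = W),
                   E = list(E = E),
                   G = list(G = G, alpha = alpha))
  new("LayerFit", layer = layer, params = params,
      trace = list(boundValues = bound,
                   constraintResiduals = data.frame(
                     step = seq_len(nSteps), maxRowSumDeviation = maxRowDev,
                     minEntry = minEntry)),
      config = cfg)
}

#' Optimize the sensing matrix W under canonical expression
#'
#' Maximizes the Jensen-Shannon bound between neural activity and stimulus
#' over the positive sensing matrix, with a canonical one-receptor-per-
#' neuron expression matrix plugged in.
#'
#' @param spec An [EnvironmentSpec-class].
#' @param M,L Receptors and neurons.
#' @param encoding [encodingParams()].
#' @param cfg [optimizerConfig()].
#' @return A [LayerFit-class] with `params$W`.
#' @export
optimizeSensing <- function(spec, M, L = M, encoding = encodingParams(),
                            cfg = optimizerConfig()) {
  E <- makeCanonicalExpression(M, L)
  scaleBatch <- generateStimuli(spec, max(cfg$batchSize, 256L),
                                seed = deriveSeed(cfg$seed, "w-scale"))
  W <- initSensing(M, spec@nOdorants, cfg$initW, batchForScale = scaleBatch,
                   seed = cfg$seed, minSensitivity = cfg$minSensitivity)
  optimizeLayer("W", spec, W, E, encoding, cfg)
}

#' Optimize the expression matrix E for a fixed sensing matrix
#'
#' @param spec An [EnvironmentSpec-class].
#' @param W Fixed M x N sensing matrix.
#' @param L Number of neurons.
#' @param encoding [encodingParams()].
#' @param cfg [optimizerConfig()]; `cfg$initE` selects the initialization.
#' @return A [LayerFit-class] with `params$E` (the initial expression is
#'   recorded in `trace$initE`).
#' @export
optimizeExpression <- function(spec, W, L, encoding = encodingParams(),
                               cfg = optimizerConfig()) {
  checkSensing(W)
  E0 <- initExpression(nrow(W), L, cfg$initE, seed = cfg$seed,
                       kMin = cfg$kMin, kMax = cfg$kMax,
                       nFamilies = cfg$nFamilies)
  fit <- optimizeLayer("E", spec, W, E0, encoding, cfg)
  fit@trace$initE <- E0
  fit
}

#' Optimize the glomerular map G and gain alpha
#'
#' With fixed W and E, maximizes the bound between glomerular activity
#' `g = G tanh(alpha r)` and the stimulus over the row-stochastic map G and
#' the positive scalar gain (optimized through a log dual).
#'
#' @param spec An [EnvironmentSpec-class].
#' @param W Fixed sensing matrix.
#' @param E Fixed expression matrix.
#' @param encoding [encodingParams()].
#' @param cfg [optimizerConfig()].
#' @return A [LayerFit-class] with `params$G` and `params$alpha`.
#' @export
optimizeGlomerular <- function(spec, W, E, encoding = encodingParams(),
                               cfg = optimizerConfig(
                                 circuitStepSize = 0.15,
                                 criticStepSize = 3e-3)) {
  checkSensing(W); checkRowStochastic(E, "E")
  M <- nrow(W); L <- nrow(E)
  G0 <- withSeed(deriveSeed(cfg$seed, "g-init"), {
    g <- matrix(rgamma(M * L, shape = 1), M, L)
    g / rowSums(g)
  })
  optimizeLayer("G", spec, W, E, encoding, cfg, Ginit = G0, alphaInit = 1)
}
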