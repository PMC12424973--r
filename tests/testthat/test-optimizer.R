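testSpec <- function(seed = 5L) {
  environmentSpec(nOdorants = 200L, nBlocks = 8L, seed = seed)
}

testCfg <- function(seed = 11L, nSteps = 2000L, ...) {
  optimizerConfig(nSteps = nSteps, batchSize = 128L, hidden = 64L,
                  embedDim = 32L, seed = seed, ...)
}

test_that("sensing initializations have the declared scale and shape", {
  spec <- testSpec()
  batch <- generateStimuli(spec, 400)
  W <- initSensing(8, 200, "scaledLogNormal", batchForScale = batch,
                   seed = 2L)
  expect_true(all(W > 0))
  lw <- log(W)
  scale <- 1 / mean(sqrt(rowSums(concentrationMatrix(batch)^2)))
  n <- length(lw)
  expect_lt(abs(mean(lw) - log(scale)), 4 / sqrt(n))
  expect_lt(abs(sd(lw) - 1), 4 / sqrt(2 * n))
  ## log-entries pass a KS test against the normal
  ks <- suppressWarnings(ks.test(as.vector(scale(as.vector(lw))), "pnorm"))
  expect_gt(ks$p.value, 1e-4)
  W2 <- initSensing(8, 200, "minSensitivityLogNormal", seed = 2L,
                    minSensitivity = 1e-4)
  expect_lt(abs(mean(log(W2)) - log(1e-4)), 4 / sqrt(n))
  expect_error(initSensing(8, 200, "scaledLogNormal"), "scale batch")
})

test_that("expression initializations satisfy their structural contracts", {
  expect_equal(initExpression(6, 6, "canonical"), diag(6))
  Er <- initExpression(10, 40, "random", seed = 1L)
  expect_equal(rowSums(Er), rep(1, 40), tolerance = 1e-9)
  En <- initExpression(10, 200, "noncanonical", seed = 2L, kMin = 3L,
                       kMax = 7L, jitterSD = 0)
  kk <- rowSums(En > 0)
  expect_true(all(kk >= 3 & kk <= 7))
  expect_true(all(sort(unique(kk)) == 3:7))   # whole range appears
  ## zero jitter: each nonzero equals 1/kappa
  expect_equal(max(abs(En[En > 0] - 1 / kk[row(En)[En > 0]])), 0)
  ## block mode draws all receptors of a row from one family
  Eb <- initExpression(12, 100, "noncanonicalBlock", seed = 3L, kMin = 2L,
                       kMax = 4L, nFamilies = 3L)
  fam <- rep(1:3, each = 4)
  famPerRow <- apply(Eb > 0, 1L, function(z) length(unique(fam[z])))
  expect_true(all(famPerRow == 1))
  expect_equal(rowSums(Eb), rep(1, 100), tolerance = 1e-9)
  expect_error(initExpression(5, 10, "noncanonical", kMax = 7L), "exceed")
})

test_that("mirror steps keep constraints exact over many updates", {
  ## fixed points and monotonicity
  u <- matrix(c(0.3, -0.2, 1, 0), 2, 2)
  same <- mirrorStepPositive(u, matrix(0, 2, 2), 0.5)
  expect_identical(same$primal, exp(u))
  up <- mirrorStepPositive(u, matrix(c(1, 0, 0, 0), 2, 2), 0.5)
  expect_gt(up$primal[1, 1], exp(u)[1, 1])
  expect_equal(up$primal[2, 1], exp(u)[2, 1])
  expect_equal(mirrorStepSimplex(matrix(2, 3, 4), matrix(0, 3, 4),
                                 1)$primal,
               matrix(0.25, 3, 4))
  ## constraint exactness after 10^4 random steps
  set.seed(4)
  uPos <- matrix(rnorm(12), 3, 4)
  uSim <- matrix(rnorm(12), 3, 4)
  for (i in 1:10000) {
    g <- matrix(rnorm(12, sd = 2), 3, 4)
    uPos <- mirrorStepPositive(uPos, g, 0.01)$dual
    uSim <- mirrorStepSimplex(uSim, g, 0.01)$dual
  }
  expect_true(all(mirrorStepPositive(uPos, matrix(0, 3, 4), 1)$primal > 0))
  rs <- rowSums(mirrorStepSimplex(uSim, matrix(0, 3, 4), 1)$primal)
  expect_equal(rs, rep(1, 3), tolerance = 1e-12)
  expect_error(mirrorStepPositive(uPos, matrix(NaN, 3, 4), 1),
               "non-finite")
})

test_that("layer optimizations are reproducible and keep constraints", {
  spec <- testSpec()
  batch <- generateStimuli(spec, 256)
  W <- initSensing(10, 200, "scaledLogNormal", batchForScale = batch,
                   seed = 7L)
  cfg <- testCfg(nSteps = 120L)
  f1 <- optimizeExpression(spec, W, 30L, encodingParams(), cfg)
  f2 <- optimizeExpression(spec, W, 30L, encodingParams(), cfg)
  expect_identical(boundTrace(f1)$boundValues, boundTrace(f2)$boundValues)
  expect_identical(fittedParams(f1)$E, fittedParams(f2)$E)
  res <- boundTrace(f1)$constraintResiduals
  expect_lte(max(res$maxRowSumDeviation), 1e-9)
  expect_true(all(res$minEntry >= 0))
  expect_equal(nrow(res), 120L)
})

test_that("the bound ascends during sensing and expression optimization", {
  spec <- testSpec()
  improvements <- vapply(1:5, function(sd) {
    fit <- optimizeExpression(
      spec,
      initSensing(10, 200, "scaledLogNormal",
                  batchForScale = generateStimuli(spec, 256, seed = sd),
                  seed = sd),
      30L, encodingParams(), testCfg(seed = sd, nSteps = 800L))
    bv <- boundTrace(fit)$boundValues
    mean(bv[301:400]) - mean(bv[1:100])
  }, numeric(1))
  expect_gte(sum(improvements > 0), 4)
})

test_that("expression optimized from null sensing models stays canonical", {
  ## the chicken-or-egg control: optimizing E from any of the five null-W
  ## models reaches at least the canonical score reached from the
  ## optimized W (up to training noise at this reduced scale)
  spec <- testSpec()
  cfgW <- testCfg(seed = 3L, nSteps = 1500L)
  Wopt <- fittedParams(optimizeSensing(spec, 10L, 30L, encodingParams(),
                                       cfgW))$W
  cfgE <- testCfg(seed = 21L, nSteps = 2000L, initE = "random")
  scoreFrom <- function(W) {
    canonicalScore(fittedParams(
      optimizeExpression(spec, W, 30L, encodingParams(), cfgE))$E)
  }
  sOpt <- scoreFrom(Wopt)
  nulls <- vapply(c("shuffleGlobal", "shuffleRows", "lognormalFit",
                    "lognormalBlock", "lognormalToeplitz"),
                  function(m) scoreFrom(makeNullSensing(Wopt, m, seed = 9L)),
                  numeric(1))
  expect_true(all(nulls >= sOpt - 0.05))
  expect_gte(mean(nulls), sOpt)
  expect_gt(sOpt, 0.5)                 # optimization is actually moving
})

test_that("more neural noise favors more canonical expression", {
  spec <- testSpec()
  W <- initSensing(10, 200, "scaledLogNormal",
                   batchForScale = generateStimuli(spec, 256, seed = 9L),
                   seed = 9L)
  scores <- vapply(c(0.01, 0.1), function(s0) {
    fit <- optimizeExpression(spec, W, 30L,
                              encodingParams(neuralNoiseSD = s0),
                              testCfg(seed = 13L))
    canonicalScore(fittedParams(fit)$E)
  }, numeric(1))
  expect_gte(scores[2], scores[1])
})
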