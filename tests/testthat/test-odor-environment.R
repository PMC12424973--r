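test_that("block covariance has the specified block structure", {
  expect_equal(buildBlockCovariance(4, 4, 0.5), diag(4))
  s <- buildBlockCovariance(4, 2, 0.5)
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[3, 4], 0.5)
  expect_equal(s[1, 3], 0)
  expect_equal(diag(s), rep(1, 4))
  ## remainder rule: N = 7, k = 3 gives blocks of sizes 3, 2, 2
  s7 <- buildBlockCovariance(7, 3, 0.3)
  expect_equal(sum(s7[1, ] > 0), 3)
  expect_equal(sum(s7[4, ] > 0), 2)
  expect_error(buildBlockCovariance(4, 2, 1), "rho")
  expect_error(buildBlockCovariance(4, 5, 0.5), "k <= N")
})

test_that("block covariance stays positive definite at scale", {
  for (r in c(0.3, 0.7, 0.9)) {
    s <- buildBlockCovariance(300, 16, r)
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1 - r - 1e-10)
  }
})

test_that("odorant frequencies follow the configured distribution", {
  flat <- environmentSpec(nOdorants = 5L, flatFrequency = TRUE,
                          flatMean = 0.01, nBlocks = 1L)
  expect_equal(drawOdorantFrequencies(flat), rep(0.01, 5))
  spec <- environmentSpec(nOdorants = 100000L, nBlocks = 1L,
                          gammaShape = 2, gammaRate = 40, seed = 5L)
  mu <- drawOdorantFrequencies(spec)
  expect_true(all(mu > 0 & mu < 1))
  ## Gamma mean identity a/b within 3 standard errors
  se <- sqrt(2 / 40^2 / length(mu))
  expect_lt(abs(mean(mu) - 2 / 40), 3 * se)
  expect_identical(mu, drawOdorantFrequencies(spec))
  expect_error(environmentSpec(gammaShape = -1), "positive")
})

test_that("copula sampling reproduces marginals and comonotone blocks", {
  ## independent fair coins
  panel <- new("OdorPanel", mu = rep(0.5, 8), sigma = diag(8),
               thresholds = rep(0, 8))
  cb <- sampleBinaryMixtures(panel, 10000, seed = 2L)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(colMeans(cb) - 0.5) < 4 * se))
  ## comonotone limit: within-block entries identical in every sample
  sig <- buildBlockCovariance(6, 2, 0.999)
  sig[sig == 0.999] <- 1
  panel2 <- new("OdorPanel", mu = rep(0.3, 6), sigma = sig,
                thresholds = rep(qnorm(0.7), 6))
  cb2 <- sampleBinaryMixtures(panel2, 200, seed = 3L)
  expect_true(all(cb2[, 1] == cb2[, 2] & cb2[, 2] == cb2[, 3]))
  expect_true(all(cb2[, 4] == cb2[, 5] & cb2[, 5] == cb2[, 6]))
  ## vanishing activation
  panel3 <- new("OdorPanel", mu = rep(1e-9, 3), sigma = diag(3),
                thresholds = rep(qnorm(1e-9, lower.tail = FALSE), 3))
  expect_equal(sum(sampleBinaryMixtures(panel3, 2000, seed = 1L)), 0)
})

test_that("copula marginal fidelity holds for Gamma-drawn frequencies", {
  spec <- environmentSpec(nOdorants = 25L, nBlocks = 5L, gammaShape = 2,
                          gammaRate = 20, seed = 8L)
  panel <- odorPanel(spec)
  n <- 100000L
  cb <- sampleBinaryMixtures(panel, n, seed = 4L)
  mu <- activationProbs(panel)
  se <- sqrt(mu * (1 - mu) / n)
  expect_true(all(abs(colMeans(cb) - mu) < 4 * se))
})

test_that("within-block binary correlation increases with latent rho", {
  cors <- sapply(c(0.1, 0.4, 0.7, 0.95), function(r) {
    sig <- buildBlockCovariance(10, 2, r)
    panel <- new("OdorPanel", mu = rep(0.2, 10), sigma = sig,
                 thresholds = rep(qnorm(0.8), 10))
    cb <- sampleBinaryMixtures(panel, 20000, seed = 9L)
    mean(cor(cb)[1:5, 1:5][upper.tri(diag(5))])
  })
  expect_true(all(diff(cors) > 0))
})

test_that("thinning scales activation frequencies by 1 - p", {
  panel <- new("OdorPanel", mu = rep(0.4, 10), sigma = diag(10),
               thresholds = rep(qnorm(0.6), 10))
  n <- 50000L
  cb <- sampleBinaryMixtures(panel, n, thinningProb = 0.25, seed = 6L)
  target <- 0.4 * 0.75
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(colMeans(cb) - target) < 4 * se))
})

test_that("concentrations are log-normal on active entries, zero elsewhere", {
  expect_equal(assignConcentrations(matrix(0L, 3, 3), 2),
               matrix(0, 3, 3))
  cb <- matrix(1L, 1000, 100)
  conc <- assignConcentrations(cb, 3, seed = 11L)
  lw <- log(conc)
  nTot <- length(lw)
  expect_lt(abs(median(log10(conc))), 3 * 1.2533 * (3 / log(10)) /
              sqrt(nTot))
  expect_lt(abs(sd(lw) - 3), 3 * 3 / sqrt(2 * nTot))
  expect_identical(conc, assignConcentrations(cb, 3, seed = 11L))
  expect_error(assignConcentrations(cb, 0), "positive")
  ## absent odorants are exactly zero, bitwise
  cb2 <- matrix(rbinom(400, 1, 0.3), 20, 20)
  c2 <- assignConcentrations(cb2, 2, seed = 1L)
  expect_identical(c2 == 0, cb2 == 0)
})

test_that("generated batches respect composition invariants", {
  spec <- smallSpec(seed = 21L)
  b <- generateStimuli(spec, 300)
  expect_s4_class(b, "StimulusBatch")
  expect_identical(dim(presenceMatrix(b)), c(300L, 40L))
  expect_identical(concentrationMatrix(b) > 0, presenceMatrix(b) == 1L)
  ## flat independent case: counts ~ Binomial(N, mu0)
  flat <- environmentSpec(nOdorants = 1000L, nBlocks = 1000L,
                          flatFrequency = TRUE, flatMean = 0.01,
                          withinBlockCorr = 0, seed = 3L)
  fb <- generateStimuli(flat, 3000)
  counts <- rowSums(presenceMatrix(fb))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 * 0.99 / 3000) + 0.05)
  ## empty batch
  eb <- generateStimuli(spec, 0)
  expect_equal(nSamples(eb), 0L)
  expect_equal(nOdorants(eb), 40L)
})

test_that("environment summaries report frequencies and correlations", {
  spec <- smallSpec(seed = 5L)
  b <- generateStimuli(spec, 500)
  s <- environmentSummary(b)
  expect_equal(s$frequency, colMeans(presenceMatrix(b)))
  expect_true(s$activeCount["min"] >= 1)
  expect_error(environmentSummary(generateStimuli(spec, 0)), "empty")
  ## comonotone block gives within-block empirical correlation 1
  sig <- buildBlockCovariance(4, 2, 0.5); sig[sig == 0.5] <- 1
  panel <- new("OdorPanel", mu = rep(0.5, 4), sigma = sig,
               thresholds = rep(0, 4))
  cb <- sampleBinaryMixtures(panel, 400, seed = 2L)
  b2 <- new("StimulusBatch", cbin = cb,
            conc = assignConcentrations(cb, 1, 1L), seed = 1L,
            specDigest = "manual")
  s2 <- environmentSummary(b2)
  expect_equal(s2$binaryCorrelation[1, 2], 1)
})

test_that("stimulus batches round-trip through plain-text persistence", {
  b <- generateStimuli(smallSpec(seed = 2L), 25)
  stem <- file.path(tempdir(), "batch-test")
  writeStimulusBatch(b, stem)
  b2 <- readStimulusBatch(stem)
  expect_identical(presenceMatrix(b2), presenceMatrix(b))
  expect_equal(concentrationMatrix(b2), concentrationMatrix(b),
               tolerance = 1e-10)
  spec <- smallSpec(seed = 9L)
  pj <- file.path(tempdir(), "spec.json")
  py <- file.path(tempdir(), "spec.yaml")
  writeEnvironmentSpec(spec, pj)
  writeEnvironmentSpec(spec, py)
  expect_equal(drawOdorantFrequencies(readEnvironmentSpec(pj)),
               drawOdorantFrequencies(spec))
  expect_equal(readEnvironmentSpec(py)@nBlocks, spec@nBlocks)
})
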