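test_that("sparsity fraction counts sub-threshold entries", {
  W <- matrix(c(1, 2, 1e-9, 1e-8), 2, 2)
  expect_equal(sparsityFraction(W, 1e-6), 0.5)
  expect_equal(sparsityFraction(W, 1e-12), 0)
  expect_equal(sparsityFraction(W, 10), 1)
  expect_error(sparsityFraction(W, 0), "positive")
})

test_that("log-normal fits recover parameters and flag mixtures", {
  set.seed(2)
  w <- matrix(exp(rnorm(100000, -3, 1.7)), 100, 1000)
  f <- fitLognormalNonzero(w, zeroThreshold = 1e-300)
  expect_lt(abs(f$logSD - 1.7) / 1.7, 0.02)
  expect_lt(abs(f$logMean + 3), 0.03)
  ## constant entries degenerate to zero spread
  expect_equal(fitLognormalNonzero(matrix(2, 5, 5),
                                   zeroThreshold = 1e-300)$logSD, 0)
  ## a two-component mixture fits worse than a pure sample
  wMix <- matrix(exp(c(rnorm(5000, -6, 0.3), rnorm(5000, 0, 0.3))),
                 100, 100)
  expect_gt(fitLognormalNonzero(wMix, 1e-300)$ks, f$ks)
  expect_error(fitLognormalNonzero(matrix(1, 2, 2), 1e-300), "at least 10")
})

test_that("specialist receptors are ratio-based outliers", {
  set.seed(3)
  base <- matrix(exp(rnorm(5 * 200, 0, 0.2)), 5, 200)
  none <- countSpecialists(base)
  expect_equal(none$count, 0)
  ## plant one receptor whose max is exactly 100x its 99th percentile
  W <- base
  p99 <- quantile(W[1, ], 0.99, names = FALSE)
  W[1, 7] <- 100 * p99
  ## recompute: inserting the outlier shifts the percentile slightly, so
  ## rescale to sit exactly at the threshold
  p99new <- quantile(W[1, ], 0.99, names = FALSE)
  W[1, 7] <- 100 * p99new
  while (W[1, 7] < 100 * quantile(W[1, ], 0.99, names = FALSE)) {
    W[1, 7] <- W[1, 7] * 1.0001
  }
  res <- countSpecialists(W)
  expect_gte(res$count, 1)
  expect_true(7 %in% res$pairs$odorant[res$pairs$receptor == 1])
  ## invariance under global rescaling
  expect_equal(countSpecialists(W * 1e6)$count, res$count)
  ## constant rows are never specialists
  expect_equal(countSpecialists(matrix(1, 3, 200))$count, 0)
  ## log-normal resampling of a specialist-free W stays specialist-free
  expect_equal(countSpecialists(makeNullSensing(base, "lognormalFit",
                                                seed = 1L))$count, 0)
  expect_warning(countSpecialists(matrix(exp(rnorm(50 * 10)), 10, 50)),
                 "interpolated")
})

test_that("odorant dynamic range matches the Hill closed form and oracle", {
  ## single receptor: (1/n) log10(81) decades for the [0.1, 0.9] window
  W1 <- matrix(5, 1, 1)
  expect_equal(odorantDynamicRange(W1, n = 1), 2 * log10(9),
               tolerance = 1e-10)
  expect_equal(odorantDynamicRange(W1, n = 2), log10(9), tolerance = 1e-10)
  ## identical receptors add nothing
  expect_equal(odorantDynamicRange(matrix(5, 4, 1), n = 1), 2 * log10(9))
  ## far-apart receptors contribute disjoint windows
  expect_equal(odorantDynamicRange(matrix(c(1, 1e6), 2, 1), n = 1),
               4 * log10(9), tolerance = 1e-10)
  ## brute-force grid oracle on random small matrices
  set.seed(5)
  W <- matrix(exp(rnorm(12, 0, 2)), 3, 4)
  expect_equal(odorantDynamicRange(W, n = 1.46),
               bruteDynamicRange(W, 1.46, 0.1, 0.9), tolerance = 1e-2)
  expect_error(odorantDynamicRange(W, loResp = 0.9, hiResp = 0.1), "<")
})

test_that("canonical score spans one-hot to uniform with the log-M norm", {
  expect_equal(canonicalScore(makeCanonicalExpression(9, 30)), 1)
  expect_equal(canonicalScore(matrix(1 / 6, 10, 6)), 0)
  for (kappa in c(2, 4)) {
    M <- 12L
    E <- matrix(0, 5, M)
    E[, seq_len(kappa)] <- 1 / kappa
    expect_equal(canonicalScore(E), 1 - log(kappa) / log(M))
  }
  expect_error(canonicalScore(matrix(0.7, 2, 2)), "simplex")
})

test_that("PC spectra distinguish isotropic from degenerate activity", {
  set.seed(6)
  iso <- matrix(rnorm(20000), 2000, 10)
  sIso <- pcVarianceSpectrum(iso)
  expect_equal(sum(sIso), 1)
  expect_true(all(abs(sIso - 0.1) < 0.02))
  rank1 <- outer(rnorm(500), rnorm(4))
  expect_gt(pcVarianceSpectrum(rank1)[1], 1 - 1e-10)
  expect_warning(pcVarianceSpectrum(matrix(1, 10, 3)), "constant")
})

test_that("robust coexpression counts pairs and tests covariances", {
  W <- fixtureSensing(M = 6L, N = 120L)
  ## canonical expression has no coexpressed pairs
  none <- robustCoexpressionStats(makeCanonicalExpression(6, 12), W)
  expect_equal(sum(none$pairs$robust), 0)
  expect_true(is.na(none$pValue))
  ## three neurons sharing receptors (1, 2) make exactly one robust pair
  E <- makeCanonicalExpression(6, 12)
  E[1:3, ] <- 0
  E[1:3, 1] <- 0.5; E[1:3, 2] <- 0.5
  one <- robustCoexpressionStats(E, W)
  expect_equal(sum(one$pairs$robust), 1)
  expect_equal(one$pairs[one$pairs$robust, c("i", "j")],
               data.frame(i = 1L, j = 2L, row.names = 1L))
  ## identical sensing rows: pair covariance equals the row variance
  W2 <- W; W2[2, ] <- W2[1, ]
  two <- robustCoexpressionStats(E, W2)
  expect_equal(two$pairs$covariance[two$pairs$i == 1 & two$pairs$j == 2],
               var(log(W2[1, ])))
  expect_true(is.finite(one$pValue))
})

test_that("null sensing models preserve what they claim to preserve", {
  W <- fixtureSensing(M = 10L, N = 1000L, logSD = 1.5)
  g <- makeNullSensing(W, "shuffleGlobal", seed = 2L)
  expect_equal(sort(as.vector(g)), sort(as.vector(W)))
  expect_false(identical(g, W))
  r <- makeNullSensing(W, "shuffleRows", seed = 2L)
  for (i in c(1, 5, 10)) expect_equal(sort(r[i, ]), sort(W[i, ]))
  f <- makeNullSensing(W, "lognormalFit", seed = 2L)
  expect_lt(abs(sd(log(f)) - sd(log(W))), 0.05)
  ## block model: within-family log correlation near rho, across near 0
  b <- makeNullSensing(W, "lognormalBlock", seed = 3L, rho = 0.6,
                       nFamilies = 2L)
  cc <- cor(t(log(b)))
  within <- mean(cc[1:5, 1:5][upper.tri(diag(5))])
  across <- mean(cc[1:5, 6:10])
  expect_lt(abs(within - 0.6), 0.08)
  expect_lt(abs(across), 0.08)
  tz <- makeNullSensing(W, "lognormalToeplitz", seed = 3L, rho = 0.5)
  cct <- cor(t(log(tz)))
  expect_lt(abs(mean(cct[cbind(1:9, 2:10)]) - 0.5), 0.08)
  expect_lt(abs(mean(cct[cbind(1:6, 5:10)]) - 0.5^4), 0.1)
})

test_that("glomerular purity separates convergence from uniform pooling", {
  E <- makeCanonicalExpression(7, 21)
  Gpure <- t(E); Gpure <- Gpure / rowSums(Gpure)
  expect_equal(glomerularPurity(Gpure, E), 1)
  Gunif <- matrix(1 / 21, 7, 21)
  expect_equal(glomerularPurity(Gunif, E), 1 / 7, tolerance = 1e-10)
  expect_error(glomerularPurity(matrix(1 / 20, 7, 20), E),
               "neuron inputs")
})

test_that("histogram entropy quantifies equalization", {
  u <- rep(seq(0.05, 0.95, by = 0.1), each = 50)
  expect_equal(activityHistogramEntropy(u, nBins = 10), log(10),
               tolerance = 1e-10)
  expect_equal(activityHistogramEntropy(rep(1, 200), nBins = 10), 0)
  expect_error(activityHistogramEntropy(1:50), "at least 100")
  ## saturating transform flattens a near-zero-clustered distribution
  set.seed(7)
  r <- abs(rnorm(5000, 0, 0.15))
  e1 <- activityHistogramEntropy(tanh(r))
  e5 <- activityHistogramEntropy(tanh(5 * r))
  expect_gt(e5, e1)
})

test_that("effective rank interpolates between 1 and full rank", {
  expect_equal(effectiveRank(outer(1:5, 1:7)), 1, tolerance = 1e-10)
  expect_equal(effectiveRank(diag(9)), 9, tolerance = 1e-10)
  set.seed(8)
  lnW <- matrix(exp(rnorm(60 * 1000)), 60, 1000)
  expect_gt(effectiveRank(lnW), 40)
  expect_error(effectiveRank(matrix(0, 2, 2)), "all-zero")
})

test_that("metrics reports assemble scalars, tables and provenance", {
  spec <- smallSpec(seed = 31L)
  batch <- generateStimuli(spec, 300)
  W <- fixtureSensing(M = 5L, N = 40L)
  E <- makeCanonicalExpression(5, 10)
  G <- t(E); G <- G / rowSums(G)
  ## 40-odorant fixture: the specialist percentile warning is expected
  rep1 <- suppressWarnings(
    circuitMetrics(W, E = E, G = G, alpha = 2, batch = batch,
                   frequency = colMeans(presenceMatrix(batch))))
  sc <- metricScalars(rep1)
  expect_true(all(c("sparsityFraction", "effectiveRank",
                    "specialistCount", "canonicalScore",
                    "glomerularPurity", "activityEntropyPre",
                    "activityEntropyPost") %in% names(sc)))
  expect_equal(sc$canonicalScore, 1)
  expect_equal(sc$glomerularPurity, 1)
  tb <- metricTables(rep1)
  expect_equal(nrow(tb$perOdorant), 40)
  expect_s4_class(rep1, "MetricsReport")
})
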