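#' Experiment configuration
#'
#' Bundles an environment, circuit sizes, encoding and optimizer settings
#' under a unique id; [runExperiment()] executes it end-to-end.
#'
#' @param id Experiment identifier (used as run-directory name).
#' @param spec An [EnvironmentSpec-class].
#' @param M,L Receptors and neurons.
#' @param encoding [encodingParams()].
#' @param cfg [optimizerConfig()].
#' @param layers Which layer optimizations to run, in order; a subset of
#'   `c("W", "E", "G")`. When `"W"` is absent a log-normal sensing matrix
#'   scaled to the stimulus is generated instead of optimized.
#' @param nMetricSamples Stimulus samples used for activity-based metrics.
#' @return A validated configuration list.
#' @export
experimentConfig <- function(id, spec, M, L, encoding = encodingParams(),
                             cfg = optimizerConfig(),
                             layers = c("W", "E"),
                             nMetricSamples = 1000L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!all(layers %in% c("W", "E", "G")))
    stop("layers must be a subset of W, E, G", call. = FALSE)
  if (encoding$hillCoeff <= 0) stop("invalid Hill coefficient",
                                    call. = FALSE)
  validObject(spec)
  list(id = id, spec = spec, M = as.integer(M), L = as.integer(L),
       encoding = encoding, cfg = cfg, layers = layers,
       nMetricSamples = as.integer(nMetricSamples))
}

#' Reduced test-scale configuration
#'
#' A small circuit (N = 200 odorants, M = 10 receptors, L = 30 neurons)
#' that exercises every code path in minutes.
#'
#' @param id Experiment id.
#' @param seed Master seed.
#' @param nSteps,batchSize Optimizer budget.
#' @param layers Layers to optimize.
#' @param ... Passed to [optimizerConfig()].
#' @return An experiment configuration.
#' @export
testScaleConfig <- function(id = "test-scale", seed = 1L, nSteps = 500L,
                            batchSize = 128L, layers = c("E"), ...) {
  experimentConfig(
    id = id,
    spec = environmentSpec(nOdorants = 200L, nBlocks = 8L, seed = seed),
    M = 10L, L = 30L,
    encoding = encodingParams(),
    cfg = optimizerConfig(nSteps = nSteps, batchSize = batchSize,
                          seed = seed, hidden = 64L, embedDim = 32L, ...),
    layers = layers)
}

#' Full-scale larva configuration (21 receptors, 1000 odorants)
#'
#' @param seed Master seed.
#' @param nSteps Optimizer budget (2e4 at full scale).
#' @return An experiment configuration.
#' @export
larvaConfig <- function(seed = 1L, nSteps = 20000L) {
  experimentConfig(
    id = "larva-W",
    spec = environmentSpec(nOdorants = 1000L, nBlocks = 32L,
                           concLogSD = 3, seed = seed),
    M = 21L, L = 21L,
    cfg = optimizerConfig(nSteps = nSteps, seed = seed),
    layers = c("W", "E"))
}

#' Full-scale adult-fly configuration (60 receptors, 1260 neurons)
#'
#' @param seed Master seed.
#' @param nSteps Optimizer budget.
#' @return An experiment configuration.
#' @export
adultConfig <- function(seed = 1L, nSteps = 20000L) {
  experimentConfig(
    id = "adult-E",
    spec = environmentSpec(nOdorants = 1000L, nBlocks = 32L,
                           concLogSD = 2, seed = seed),
    M = 60L, L = 1260L,
    cfg = optimizerConfig(nSteps = nSteps, seed = seed,
                          initE = "noncanonical"),
    layers = c("W", "E"))
}

#' Run an experiment end-to-end
#'
#' Generates the environment, runs the configured layer optimizations in
#' order, computes metrics, and writes parameters (TSV), traces (TSV),
#' metrics (JSON) and a manifest (JSON) into `outDir/id`. Re-running with
#' the same configuration and seed reproduces the outputs.
#'
#' @param config From [experimentConfig()].
#' @param outDir Output directory root.
#' @return The run directory path, invisibly; the fitted objects are
#'   attached as attributes `fits` and `metrics`.
#' @export
runExperiment <- function(config, outDir = tempdir()) {
  runDir <- file.path(outDir, config$id)
  dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec
  cfg <- config$cfg
  fits <- list()
  if ("W" %in% config$layers) {
    fits$W <- optimizeSensing(spec, config$M, config$L, config$encoding,
                              cfg)
    W <- fits$W@params$W
  } else {
    scaleBatch <- generateStimuli(spec, 512L,
                                  seed = deriveSeed(cfg$seed, "w-scale"))
    W <- initSensing(config$M, spec@nOdorants, "scaledLogNormal",
                     batchForScale = scaleBatch, seed = cfg$seed)
  }
  E <- makeCanonicalExpression(config$M, config$L)
  if ("E" %in% config$layers) {
    fits$E <- optimizeExpression(spec, W, config$L, config$encoding, cfg)
    E <- fits$E@params$E
  }
  G <- NULL; alpha <- 1
  if ("G" %in% config$layers) {
    fits$G <- optimizeGlomerular(spec, W, E, config$encoding, cfg)
    G <- fits$G@params$G
    alpha <- fits$G@params$alpha
  }
  batch <- generateStimuli(spec, config$nMetricSamples,
                           seed = deriveSeed(cfg$seed, "metrics"))
  freq <- colMeans(batch@cbin)
  metrics <- circuitMetrics(W, E = E, G = G, alpha = alpha, batch = batch,
                            encoding = config$encoding, frequency = freq,
                            seed = deriveSeed(cfg$seed, "metric-noise"))
  ## persist: parameters, traces, metrics, manifest
  writeMatrixTSV(W, file.path(runDir, "W.tsv"))
  writeMatrixTSV(E, file.path(runDir, "E.tsv"))
  if (!is.null(G)) writeMatrixTSV(G, file.path(runDir, "G.tsv"))
  for (nm in names(fits)) {
    tr <- fits[[nm]]@trace
    utils::write.table(
      data.frame(step = seq_along(tr$boundValues), bound = tr$boundValues,
                 maxRowSumDeviation = tr$constraintResiduals$maxRowSumDeviation,
                 minEntry = tr$constraintResiduals$minEntry),
      file.path(runDir, paste0("trace-", nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(scalars = metrics@scalars, provenance = metrics@provenance),
    file.path(runDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(id = config$id, seed = cfg$seed,
         specDigest = objectDigest(spec),
         configDigest = objectDigest(config[setdiff(names(config),
                                                    "spec")]),
         layers = config$layers, alpha = alpha,
         packageVersion =
           as.character(utils::packageVersion("olfec"))),
    file.path(runDir, "manifest.json"), auto_unbox = TRUE)
  structure(invisible(runDir), fits = fits, metrics = metrics)
}

#' Phase-diagram sweep over environment parameters
#'
#' For each (number of sources k, concentration spread sigma_c, seed) cell:
#' build the environment, obtain a sensing matrix (a null model of the
#' given mode, or a freshly optimized one), optimize expression from the
#' configured initialization, and record the final canonical score.
#'
#' @param kValues Numbers of sources.
#' @param sigmaCValues Concentration log-SD values.
#' @param base Base experiment configuration (sizes, encoding, optimizer).
#' @param wMode `"optimized"` or a [makeNullSensing()] mode applied to a
#'   scaled log-normal reference (null models of W).
#' @param seedsPerCell Seeds per cell; cell seeds are derived from the base
#'   seed and the cell coordinates so cells are independently rerunnable.
#' @return A data frame: k, sigmaC, seed, initScore, finalScore.
#' @export
runPhaseSweep <- function(kValues, sigmaCValues, base,
                          wMode = "shuffleGlobal", seedsPerCell = 1L) {
  if (!length(kValues) || !length(sigmaCValues) || seedsPerCell < 1L)
    stop("sweep grid must be non-empty with seeds >= 1", call. = FALSE)
  rows <- list()
  for (k in kValues) for (sc in sigmaCValues) {
    for (i in seq_len(seedsPerCell)) {
      cellSeed <- deriveSeed(base$cfg$seed,
                             sprintf("cell-%d-%g-%d", k, sc, i))
      res <- tryCatch({
        spec <- environmentSpec(
          nOdorants = base$spec@nOdorants, nBlocks = as.integer(k),
          withinBlockCorr = base$spec@withinBlockCorr,
          gammaShape = base$spec@gammaShape,
          gammaRate = base$spec@gammaRate,
          thinningProb = defaultThinning(as.integer(k)),
          concLogSD = sc, seed = cellSeed)
        cfg <- base$cfg; cfg$seed <- cellSeed
        if (identical(wMode, "optimized")) {
          W <- optimizeSensing(spec, base$M, base$L, base$encoding,
                               cfg)@params$W
        } else {
          scaleBatch <- generateStimuli(spec, 512L,
                                        seed = deriveSeed(cellSeed, "ws"))
          Wref <- initSensing(base$M, spec@nOdorants, "scaledLogNormal",
                              batchForScale = scaleBatch, seed = cellSeed)
          W <- makeNullSensing(Wref, wMode, seed = cellSeed)
        }
        fit <- optimizeExpression(spec, W, base$L, base$encoding, cfg)
        data.frame(k = k, sigmaC = sc, seed = cellSeed,
                   initScore = canonicalScore(fit@trace$initE),
                   finalScore = canonicalScore(fit@params$E),
                   error = NA_character_)
      }, error = function(e) {
        data.frame(k = k, sigmaC = sc, seed = cellSeed,
                   initScore = NA_real_, finalScore = NA_real_,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Consolidate metrics from several run directories
#'
#' Merges the `metrics.json` of each run into one comparison table and
#' flags monotone trends (canonical score vs neural noise, specialist
#' count vs receptor number) when the relevant columns are present.
#'
#' @param runDirs Character vector of run directories written by
#'   [runExperiment()].
#' @param outFile Optional path for the consolidated JSON report.
#' @return A list with `table` (one row per run) and `trends`.
#' @export
writeReport <- function(runDirs, outFile = NULL) {
  if (!length(runDirs)) stop("need at least one completed run",
                             call. = FALSE)
  rows <- lapply(runDirs, function(d) {
    mf <- file.path(d, "metrics.json")
    if (!file.exists(mf)) stop("no metrics.json in ", d, call. = FALSE)
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    man <- jsonlite::read_json(file.path(d, "manifest.json"),
                               simplifyVector = TRUE)
    cbind(data.frame(id = man$id, seed = man$seed),
          as.data.frame(m$scalars))
  })
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA
    r[nms]
  })
  tab <- do.call(rbind, rows)
  trends <- list()
  if (!is.null(tab$canonicalScore) && nrow(tab) > 1L)
    trends$canonicalScoreNonDecreasing <-
      !is.unsorted(tab$canonicalScore, na.rm = TRUE)
  report <- list(table = tab, trends = trends)
  if (!is.null(outFile)) {
    jsonlite::write_json(report, outFile, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  report
}
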