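#' Plain-text persistence
#'
#' Batches and circuit parameters are persisted in plain-text containers: a
#' TSV pair (`<stem>-cbin.tsv`, `<stem>-conc.tsv`) plus a JSON sidecar with
#' the seed and spec digest for stimulus batches; TSV matrices for circuit
#' parameters; JSON/YAML for environment specifications.
#'
#' @param batch A [StimulusBatch-class].
#' @param stem Path stem (files get suffixes).
#' @return `stem`, invisibly (writers); the reconstructed object (readers).
#' @name persistence
NULL

writeMatrixTSV <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

readMatrixTSV <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @rdname persistence
#' @export
writeStimulusBatch <- function(batch, stem) {
  writeMatrixTSV(batch@cbin, paste0(stem, "-cbin.tsv"))
  writeMatrixTSV(signif(batch@conc, 12), paste0(stem, "-conc.tsv"))
  jsonlite::write_json(list(seed = batch@seed,
                            specDigest = batch@specDigest,
                            nSamples = nSamples(batch),
                            nOdorants = nOdorants(batch)),
                       paste0(stem, "-meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname persistence
#' @export
readStimulusBatch <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "-meta.json"),
                              simplifyVector = TRUE)
  cbin <- readMatrixTSV(paste0(stem, "-cbin.tsv"))
  storage.mode(cbin) <- "integer"
  conc <- readMatrixTSV(paste0(stem, "-conc.tsv"))
  dimnames(cbin) <- dimnames(conc) <- NULL
  new("StimulusBatch", cbin = cbin, conc = conc,
      seed = as.integer(meta$seed), specDigest = meta$specDigest)
}

#' @rdname persistence
#' @param spec An [EnvironmentSpec-class].
#' @param path File path (`.json` or `.yaml`/`.yml`).
#' @export
writeEnvironmentSpec <- function(spec, path) {
  lst <- list(schema = "olfec/environment/1",
              nOdorants = spec@nOdorants, nBlocks = spec@nBlocks,
              withinBlockCorr = spec@withinBlockCorr,
              gammaShape = spec@gammaShape, gammaRate = spec@gammaRate,
              thinningProb = spec@thinningProb,
              concLogSD = spec@concLogSD,
              flatFrequency = spec@flatFrequency,
              flatMean = spec@flatMean, seed = spec@seed)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname persistence
#' @export
readEnvironmentSpec <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(lst$schema, "olfec/environment/1"))
    stop("unrecognized environment schema: ", lst$schema, call. = FALSE)
  environmentSpec(nOdorants = lst$nOdorants, nBlocks = lst$nBlocks,
                  withinBlockCorr = lst$withinBlockCorr,
                  gammaShape = lst$gammaShape, gammaRate = lst$gammaRate,
                  thinningProb = lst$thinningProb,
                  concLogSD = lst$concLogSD,
                  flatFrequency = lst$flatFrequency,
                  flatMean = lst$flatMean, seed = lst$seed)
}
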