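#' @name accessors
#' @title Accessors for olfec containers
#' @param x An olfec object.
#' @description Slot accessors for the S4 containers: number of odorants and
#'   samples, presence and concentration matrices, activation probabilities,
#'   latent covariance, fitted parameters and optimization traces.
NULL

#' @rdname accessors
#' @export
setGeneric("nOdorants", function(x) standardGeneric("nOdorants"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("concentrationMatrix",
           function(x) standardGeneric("concentrationMatrix"))
#' @rdname accessors
#' @export
setGeneric("activationProbs", function(x) standardGeneric("activationProbs"))
#' @rdname accessors
#' @export
setGeneric("latentCovariance", function(x) standardGeneric("latentCovariance"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("boundTrace", function(x) standardGeneric("boundTrace"))
#' @rdname accessors
#' @export
setGeneric("metricScalars", function(x) standardGeneric("metricScalars"))
#' @rdname accessors
#' @export
setGeneric("metricTables", function(x) standardGeneric("metricTables"))

#' @rdname accessors
#' @export
setMethod("nOdorants", "EnvironmentSpec", function(x) x@nOdorants)
#' @rdname accessors
#' @export
setMethod("nOdorants", "OdorPanel", function(x) length(x@mu))
#' @rdname accessors
#' @export
setMethod("nOdorants", "StimulusBatch", function(x) ncol(x@cbin))
#' @rdname accessors
#' @export
setMethod("nSamples", "StimulusBatch", function(x) nrow(x@cbin))
#' @rdname accessors
#' @export
setMethod("presenceMatrix", "StimulusBatch", function(x) x@cbin)
#' @rdname accessors
#' @export
setMethod("concentrationMatrix", "StimulusBatch", function(x) x@conc)
#' @rdname accessors
#' @export
setMethod("activationProbs", "OdorPanel", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("latentCovariance", "OdorPanel", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("fittedParams", "LayerFit", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("boundTrace", "LayerFit", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("metricScalars", "MetricsReport", function(x) x@scalars)
#' @rdname accessors
#' @export
setMethod("metricTables", "MetricsReport", function(x) x@tables)
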