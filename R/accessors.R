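## Accessor generics and show() methods.  Users should use these rather
## than reaching into slots.

#' Accessors for plvnet classes
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @return `tsData()` the locations x samples matrix; `samplingRate()`
#'   the sampling rate in Hz; `locationIds()` the location identifiers;
#'   `phaseValues()` the locations x retained-samples phase matrix;
#'   `plvValues()` the symmetric PLV matrix; `centralityScores()` the
#'   named numeric centrality vector; `parcelLabels()` the integer label
#'   vector; `parcelCentroids()` the centroid vertex indices;
#'   `networkEdges()` the per-pair test data.frame.
#' @name accessors
#' @aliases tsData samplingRate locationIds phaseValues plvValues
#'   centralityScores parcelLabels parcelCentroids networkEdges
NULL

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("locationIds", function(x) standardGeneric("locationIds"))
#' @rdname accessors
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))
#' @rdname accessors
#' @export
setGeneric("plvValues", function(x) standardGeneric("plvValues"))
#' @rdname accessors
#' @export
setGeneric("centralityScores", function(x) standardGeneric("centralityScores"))
#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(x) standardGeneric("parcelLabels"))
#' @rdname accessors
#' @export
setGeneric("parcelCentroids", function(x) standardGeneric("parcelCentroids"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
setMethod("tsData", "TimeSeriesSet", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "TimeSeriesSet", function(x) x@fs)
#' @rdname accessors
setMethod("locationIds", "TimeSeriesSet", function(x) x@locationIds)
#' @rdname accessors
setMethod("phaseValues", "PhaseSeries", function(x) x@phases)
#' @rdname accessors
setMethod("locationIds", "PhaseSeries", function(x) x@locationIds)
#' @rdname accessors
setMethod("plvValues", "PLVMatrix", function(x) x@values)
#' @rdname accessors
setMethod("locationIds", "PLVMatrix", function(x) x@locationIds)
#' @rdname accessors
setMethod("centralityScores", "CentralityVector",
          function(x) setNames(x@scores, x@locationIds))
#' @rdname accessors
setMethod("locationIds", "CentralityVector", function(x) x@locationIds)
#' @rdname accessors
setMethod("parcelLabels", "Parcellation", function(x) x@labels)
#' @rdname accessors
setMethod("parcelCentroids", "Parcellation", function(x) x@centroids)
#' @rdname accessors
setMethod("networkEdges", "RegionNetwork", function(x) x@edges)

setMethod("show", "WaveletSpec", function(object) {
  cat(sprintf(
    "Morlet WaveletSpec: f0 = %g Hz, c = %g, sigma_f = %.4g Hz, sigma_t = %.4g s\n",
    object@f0, object@cRatio, object@sigmaF, object@sigmaT))
})

setMethod("show", "TimeSeriesSet", function(object) {
  cat(sprintf("TimeSeriesSet: %d locations x %d samples at %g Hz (%.3g s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf(
    "PhaseSeries at %g Hz: %d locations x %d retained samples (%d..%d)\n",
    object@f0, nrow(object@phases), ncol(object@phases),
    object@validRange[1], object@validRange[2]))
})

setMethod("show", "PLVMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "PLVMatrix (%s Hz): %d x %d, off-diagonal range [%.3f, %.3f], mean %.3f\n",
    object@band, nrow(object@values), ncol(object@values),
    min(off), max(off), mean(off)))
})

setMethod("show", "CentralityVector", function(object) {
  cat(sprintf("CentralityVector: %d dipoles, top score %.4f at %s\n",
              length(object@scores), max(object@scores),
              object@locationIds[which.max(object@scores)]))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf(
    "Parcellation: %d vertices in %d regions (objective %.4f, %d iterations%s)\n",
    length(object@labels), object@k, object@objective, object@iterations,
    if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "RegionNetwork", function(object) {
  cat(sprintf(
    "RegionNetwork: %d regions, %d pairs tested, %d significant at alpha = %g\n",
    object@k, nrow(object@edges), sum(object@edges$significant),
    object@alpha))
})

setMethod("show", "SurfaceGeometry", function(object) {
  cat(sprintf("SurfaceGeometry: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "InverseModel", function(object) {
  cat(sprintf(
    "InverseModel: %d sensors -> %d sources, snr = %g (lambda^2 = %g)\n",
    nrow(object@A), ncol(object@A), object@snr, object@lambda2))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s' (seed %d): %s\n", object@kind, object@seed,
              paste(names(object@params), collapse = ", ")))
})
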