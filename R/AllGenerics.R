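#' @export
setGeneric("encode", function(model, x, ...) standardGeneric("encode"))

#' @export
setGeneric("classify", function(model, x, ...) standardGeneric("classify"))

#' @export
setGeneric("decode", function(model, x, ...) standardGeneric("decode"))

#' @export
setGeneric("trainModel", function(model, segments, ...)
  standardGeneric("trainModel"))

#' @export
setGeneric("segmentScores", function(fit, segments, ...)
  standardGeneric("segmentScores"))

#' @export
setGeneric("callPeaks", function(fit, segments, ...)
  standardGeneric("callPeaks"))

#' @export
setGeneric("denoisedTracks", function(fit, segments, ...)
  standardGeneric("denoisedTracks"))

#' Accessors for PeakSegments and ContrastModel objects
#'
#' \code{segTensor} returns the S x R x alpha coverage tensor;
#' \code{candidateRegions} and \code{segmentRanges} the region/segment
#' \code{GRanges}; \code{resolvedThresholds} the per-chromosome coverage
#' thresholds used during selection; \code{lossHistory} the per-epoch loss
#' table of a fit; \code{modelConfig} and \code{modelParams} the model
#' hyperparameters and parameter arrays; \code{peakClass} the resolved
#' peak-class column.
#'
#' @param x a \code{\link{PeakSegments}}, \code{\link{ContrastModel}} or
#'   \code{\link{ContrastFit}} object
#' @return see individual descriptions above
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("segTensor", function(x) standardGeneric("segTensor"))
#' @rdname accessors
#' @export
setGeneric("candidateRegions", function(x) standardGeneric("candidateRegions"))
#' @rdname accessors
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))
#' @rdname accessors
#' @export
setGeneric("resolvedThresholds", function(x)
  standardGeneric("resolvedThresholds"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("peakClass", function(x) standardGeneric("peakClass"))

#' @rdname accessors
#' @export
setMethod("segTensor", "PeakSegments", function(x) x@tensor)
#' @rdname accessors
#' @export
setMethod("candidateRegions", "PeakSegments", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("segmentRanges", "PeakSegments", function(x) x@segments)
#' @rdname accessors
#' @export
setMethod("resolvedThresholds", "PeakSegments", function(x) x@thresholds)
#' @rdname accessors
#' @export
setMethod("lossHistory", "ContrastFit", function(x) x@history)
#' @rdname accessors
#' @export
setMethod("modelConfig", "ContrastModel", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("modelParams", "ContrastModel", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("peakClass", "ContrastFit", function(x) x@peakClass)
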