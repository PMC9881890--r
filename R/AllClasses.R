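#' PeakSegments: candidate regions, segments and the coverage tensor
#'
#' Container produced by \code{\link{prepareSegments}}. Holds the candidate
#' region set (variable-length intervals surviving threshold-merge-filter),
#' the fixed-length segments extracted from them, and the per-base coverage
#' tensor (segments x replicates x segment length) that is the model input.
#'
#' @slot regions \code{GRanges} of candidate regions; metadata column
#'   \code{region} carries the integer region identifier.
#' @slot segments \code{GRanges} of fixed-length segments; metadata column
#'   \code{region} maps each segment to its parent region.
#' @slot tensor numeric array of dimension \code{S x R x alpha}: per-base
#'   coverage of segment \code{i} in replicate \code{r}.
#' @slot replicates character vector of replicate names (length \code{R}).
#' @slot thresholds named numeric vector of resolved per-chromosome coverage
#'   thresholds (may be empty when a fixed threshold was supplied).
#' @slot alpha integer segment length in bp.
#'
#' @seealso \code{\link{prepareSegments}}, \code{\link{segTensor}},
#'   \code{\link{candidateRegions}}
#' @export
setClass("PeakSegments",
  representation(
    regions    = "GRanges",
    segments   = "GRanges",
    tensor     = "array",
    replicates = "character",
    thresholds = "numeric",
    alpha      = "integer"
  )
)

setValidity("PeakSegments", function(object) {
  msg <- character()
  d <- dim(object@tensor)
  if (length(d) != 3L)
    msg <- c(msg, "tensor must be a 3-d array (segments x replicates x alpha)")
  else {
    if (d[1L] != length(object@segments))
      msg <- c(msg, "tensor rows must match number of segments")
    if (d[2L] != length(object@replicates))
      msg <- c(msg, "tensor replicate dimension must match replicate names")
    if (d[3L] != object@alpha)
      msg <- c(msg, "tensor base dimension must equal alpha")
  }
  if (length(object@segments) &&
      !all(GenomicRanges::width(object@segments) == object@alpha))
    msg <- c(msg, "all segments must have width alpha")
  if (is.null(object@segments$region) ||
      (length(object@segments) &&
       !all(object@segments$region %in% object@regions$region)))
    msg <- c(msg, "every segment must map to a known region id")
  if (length(msg)) msg else TRUE
})

#' ContrastModel: encoder / classifier head / decoder parameters
#'
#' Model state for the contrastive peak-calling network: a dilated 1-d
#' convolutional ResNet encoder mapping an \code{alpha}-bp coverage vector to
#' an \code{embedDim}-dimensional embedding, a two-class softmax head (one
#' hidden layer of width \code{embedDim}) and a decoder symmetric to the
#' encoder that reconstructs the coverage vector.
#'
#' @slot config list of architecture and loss hyperparameters
#'   (see \code{\link{contrastModel}}).
#' @slot params named list of numeric parameter arrays.
#'
#' @seealso \code{\link{contrastModel}}, \code{\link{trainModel}}
#' @export
setClass("ContrastModel",
  representation(config = "list", params = "list")
)

setValidity("ContrastModel", function(object) {
  cfg <- object@config
  need <- c("alpha", "embedDim", "kernelSize", "dilation", "nModules",
            "channels", "tau1", "tau2", "lossWeights")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    return(paste("config missing fields:", paste(miss, collapse = ", ")))
  if (cfg$tau1 <= 0 || cfg$tau2 <= 0) return("temperatures must be positive")
  if (cfg$kernelSize %% 2L == 0L) return("kernelSize must be odd")
  if (cfg$embedDim <= 0L) return("embedDim must be positive")
  if (cfg$alpha %% 2L != 0L) return("alpha must be even")
  TRUE
})

#' ContrastFit: a trained ContrastModel
#'
#' Extends \code{\link{ContrastModel}} with the per-epoch loss history and
#' the resolved identity of the peak class (softmax output column whose
#' probability rises with segment coverage).
#'
#' @slot history data.frame with one row per epoch: \code{epoch}, \code{l1},
#'   \code{l2}, \code{l3}, \code{total}.
#' @slot peakClass integer, 1 or 2; which softmax column is "peak"
#'   (\code{NA} until resolved).
#'
#' @seealso \code{\link{trainModel}}, \code{\link{segmentScores}}
#' @export
setClass("ContrastFit",
  contains = "ContrastModel",
  representation(history = "data.frame", peakClass = "integer"),
  prototype(peakClass = NA_integer_)
)

#' @describeIn PeakSegments display a summary
#' @param object a \code{PeakSegments} object
#' @export
setMethod("show", "PeakSegments", function(object) {
  cat("PeakSegments object\n")
  cat("  candidate regions:", length(object@regions), "\n")
  cat("  segments:         ", length(object@segments),
      sprintf("(alpha = %d bp)", object@alpha), "\n")
  cat("  replicates:       ", length(object@replicates),
      paste0("(", paste(object@replicates, collapse = ", "), ")"), "\n")
  if (length(object@thresholds))
    cat("  thresholds:       ",
        paste(sprintf("%s=%g", names(object@thresholds), object@thresholds),
              collapse = ", "), "\n")
})

#' @describeIn ContrastModel display a summary
#' @param object a \code{ContrastModel} object
#' @export
setMethod("show", "ContrastModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  cat(class(object), "\n")
  cat(sprintf("  input length alpha: %d bp\n", cfg$alpha))
  cat(sprintf("  embedding dim:      %d\n", cfg$embedDim))
  cat(sprintf("  encoder: %d ResNet modules, %d channels, kernel %d, dilation %d\n",
              cfg$nModules, cfg$channels, cfg$kernelSize, cfg$dilation))
  cat(sprintf("  temperatures: tau1 = %g, tau2 = %g\n", cfg$tau1, cfg$tau2))
  cat(sprintf("  parameters: %d\n", np))
  if (is(object, "ContrastFit")) {
    cat(sprintf("  trained epochs: %d\n", nrow(object@history)))
    if (nrow(object@history))
      cat(sprintf("  final loss: %.5f\n",
                  object@history$total[nrow(object@history)]))
    cat(sprintf("  peak class: %s\n",
                ifelse(is.na(object@peakClass), "unresolved",
                       object@peakClass)))
  }
})
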