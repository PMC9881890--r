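#' End-to-end peak calling from coverage tracks
#'
#' Convenience wrapper chaining segment preparation
#' (\code{\link{prepareSegments}}), model construction and training
#' (\code{\link{contrastModel}}, \code{\link{trainModel}}) and peak calling
#' (\code{\link{callPeaks}}) with the default hyperparameters.
#'
#' @inheritParams prepareSegments
#' @param epochs training epochs (default 25)
#' @param batchSize segments per batch (default 256)
#' @param learningRate Adam step size (default 1e-4)
#' @param cutoff peak score cutoff (default 0.5)
#' @param seed integer seed driving parameter initialisation and shuffling
#' @param outBed optional path for the called-peak BED
#' @param verbose print per-epoch losses
#' @param ... further arguments to \code{\link{contrastModel}}
#' @return list with \code{segments} (\code{\link{PeakSegments}}),
#'   \code{fit} (\code{\link{ContrastFit}}) and \code{peaks}
#'   (scored candidate-region \code{GRanges} with \code{isPeak})
#' @export
peakCallingPipeline <- function(tracks, blacklist = NULL, t = "median",
                                alpha = 1000L, mergeGap = 90L,
                                minRegionLen = 100L, quantile = 0.95,
                                epochs = 25L, batchSize = 256L,
                                learningRate = 1e-4, cutoff = 0.5,
                                seed = 1L, outBed = NULL, verbose = FALSE,
                                ...) {
  segs <- prepareSegments(tracks, blacklist = blacklist, t = t,
                          alpha = alpha, mergeGap = mergeGap,
                          minRegionLen = minRegionLen, quantile = quantile)
  model <- contrastModel(alpha = alpha, seed = seed, ...)
  fit <- trainModel(model, segs, epochs = epochs, batchSize = batchSize,
                    learningRate = learningRate, seed = seed,
                    verbose = verbose)
  peaks <- callPeaks(fit, segs, cutoff = cutoff, outBed = outBed)
  list(segments = segs, fit = fit, peaks = peaks)
}
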