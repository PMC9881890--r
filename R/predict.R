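#' Per segment-replicate peak prediction scores
#'
#' The peak prediction score of segment i in replicate r is the trained
#' classifier's peak-class probability for that segment-replicate. Requires
#' the peak-class identity to have been resolved (done automatically at the
#' end of \code{\link{trainModel}}).
#'
#' @param fit a trained \code{\link{ContrastFit}}
#' @param segments a \code{\link{PeakSegments}} object (or S x R x alpha
#'   array)
#' @return numeric matrix of scores in [0,1], replicates x segments
#' @export
setMethod("segmentScores", "ContrastFit", function(fit, segments) {
  if (is.na(fit@peakClass))
    stop("peak class unresolved; train the model (trainModel) or set ",
         "the peak class after calibrating against coverage")
  X <- .checkTensor(fit, segments)
  S <- dim(X)[1L]; R <- dim(X)[2L]
  E <- .encoderF(fit@params, fit@config, .tensorToCube(X))$E
  q <- .headF(fit@params, E)$q
  xi <- .unstackSR(q, S, R)[, , fit@peakClass, drop = FALSE]
  t(matrix(xi, nrow = S, ncol = R))
})

#' Score candidate regions from segment scores
#'
#' A region's score is the arithmetic mean of the peak prediction scores of
#' all its segments over all replicates.
#'
#' @param xi replicates x segments score matrix (from
#'   \code{\link{segmentScores}})
#' @param segmentRegion integer vector mapping each segment (column of
#'   \code{xi}) to its region id
#' @return data.frame with columns \code{region} and \code{score}
#' @export
regionScores <- function(xi, segmentRegion) {
  stopifnot(ncol(xi) == length(segmentRegion))
  if (anyNA(segmentRegion)) stop("every segment must map to a region")
  # every segment carries the same replicate count, so the mean of
  # per-segment replicate means equals the mean over the full score block
  perSeg <- colMeans(xi)
  agg <- tapply(perSeg, segmentRegion, mean)
  data.frame(region = as.integer(names(agg)), score = as.numeric(agg))
}

#' Call peaks from a trained model
#'
#' Scores every candidate region (mean peak-class probability over its
#' segments and all replicates) and calls it a peak when the score reaches
#' \code{cutoff} (inclusive; default 0.5).
#'
#' @param fit a trained \code{\link{ContrastFit}}
#' @param segments a \code{\link{PeakSegments}} object
#' @param cutoff peak score cutoff (default 0.5, inclusive)
#' @param outBed optional path: called peaks are written there as BED with
#'   the score in column 5
#' @return \code{GRanges} of all candidate regions with metadata columns
#'   \code{score} and \code{isPeak}
#' @export
setMethod("callPeaks", "ContrastFit",
function(fit, segments, cutoff = 0.5, outBed = NULL) {
  stopifnot(is(segments, "PeakSegments"))
  xi <- segmentScores(fit, segments)
  rs <- regionScores(xi, segments@segments$region)
  regions <- segments@regions
  m <- match(regions$region, rs$region)
  if (anyNA(m)) stop("candidate region without any segment cannot be scored")
  regions$score <- rs$score[m]
  regions$isPeak <- regions$score >= cutoff
  if (!is.null(outBed)) {
    peaks <- regions[regions$isPeak]
    peaks$name <- sprintf("peak_%d", peaks$region)
    writeBed(peaks, outBed)
  }
  regions
})

#' Reconstructed (denoised) coverage for segments
#'
#' Runs the autoencoder to produce the model's denoised view of each
#' segment's coverage in each replicate, optionally written as one
#' bedGraph per replicate (overlapping segments are averaged base-wise).
#'
#' @param fit a trained \code{\link{ContrastFit}} (an untrained
#'   \code{ContrastModel} wrapped in a fit also works; outputs are then
#'   arbitrary but finite)
#' @param segments a \code{\link{PeakSegments}} object
#' @param outDir optional directory for per-replicate bedGraph output
#' @return S x R x alpha array of reconstructed coverage
#' @export
setMethod("denoisedTracks", "ContrastFit", function(fit, segments,
                                                    outDir = NULL) {
  stopifnot(is(segments, "PeakSegments"))
  X <- segTensor(segments)
  E <- encode(fit, X)
  Mhat <- decode(fit, E)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    segs <- segments@segments
    sl <- GenomeInfoDb::seqlengths(segs)
    for (r in seq_along(segments@replicates)) {
      acc <- lapply(sl, function(L) numeric(L))
      cnt <- lapply(sl, function(L) numeric(L))
      for (i in seq_along(segs)) {
        ch <- as.character(GenomicRanges::seqnames(segs)[i])
        at <- GenomicRanges::start(segs)[i]:GenomicRanges::end(segs)[i]
        acc[[ch]][at] <- acc[[ch]][at] + Mhat[i, r, ]
        cnt[[ch]][at] <- cnt[[ch]][at] + 1
      }
      track <- lapply(names(acc), function(ch) {
        v <- acc[[ch]]
        v[cnt[[ch]] > 0] <- v[cnt[[ch]] > 0] / cnt[[ch]][cnt[[ch]] > 0]
        S4Vectors::Rle(round(v, 4))
      })
      names(track) <- names(acc)
      writeBedGraph(methods::as(track, "RleList"),
                    file.path(outDir, sprintf(
                      "denoised_%s.bedgraph", segments@replicates[r])))
    }
  }
  Mhat
})
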