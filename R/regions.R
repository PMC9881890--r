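#' Genome positions exceeding the coverage threshold in every replicate
#'
#' Step 1 of candidate-region selection: a position is retained iff its
#' coverage is strictly greater than the chromosome's threshold in all
#' replicates.
#'
#' @param tracks list of per-replicate coverage \code{RleList}s
#' @param thresholds named numeric vector of per-chromosome thresholds
#'   (e.g. from \code{\link{chromosomeMedianThresholds}}); chromosomes with
#'   \code{NA} threshold are skipped
#' @return named \code{IRangesList}: per chromosome, the runs of retained
#'   positions (1-based closed in-memory coordinates)
#' @export
retainedPositions <- function(tracks, thresholds) {
  chroms <- names(thresholds)[!is.na(thresholds)]
  out <- lapply(chroms, function(ch) {
    keep <- Reduce(`&`, lapply(tracks, function(tr) tr[[ch]] > thresholds[ch]))
    methods::as(keep, "IRanges")
  })
  names(out) <- chroms
  methods::as(out, "IRangesList")
}

#' Aggregate retained positions into the candidate region set
#'
#' Step 2: contiguous retained positions form raw regions; regions whose
#' gap is at most \code{mergeGap} bp are merged transitively; merged regions
#' strictly longer than \code{minRegionLen} bp survive.
#'
#' @param retained \code{IRangesList} from \code{\link{retainedPositions}}
#' @param mergeGap merge regions separated by at most this many bp
#'   (default 90, the upper end of DNA linker lengths)
#' @param minRegionLen keep regions strictly longer than this (default 100)
#' @return \code{GRanges} of candidate regions with integer \code{region}
#'   identifiers
#' @export
buildRegionSet <- function(retained, mergeGap = 90L, minRegionLen = 100L) {
  grl <- lapply(names(retained), function(ch) {
    merged <- IRanges::reduce(retained[[ch]], min.gapwidth = mergeGap + 1L)
    merged <- merged[IRanges::width(merged) > minRegionLen]
    GenomicRanges::GRanges(rep(ch, length(merged)), merged)
  })
  gr <- suppressWarnings(do.call(c, grl))
  if (length(gr)) gr$region <- seq_along(gr)
  else gr$region <- integer(0)
  gr
}

#' Extract fixed-length segments from candidate regions
#'
#' Steps 3.1-3.2: a region no longer than \code{alpha} bp yields one
#' \code{alpha}-bp segment centred on its midpoint. A longer region is
#' scanned for positions whose replicate-summed coverage reaches the
#' region's \code{quantile} coverage quantile (linear-interpolation
#' estimator, ties included); those positions are merged when separated by
#' at most \code{alpha} bp, and one \code{alpha}-bp segment is centred on
#' each merged cluster's midpoint. Segments running past a chromosome edge
#' are shifted inward to fit.
#'
#' @param regions \code{GRanges} of candidate regions (with \code{region}
#'   ids, see \code{\link{buildRegionSet}})
#' @param mergedTrack replicate-summed coverage \code{RleList} (merged
#'   alignments)
#' @param alpha segment length in bp (even; default 1000)
#' @param quantile coverage quantile defining high-coverage positions
#'   within long regions (default 0.95)
#' @return \code{GRanges} of segments, each of width \code{alpha}, with the
#'   parent \code{region} id
#' @export
extractSegments <- function(regions, mergedTrack, alpha = 1000L,
                            quantile = 0.95) {
  alpha <- as.integer(alpha)
  stopifnot(alpha > 0L, alpha %% 2L == 0L, quantile > 0, quantile < 1)
  half <- alpha %/% 2L
  chromLen <- vapply(mergedTrack, length, integer(1))

  segChrom <- character(0); segStart0 <- integer(0); segRegion <- integer(0)
  for (k in seq_along(regions)) {
    ch <- as.character(GenomicRanges::seqnames(regions)[k])
    s1 <- GenomicRanges::start(regions)[k]
    e1 <- GenomicRanges::end(regions)[k]
    w <- e1 - s1 + 1L
    if (w <= alpha) {
      mids0 <- (s1 - 1L + e1) %/% 2L
    } else {
      v <- as.numeric(IRanges::Views(mergedTrack[[ch]], s1, e1)[[1L]])
      qv <- stats::quantile(v, quantile, names = FALSE, type = 7)
      pos <- which(v >= qv)
      cl <- IRanges::reduce(IRanges::IRanges(pos, pos),
                            min.gapwidth = alpha + 1L)
      # cluster [a, b] (1-based, in-region) -> 0-based genomic [s0+a-1, s0+b)
      a0 <- (s1 - 1L) + IRanges::start(cl) - 1L
      b0 <- (s1 - 1L) + IRanges::end(cl)
      mids0 <- (a0 + b0) %/% 2L
    }
    st0 <- mids0 - half
    len <- unname(chromLen[ch])
    if (is.na(len)) stop("region on chromosome absent from mergedTrack: ", ch)
    if (len < alpha)
      stop("chromosome ", ch, " is shorter than alpha (", alpha, " bp)")
    st0 <- pmin(pmax(st0, 0L), len - alpha)
    st0 <- unique(st0)
    segChrom <- c(segChrom, rep(ch, length(st0)))
    segStart0 <- c(segStart0, st0)
    segRegion <- c(segRegion, rep(regions$region[k], length(st0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = segChrom,
    ranges = IRanges::IRanges(start = segStart0 + 1L, width = alpha)
  )
  gr$region <- segRegion
  gr
}

#' Assemble the segment coverage tensor
#'
#' Entry (i, r, b) is the replicate-r coverage at base b of segment i.
#'
#' @param segments \code{GRanges} of fixed-length segments
#' @param tracks list of per-replicate coverage \code{RleList}s
#' @return numeric array of dimension \code{S x R x alpha}
#' @export
assembleSegmentTensor <- function(segments, tracks) {
  S <- length(segments)
  R <- length(tracks)
  if (S == 0L) stop("no segments to assemble")
  alpha <- unique(GenomicRanges::width(segments))
  if (length(alpha) != 1L) stop("segments must share a single length")
  tens <- array(0, dim = c(S, R, alpha))
  chs <- as.character(GenomicRanges::seqnames(segments))
  st <- GenomicRanges::start(segments)
  en <- GenomicRanges::end(segments)
  for (r in seq_len(R)) {
    tr <- tracks[[r]]
    for (ch in unique(chs)) {
      i <- which(chs == ch)
      if (any(en[i] > length(tr[[ch]]) | st[i] < 1L))
        stop("segment outside chromosome bounds on ", ch)
      tens[i, r, ] <- methods::as(
        IRanges::Views(tr[[ch]], st[i], en[i]), "matrix")
    }
  }
  tens
}

#' Candidate-region and segment preparation pipeline
#'
#' Runs the full selection procedure: resolve per-chromosome coverage
#' thresholds, retain positions exceeding them in every replicate, merge
#' and filter into candidate regions, extract fixed-length segments from
#' the replicate-summed coverage, remove blacklisted segments, and build
#' the segment coverage tensor.
#'
#' @param tracks named list of per-replicate coverage \code{RleList}s (one
#'   element per replicate; names become replicate names)
#' @param blacklist optional \code{GRanges} of excluded intervals; any
#'   segment overlapping one by >= 1 bp is removed
#' @param t coverage threshold: \code{"median"} (default; chromosome-wise
#'   minimum-of-replicate-medians), a single number applied to all
#'   chromosomes, or a named per-chromosome numeric vector. Retention is
#'   strict (coverage > t).
#' @param alpha segment length in bp (default 1000)
#' @param mergeGap region merge gap in bp (default 90)
#' @param minRegionLen minimum region length in bp, strict (default 100)
#' @param quantile within-region coverage quantile for long regions
#'   (default 0.95)
#' @param thresholdsFile optional path: resolved thresholds are written
#'   there as a two-column TSV for reproducibility
#' @return a \code{\link{PeakSegments}} object
#' @export
prepareSegments <- function(tracks, blacklist = NULL, t = "median",
                            alpha = 1000L, mergeGap = 90L,
                            minRegionLen = 100L, quantile = 0.95,
                            thresholdsFile = NULL) {
  if (is.null(names(tracks)))
    names(tracks) <- paste0("rep", seq_along(tracks))
  chroms <- names(tracks[[1L]])
  if (identical(t, "median")) {
    th <- chromosomeMedianThresholds(tracks)
  } else if (is.numeric(t) && length(t) == 1L && is.null(names(t))) {
    th <- stats::setNames(rep(as.numeric(t), length(chroms)), chroms)
  } else if (is.numeric(t) && !is.null(names(t))) {
    miss <- setdiff(chroms, names(t))
    if (length(miss))
      stop("no threshold supplied for chromosome(s): ",
           paste(miss, collapse = ", "))
    th <- t[chroms]
  } else stop("t must be \"median\", a number, or a named numeric vector")
  if (!is.null(thresholdsFile))
    write.table(data.frame(chrom = names(th), threshold = th),
                thresholdsFile, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)

  retained <- retainedPositions(tracks, th)
  regions <- buildRegionSet(retained, mergeGap = mergeGap,
                            minRegionLen = minRegionLen)
  if (!length(regions))
    stop("no candidate regions survive selection; lower the threshold t")
  merged <- Reduce(`+`, tracks)
  segs <- extractSegments(regions, merged, alpha = alpha, quantile = quantile)
  segs <- removeBlacklisted(segs, blacklist)
  if (!length(segs))
    stop("all segments removed by the blacklist")
  keptRegions <- regions[regions$region %in% segs$region]
  tens <- assembleSegmentTensor(segs, tracks)
  sl <- vapply(tracks[[1L]], length, integer(1))
  GenomeInfoDb::seqlengths(segs) <- sl[GenomeInfoDb::seqlevels(segs)]
  GenomeInfoDb::seqlengths(keptRegions) <-
    sl[GenomeInfoDb::seqlevels(keptRegions)]
  methods::new("PeakSegments",
    regions = keptRegions, segments = segs, tensor = tens,
    replicates = names(tracks), thresholds = th[!is.na(th)],
    alpha = as.integer(alpha))
}
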