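#' Simulate multi-replicate coverage with planted peaks
#'
#' Generates per-replicate per-base fragment-coverage tracks over a toy
#' genome with non-overlapping enriched regions (planted peaks), matching
#' truth intervals, replicate-correlated peak intensities and
#' negative-binomial background noise. Background bases draw independent
#' negative-binomial counts with mean \code{backgroundRate}; each peak
#' draws a latent gamma intensity multiplier per replicate, a fraction
#' \code{replicateCorrelation} of which is shared across replicates, and
#' peak bases draw Poisson counts around
#' \code{backgroundRate * peakEnrichment * multiplier} (a gamma-mixed
#' Poisson, i.e. negative binomial around the shared latent intensity).
#' Fully reproducible from \code{seed}.
#'
#' @param genomeLength total genome size in bp (default 200000)
#' @param nChroms number of equally sized chromosomes (default 2)
#' @param replicates number of replicates R (default 2)
#' @param nPeaks number of planted peaks (default 100)
#' @param peakLenRange min/max peak length in bp (default c(300, 800))
#' @param peakEnrichment mean coverage multiplier inside peaks (default 8)
#' @param backgroundRate mean background coverage per base (default 0.5)
#' @param replicateCorrelation fraction of each peak's latent intensity
#'   shared across replicates, in [0,1] (default 0.8)
#' @param noiseDispersion negative-binomial size parameter; larger is less
#'   overdispersed (default 10)
#' @param seed integer seed
#' @return list with elements \code{tracks} (per-replicate \code{RleList}),
#'   \code{truth} (\code{GRanges} of planted peaks), \code{seqlengths} and
#'   \code{config}
#' @export
simulateFixture <- function(genomeLength = 200000L, nChroms = 2L,
                            replicates = 2L, nPeaks = 100L,
                            peakLenRange = c(300L, 800L),
                            peakEnrichment = 8, backgroundRate = 0.5,
                            replicateCorrelation = 0.8,
                            noiseDispersion = 10, seed = 1L) {
  stopifnot(backgroundRate >= 0, peakEnrichment >= 0,
            replicateCorrelation >= 0, replicateCorrelation <= 1,
            noiseDispersion > 0, nChroms >= 1L)
  set.seed(seed)
  chromLen <- rep(genomeLength %/% nChroms, nChroms)
  names(chromLen) <- paste0("chr", seq_len(nChroms))

  # spread peaks across chromosomes proportionally, place without overlap
  alloc <- rep(seq_len(nChroms), length.out = nPeaks)
  truth <- GenomicRanges::GRanges()
  for (ci in seq_len(nChroms)) {
    k <- sum(alloc == ci)
    if (k == 0L) next
    lens <- sample(seq(peakLenRange[1L], peakLenRange[2L]), k,
                   replace = TRUE)
    placed <- IRanges::IRanges()
    tries <- 0L
    while (length(placed) < k) {
      need <- k - length(placed)
      st <- sample.int(chromLen[ci] - max(lens), need, replace = TRUE)
      cand <- IRanges::IRanges(st, width = lens[seq_len(need) +
                                                  length(placed)])
      # accept candidates one by one to keep determinism simple
      for (j in seq_along(cand)) {
        if (length(placed) == k) break
        if (!IRanges::overlapsAny(cand[j], placed))
          placed <- c(placed, cand[j])
      }
      tries <- tries + 1L
      if (tries > 200L)
        stop("could not place ", k, " non-overlapping peaks; ",
             "use fewer or shorter peaks")
    }
    gr <- GenomicRanges::GRanges(names(chromLen)[ci], sort(placed))
    truth <- suppressWarnings(c(truth, gr))
  }
  GenomeInfoDb::seqlengths(truth) <- chromLen[GenomeInfoDb::seqlevels(truth)]
  truth <- sort(truth)

  rho <- replicateCorrelation
  kdisp <- noiseDispersion
  # per-base latent gamma intensity inside peaks, shared across replicates:
  # replicate counts are gamma-mixed Poisson (negative binomial) around it
  sharedG <- lapply(seq_along(truth), function(j)
    rgamma(GenomicRanges::width(truth)[j], shape = kdisp, rate = kdisp))
  tracks <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    trk <- lapply(names(chromLen), function(ch) {
      L <- chromLen[[ch]]
      v <- rnbinom(L, size = kdisp, mu = backgroundRate)
      sel <- which(as.character(GenomicRanges::seqnames(truth)) == ch)
      for (j in sel) {
        at <- GenomicRanges::start(truth)[j]:GenomicRanges::end(truth)[j]
        own <- rgamma(length(at), shape = kdisp, rate = kdisp)
        mult <- rho * sharedG[[j]] + (1 - rho) * own
        v[at] <- rpois(length(at),
                       backgroundRate * peakEnrichment * mult)
      }
      S4Vectors::Rle(as.integer(v))
    })
    names(trk) <- names(chromLen)
    tracks[[r]] <- methods::as(trk, "RleList")
  }
  names(tracks) <- paste0("rep", seq_len(replicates))
  list(tracks = tracks, truth = truth, seqlengths = chromLen,
       config = list(genomeLength = genomeLength, nChroms = nChroms,
                     replicates = replicates, nPeaks = nPeaks,
                     peakLenRange = peakLenRange,
                     peakEnrichment = peakEnrichment,
                     backgroundRate = backgroundRate,
                     replicateCorrelation = replicateCorrelation,
                     noiseDispersion = noiseDispersion, seed = seed))
}

#' Region-level precision and recall against planted truth
#'
#' A call is a true positive iff it overlaps a planted peak by at least
#' 1 bp; a planted peak is recovered iff at least one call overlaps it.
#'
#' @param calls \code{GRanges} of called peaks
#' @param truth \code{GRanges} of planted peaks
#' @return list with \code{precision}, \code{recall}, \code{f1}
#' @export
fixtureTruthMetrics <- function(calls, truth) {
  recall <- if (length(truth))
    mean(IRanges::overlapsAny(truth, calls, minoverlap = 1L)) else NA_real_
  precision <- if (length(calls))
    mean(IRanges::overlapsAny(calls, truth, minoverlap = 1L)) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Simulate proper read pairs and write them as SAM
#'
#' Generates paired-end fragments along a toy genome (uniform background
#' plus optional enrichment inside supplied peaks) and writes them as a
#' valid SAM file of properly paired records, so alignment-based coverage
#' extraction can be tested end to end without real data.
#'
#' @param seqlengths named integer vector of chromosome lengths
#' @param nFragments total number of fragments
#' @param fragLenRange min/max fragment length (default c(100, 300))
#' @param peaks optional \code{GRanges}; fragment midpoints are drawn
#'   preferentially from peaks with weight \code{enrichment}
#' @param enrichment sampling weight of peak bases (default 8)
#' @param readLen read length of each mate (default 50)
#' @param seed integer seed
#' @return \code{GRanges} of fragment spans (invisibly carries no file);
#'   use \code{\link{writeSam}} to serialise
#' @export
simulateFragments <- function(seqlengths, nFragments,
                              fragLenRange = c(100L, 300L), peaks = NULL,
                              enrichment = 8, readLen = 50L, seed = 1L) {
  set.seed(seed)
  chroms <- names(seqlengths)
  w <- as.numeric(seqlengths)
  ci <- sample(seq_along(chroms), nFragments, replace = TRUE,
               prob = w / sum(w))
  lens <- sample(seq(fragLenRange[1L], fragLenRange[2L]), nFragments,
                 replace = TRUE)
  starts <- integer(nFragments)
  for (i in seq_len(nFragments)) {
    L <- seqlengths[[ci[i]]]
    maxStart <- L - lens[i] + 1L
    if (!is.null(peaks)) {
      pk <- peaks[as.character(GenomicRanges::seqnames(peaks)) ==
                    chroms[ci[i]]]
      if (length(pk) && runif(1) < min(
        1, enrichment * sum(GenomicRanges::width(pk)) / L)) {
        j <- sample.int(length(pk), 1L)
        starts[i] <- sample(
          max(1L, GenomicRanges::start(pk)[j] - lens[i] %/% 2L):
            min(maxStart, GenomicRanges::end(pk)[j]), 1L)
        next
      }
    }
    starts[i] <- sample.int(maxStart, 1L)
  }
  gr <- GenomicRanges::GRanges(chroms[ci],
                               IRanges::IRanges(starts, width = lens))
  GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  sort(gr)
}

#' @rdname simulateFragments
#' @param fragments \code{GRanges} of fragment spans (with seqlengths set)
#' @param path output SAM path
#' @export
writeSam <- function(fragments, path, readLen = 50L) {
  sl <- GenomeInfoDb::seqlengths(fragments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl), con)
  ch <- as.character(GenomicRanges::seqnames(fragments))
  st <- GenomicRanges::start(fragments)
  en <- GenomicRanges::end(fragments)
  w <- GenomicRanges::width(fragments)
  rl <- pmin(readLen, w)
  matePos <- en - rl + 1L
  seqstr <- vapply(rl, function(n) strrep("A", n), character(1))
  qualstr <- vapply(rl, function(n) strrep("I", n), character(1))
  for (i in seq_along(fragments)) {
    qn <- sprintf("frag%06d", i)
    writeLines(sprintf(
      "%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
      qn, ch[i], st[i], rl[i], matePos[i], w[i], seqstr[i], qualstr[i]),
      con)
    writeLines(sprintf(
      "%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
      qn, ch[i], matePos[i], rl[i], st[i], -w[i], seqstr[i], qualstr[i]),
      con)
  }
  invisible(path)
}
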