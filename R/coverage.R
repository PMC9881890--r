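#' Per-base fragment coverage from a paired-end alignment file
#'
#' Computes, for every base of every chromosome, the number of sequenced
#' fragments whose span covers that base (the \code{bedtools genomecov -pc}
#' semantics): each properly paired read pair contributes once, over the
#' full fragment span from the leftmost mate start to the rightmost mate
#' end. Unmapped, secondary, supplementary and improperly paired records are
#' skipped and their counts reported via \code{message()}.
#'
#' @param file path to a coordinate-sorted BAM or SAM file (SAM files are
#'   converted on the fly)
#' @param chromSizes optional named integer vector of chromosome lengths;
#'   defaults to the alignment header. Records on chromosomes absent from
#'   \code{chromSizes} raise an error naming the chromosome.
#' @param skipDuplicates skip duplicate-flagged records (duplicate marking
#'   is normally done upstream; off by default)
#' @return named \code{RleList} of integer coverage, one per chromosome in
#'   \code{chromSizes}
#' @examples
#' \dontrun{cov <- fragmentCoverage("rep1.bam")}
#' @export
fragmentCoverage <- function(file, chromSizes = NULL, skipDuplicates = FALSE) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(file)[[1L]]$targets
  if (is.null(chromSizes)) {
    if (!length(hdr))
      stop("alignment header of '", file, "' declares no chromosome ",
           "lengths; supply chromSizes")
    chromSizes <- hdr
  }
  p <- Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "isize"))
  rec <- Rsamtools::scanBam(file, param = p)[[1L]]
  flag <- rec$flag
  n <- length(flag)

  bit <- function(mask) bitwAnd(flag, mask) != 0L
  unmapped <- bit(0x4L)
  secondary <- bit(0x100L) | bit(0x800L)
  notProper <- !bit(0x2L)
  dup <- bit(0x400L)
  skip <- unmapped | secondary | notProper
  if (skipDuplicates) skip <- skip | dup
  nSkip <- c(unmapped = sum(unmapped), secondary = sum(secondary),
             improper = sum(notProper & !unmapped & !secondary))
  if (any(nSkip > 0L))
    message("fragmentCoverage: skipped ", sum(skip), " record(s) (",
            paste(sprintf("%s=%d", names(nSkip), nSkip), collapse = ", "),
            ")")
  # leftmost mate of each proper pair carries a positive TLEN; counting it
  # once yields one full fragment span per pair
  use <- !skip & !is.na(rec$isize) & rec$isize > 0L & !is.na(rec$pos)
  chrom <- as.character(rec$rname[use])
  unknown <- setdiff(unique(chrom), names(chromSizes))
  if (length(unknown))
    stop("fragmentCoverage: record(s) on unknown chromosome '",
         unknown[1L], "'")
  starts <- rec$pos[use]
  ends <- starts + rec$isize[use] - 1L
  out <- lapply(names(chromSizes), function(ch) {
    i <- which(chrom == ch)
    len <- unname(chromSizes[ch])
    if (!length(i)) return(S4Vectors::Rle(0L, len))
    if (any(ends[i] > len))
      stop("fragmentCoverage: fragment past end of ", ch)
    IRanges::coverage(IRanges::IRanges(starts[i], ends[i]), width = len)
  })
  names(out) <- names(chromSizes)
  methods::as(out, "RleList")
}

#' Per-chromosome median-based coverage thresholds
#'
#' For each chromosome, computes each replicate's median coverage over
#' positions with non-zero coverage, then returns the minimum of these
#' medians across replicates as the chromosome's threshold. Even-count
#' medians use the midpoint convention (average of the two central values),
#' so thresholds may be non-integer. A chromosome with all-zero coverage in
#' some replicate has no defined threshold: a warning is emitted and
#' \code{NA} returned for it (it is excluded from downstream selection).
#'
#' @param tracks list of per-replicate coverage \code{RleList}s, all sharing
#'   the same chromosomes
#' @return named numeric vector of thresholds, \code{NA} where undefined
#' @export
chromosomeMedianThresholds <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  chroms <- names(tracks[[1L]])
  for (tr in tracks)
    if (!identical(sort(names(tr)), sort(chroms)))
      stop("all replicates must cover the same chromosomes")
  th <- vapply(chroms, function(ch) {
    med <- vapply(tracks, function(tr) .nonzeroMedian(tr[[ch]]), numeric(1))
    if (anyNA(med)) NA_real_ else min(med)
  }, numeric(1))
  if (anyNA(th))
    warning("no non-zero coverage on chromosome(s) ",
            paste(chroms[is.na(th)], collapse = ", "),
            " in some replicate; excluded from selection")
  th
}

# weighted median of the non-zero run values of an Rle (midpoint convention
# for even counts), without expanding the run-length encoding
.nonzeroMedian <- function(r) {
  rv <- as.numeric(S4Vectors::runValue(r))
  rl <- S4Vectors::runLength(r)
  keep <- rv > 0
  rv <- rv[keep]
  rl <- as.numeric(rl[keep])
  if (!length(rv)) return(NA_real_)
  o <- order(rv)
  rv <- rv[o]
  cum <- cumsum(rl[o])
  n <- cum[length(cum)]
  at <- function(k) rv[which(cum >= k)[1L]]
  k <- (n + 1) / 2
  (at(floor(k)) + at(ceiling(k))) / 2
}

#' Remove intervals overlapping a blacklist
#'
#' Drops every interval that overlaps any blacklist interval by at least
#' 1 bp; adjacency (half-open touching) is not overlap. With an empty
#' blacklist the input is returned unchanged. The operation is idempotent.
#'
#' @param gr \code{GRanges} of intervals to filter
#' @param blacklist \code{GRanges} of excluded intervals (may be empty or
#'   \code{NULL})
#' @return the retained subset of \code{gr}
#' @export
removeBlacklisted <- function(gr, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0L) return(gr)
  gr[!IRanges::overlapsAny(gr, blacklist, minoverlap = 1L)]
}
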