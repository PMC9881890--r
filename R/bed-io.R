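#' Read a BED file of genomic intervals
#'
#' Reads a BED file (>= 3 columns, 0-based half-open text coordinates) into
#' a \code{GRanges} (1-based closed, the in-memory convention). Column 4, if
#' present, is stored as \code{name} and column 5 as numeric \code{score}.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path path to a BED file (plain text or gzipped)
#' @return \code{GRanges} with optional \code{name} and \code{score} columns
#' @seealso \code{\link{writeBed}}, \code{\link{readLabeledBed}}
#' @export
readBed <- function(path) {
  fields <- .readBedFields(path, minCols = 3L)
  gr <- GenomicRanges::GRanges(
    seqnames = fields$chrom,
    ranges   = IRanges::IRanges(start = fields$start + 1L, end = fields$end)
  )
  if (!is.null(fields$name)) gr$name <- fields$name
  if (!is.null(fields$score)) gr$score <- fields$score
  gr
}

#' Read a BED file with a binary label column
#'
#' Evaluation labels are BED intervals whose 4th column is the binary truth
#' label (1 = positive, 0 = negative).
#'
#' @param path path to a 4+ column BED file
#' @return \code{GRanges} with integer \code{label} column
#' @export
readLabeledBed <- function(path) {
  fields <- .readBedFields(path, minCols = 4L)
  lab <- suppressWarnings(as.integer(fields$name))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad))
    stop("labeled BED '", path, "': line ", fields$line[bad[1L]],
         ": label column must be 0 or 1")
  gr <- GenomicRanges::GRanges(
    seqnames = fields$chrom,
    ranges   = IRanges::IRanges(start = fields$start + 1L, end = fields$end)
  )
  gr$label <- lab
  gr
}

.readBedFields <- function(path, minCols = 3L) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(list(chrom = character(), start = integer(), end = integer(),
                line = integer()))
  parts <- strsplit(lines, "[ \t]+")
  ncols <- lengths(parts)
  if (any(ncols < minCols))
    stop("BED '", path, "': line ", lineNo[which(ncols < minCols)[1L]],
         ": expected at least ", minCols, " columns")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED '", path, "': line ", lineNo[bad[1L]],
         ": start/end must be integers")
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop("BED '", path, "': line ", lineNo[bad[1L]],
         ": require 0 <= start < end")
  out <- list(chrom = chrom, start = start, end = end, line = lineNo)
  if (all(ncols >= 4L))
    out$name <- vapply(parts, `[[`, character(1), 4L)
  if (all(ncols >= 5L))
    out$score <- suppressWarnings(
      as.numeric(vapply(parts, `[[`, character(1), 5L)))
  out
}

#' Write intervals to a BED file
#'
#' Writes a \code{GRanges} as BED text (0-based half-open). A \code{name}
#' metadata column becomes column 4 and a numeric \code{score} column (kept
#' on its native scale, e.g. peak scores in [0,1]) becomes column 5.
#'
#' @param gr \code{GRanges} to write
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  hasScore <- !is.null(gr$score)
  if (!is.null(gr$name)) df$name <- gr$name
  else if (hasScore) df$name <- sprintf("region_%d", seq_along(gr))
  if (hasScore) df$score <- format(gr$score, digits = 15, trim = TRUE,
                                   scientific = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Reads a 4-column bedGraph (chrom, start, end, value; 0-based half-open)
#' into a per-chromosome run-length encoded coverage list. Runs must be
#' disjoint within a chromosome; bases outside any run get value 0.
#'
#' @param path path to a bedGraph file
#' @param seqlengths optional named integer vector of chromosome lengths;
#'   defaults to the largest end coordinate seen per chromosome
#' @return named \code{RleList}, one run-length vector per chromosome
#' @seealso \code{\link{writeBedGraph}}
#' @export
readBedGraph <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("bedGraph '", path, "': no data lines")
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) < 4L))
    stop("bedGraph '", path, "': line ",
         lineNo[which(lengths(parts) < 4L)[1L]], ": expected 4 columns")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(val) | start < 0L |
                 start >= end)
  if (length(bad))
    stop("bedGraph '", path, "': line ", lineNo[bad[1L]], ": malformed run")
  chroms <- unique(chrom)
  if (is.null(seqlengths)) {
    seqlengths <- vapply(chroms, function(ch) max(end[chrom == ch]),
                         integer(1))
  } else {
    missing <- setdiff(chroms, names(seqlengths))
    if (length(missing))
      stop("bedGraph '", path, "': chromosome '", missing[1L],
           "' not in seqlengths")
  }
  out <- lapply(names(seqlengths), function(ch) {
    i <- which(chrom == ch)
    if (!length(i))
      return(S4Vectors::Rle(0, unname(seqlengths[ch])))
    o <- i[order(start[i])]
    if (any(start[o][-1L] < end[o][-length(o)]))
      stop("bedGraph '", path, "': overlapping runs on ", ch)
    if (max(end[o]) > seqlengths[ch])
      stop("bedGraph '", path, "': run past end of ", ch)
    cov <- numeric(seqlengths[ch])
    for (j in o) cov[(start[j] + 1L):end[j]] <- val[j]
    S4Vectors::Rle(cov)
  })
  names(out) <- names(seqlengths)
  methods::as(out, "RleList")
}

#' Write a coverage track as bedGraph
#'
#' Writes every run, including zero runs (the \code{-bga} style), in
#' 0-based half-open text coordinates.
#'
#' @param track named \code{RleList} (or plain list of \code{Rle}) of
#'   per-chromosome coverage
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl)
    starts <- ends - rl
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts, ends,
                       format(rv, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}
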