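sq <- "@SQ\tSN:chr1\tLN:1000"

pairLines <- function(id, chrom, fragStart0, fragLen, readLen = 20L) {
  # 0-based fragment [fragStart0, fragStart0 + fragLen)
  p1 <- fragStart0 + 1L
  p2 <- fragStart0 + fragLen - readLen + 1L
  s <- strrep("A", readLen); q <- strrep("I", readLen)
  c(sprintf("%s\t99\tchr1\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
            id, p1, readLen, p2, fragLen, s, q),
    sprintf("%s\t147\tchr1\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
            id, p2, readLen, p1, -fragLen, s, q))
}

test_that("fragment coverage counts each proper pair once over its span", {
  sam <- tempfile(fileext = ".sam")

  # no alignments -> all-zero track
  writeHandSam(sam, sq, character(0))
  cov <- fragmentCoverage(sam)
  expect_equal(sum(cov$chr1), 0)
  expect_equal(length(cov$chr1), 1000L)

  # one pair with fragment span [10, 60): 1 on the span, 0 elsewhere
  writeHandSam(sam, sq, pairLines("f1", "chr1", 10L, 50L))
  v <- as.integer(fragmentCoverage(sam)$chr1)
  expect_equal(v[11:60], rep(1L, 50))
  expect_equal(sum(v), 50L)

  # pairs [10,60) and [40,90): 2 on [40,60), 1 on [10,40) and [60,90)
  writeHandSam(sam, sq, c(pairLines("f1", "chr1", 10L, 50L),
                          pairLines("f2", "chr1", 40L, 50L)))
  v <- as.integer(fragmentCoverage(sam)$chr1)
  expect_equal(v[41:60], rep(2L, 20))
  expect_equal(v[11:40], rep(1L, 30))
  expect_equal(v[61:90], rep(1L, 30))
  expect_equal(v[91:100], rep(0L, 10))
})

test_that("improper records are skipped with a reported count", {
  sam <- tempfile(fileext = ".sam")
  unpaired <- sprintf("u1\t0\tchr1\t%d\t60\t20M\t*\t0\t0\t%s\t%s",
                      501L, strrep("A", 20), strrep("I", 20))
  writeHandSam(sam, sq, c(pairLines("f1", "chr1", 10L, 50L), unpaired))
  expect_message(cov <- fragmentCoverage(sam), "skipped 1 record")
  expect_equal(sum(cov$chr1), 50)
})

test_that("coverage matches a naive per-fragment accumulation oracle", {
  set.seed(31)
  sl <- c(chrA = 5000L, chrB = 3000L)
  frags <- simulateFragments(sl, nFragments = 80L,
                             fragLenRange = c(60L, 200L), seed = 5)
  sam <- tempfile(fileext = ".sam")
  writeSam(frags, sam, readLen = 30L)
  cov <- fragmentCoverage(sam)
  for (ch in names(sl)) {
    i <- as.character(GenomicRanges::seqnames(frags)) == ch
    oracle <- naiveFragmentCoverage(GenomicRanges::start(frags)[i],
                                    GenomicRanges::end(frags)[i],
                                    sl[[ch]])
    expect_equal(as.integer(cov[[ch]]), oracle)
  }
  # coverage conservation: total bases covered == total fragment length
  expect_equal(sum(sapply(cov, sum)), sum(GenomicRanges::width(frags)))
})

test_that("median thresholds use nonzero positions, midpoints and the
           minimum across replicates", {
  tr1 <- vectorsToTrack(list(chr1 = c(0L, 1L, 2L, 3L, 0L)))
  expect_equal(unname(chromosomeMedianThresholds(list(tr1))["chr1"]), 2)

  # midpoint convention on even counts: {2, 4} -> 3
  tr2 <- vectorsToTrack(list(chr1 = c(2L, 0L, 4L)))
  expect_equal(unname(chromosomeMedianThresholds(list(tr2))["chr1"]), 3)

  # minimum of per-replicate medians: medians 4 and 2 -> threshold 2
  trA <- vectorsToTrack(list(chr1 = rep(4L, 10)))
  trB <- vectorsToTrack(list(chr1 = rep(c(2L, 0L), 5)))
  expect_equal(unname(chromosomeMedianThresholds(list(trA, trB))["chr1"]), 2)

  # all-zero chromosome in one replicate: warning and NA
  trC <- vectorsToTrack(list(chr1 = rep(0L, 10)))
  expect_warning(th <- chromosomeMedianThresholds(list(trA, trC)),
                 "excluded")
  expect_true(is.na(th["chr1"]))
})

test_that("blacklist removal drops >= 1 bp overlaps but not adjacency", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)) # [100,200)
  blOverlap <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  blAdjacent <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  expect_length(removeBlacklisted(gr, blOverlap), 0L)   # 1 bp overlap
  expect_length(removeBlacklisted(gr, blAdjacent), 1L)  # touching, kept
  expect_identical(removeBlacklisted(gr, NULL), gr)
  expect_identical(removeBlacklisted(gr, GenomicRanges::GRanges()), gr)

  # idempotent and order-invariant
  set.seed(7)
  many <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(1000, 30), width = sample(50, 30, TRUE)))
  bl <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(1000, 5), width = 80))
  once <- removeBlacklisted(many, bl)
  expect_identical(removeBlacklisted(once, bl), once)
  shuf <- removeBlacklisted(many[sample(length(many))], bl)
  expect_identical(sort(shuf), sort(once))
})

test_that("BED round trips, scores survive, malformed lines are located", {
  gr <- GenomicRanges::GRanges("chr2",
    IRanges::IRanges(c(1, 501, 901), c(100, 600, 1000)))
  gr$name <- c("a", "b", "c")
  gr$score <- c(0.25, 0.5, 0.999)
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$score, gr$score)

  writeLines(c("chr1\t0\t100", "chr1\t200"), f)
  expect_error(readBed(f), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\t300\t200\tx"), f)
  expect_error(readBed(f), "line 2")

  writeLines(c("chr1\t0\t100\t1", "chr1\t500\t700\t0"), f)
  lab <- readLabeledBed(f)
  expect_equal(lab$label, c(1L, 0L))
  writeLines("chr1\t0\t100\tpositive", f)
  expect_error(readLabeledBed(f), "label")
})

test_that("bedGraph runs are half-open, disjoint and round trip", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t5\t3", f)
  cov <- readBedGraph(f, seqlengths = c(chr1 = 10L))
  expect_equal(as.numeric(cov$chr1), c(rep(3, 5), rep(0, 5)))

  writeLines(c("chr1\t0\t5\t3", "chr1\t3\t8\t1"), f)
  expect_error(readBedGraph(f, seqlengths = c(chr1 = 10L)), "overlapping")

  tr <- vectorsToTrack(list(chr1 = c(0L, 0L, 2L, 2L, 1L),
                            chr2 = c(5L, 5L, 5L, 0L, 0L)))
  writeBedGraph(tr, f)
  back <- readBedGraph(f, seqlengths = c(chr1 = 5L, chr2 = 5L))
  expect_equal(lapply(back, as.numeric), lapply(tr, as.numeric))
})
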