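test_that("positions must exceed the threshold in every replicate", {
  v1 <- integer(300); v1[101:160] <- 3L
  v2 <- integer(300); v2[101:160] <- 3L; v2[130] <- 1L
  tr1 <- vectorsToTrack(list(chr1 = v1))
  tr2 <- vectorsToTrack(list(chr1 = v2))

  ret <- retainedPositions(list(tr1, tr1), c(chr1 = 2))
  expect_equal(as.data.frame(ret$chr1)[, c("start", "end")],
               data.frame(start = 101L, end = 160L))

  # one replicate dipping to 1 at a position drops that position
  ret <- retainedPositions(list(tr1, tr2), c(chr1 = 2))
  expect_equal(IRanges::start(ret$chr1), c(101L, 131L))
  expect_equal(IRanges::end(ret$chr1), c(129L, 160L))

  # threshold above the global maximum leaves nothing
  ret <- retainedPositions(list(tr1), c(chr1 = 99))
  expect_length(ret$chr1, 0L)
})

test_that("retained bases are non-increasing in the threshold", {
  set.seed(12)
  tr <- vectorsToTrack(list(chr1 = rpois(2000, 2)))
  prev <- Inf
  for (t in c(0, 1, 2, 3, 5)) {
    n <- sum(IRanges::width(retainedPositions(list(tr), c(chr1 = t))$chr1))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("region building merges within the gap and keeps long regions", {
  # runs [100,200) and [250,300): gap 50 <= 90 -> merged [100,300)
  ret <- methods::as(list(chr1 = IRanges::IRanges(c(101L, 251L),
                                                  c(200L, 300L))),
                     "IRangesList")
  regs <- buildRegionSet(ret)
  expect_equal(GenomicRanges::start(regs), 101L)
  expect_equal(GenomicRanges::end(regs), 300L)

  # a 90 bp region is not longer than 100 bp: excluded; 101 bp survives
  ret <- methods::as(list(chr1 = IRanges::IRanges(1L, 90L),
                          chr2 = IRanges::IRanges(1L, 101L)),
                     "IRangesList")
  regs <- buildRegionSet(ret)
  expect_equal(as.character(GenomicRanges::seqnames(regs)), "chr2")

  # gap 250 > 90: two separate regions
  ret <- methods::as(list(chr1 = IRanges::IRanges(c(1L, 401L),
                                                  c(150L, 600L))),
                     "IRangesList")
  expect_length(buildRegionSet(ret), 2L)
})

test_that("segment extraction centres on midpoints and clamps at edges", {
  track <- vectorsToTrack(list(chr1 = rep(1L, 10000)))

  # region [4500, 4900): midpoint 4700, alpha 1000 -> [4200, 5200)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4501, 4900))
  reg$region <- 1L
  seg <- extractSegments(reg, track, alpha = 1000L)
  expect_equal(GenomicRanges::start(seg) - 1L, 4200L)
  expect_equal(GenomicRanges::end(seg), 5200L)

  # region of length exactly alpha: the identical interval comes back
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 3000))
  reg$region <- 1L
  seg <- extractSegments(reg, track, alpha = 1000L)
  expect_equal(GenomicRanges::start(seg), 2001L)
  expect_equal(GenomicRanges::end(seg), 3000L)

  # long region with two high-coverage clusters > alpha apart: two segments
  v <- rep(1L, 10000)
  v[451:550] <- 50L; v[2451:2550] <- 50L # 0-based [450,550) and [2450,2550)
  track2 <- vectorsToTrack(list(chr1 = v))
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3000))
  reg$region <- 1L
  seg <- extractSegments(reg, track2, alpha = 1000L)
  expect_length(seg, 2L)
  expect_equal(GenomicRanges::start(seg) - 1L, c(0L, 2000L))

  # a segment that would start before the chromosome start is shifted in
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 250))
  reg$region <- 1L
  seg <- extractSegments(reg, track, alpha = 1000L)
  expect_equal(GenomicRanges::start(seg), 1L)
  expect_equal(GenomicRanges::width(seg), 1000L)
})

test_that("the segment tensor equals direct per-base lookups", {
  set.seed(9)
  vl1 <- list(chr1 = rpois(4000, 2), chr2 = rpois(4000, 1))
  vl2 <- list(chr1 = rpois(4000, 2), chr2 = rpois(4000, 1))
  tracks <- list(rep1 = vectorsToTrack(vl1), rep2 = vectorsToTrack(vl2))
  segs <- GenomicRanges::GRanges(c("chr1", "chr2", "chr1"),
    IRanges::IRanges(c(11, 1001, 3001), width = 500))
  segs$region <- 1:3
  tens <- assembleSegmentTensor(segs, tracks)
  expect_equal(dim(tens), c(3L, 2L, 500L))
  vls <- list(vl1, vl2)
  for (i in 1:3) for (r in 1:2) {
    ch <- as.character(GenomicRanges::seqnames(segs)[i])
    at <- GenomicRanges::start(segs)[i]:GenomicRanges::end(segs)[i]
    expect_equal(tens[i, r, ], as.numeric(vls[[r]][[ch]][at]))
  }
  # a segment over an all-zero stretch gives all-zero rows
  z <- vectorsToTrack(list(chr1 = integer(2000)))
  tens0 <- assembleSegmentTensor(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500), region = 1L),
    list(z))
  expect_true(all(tens0 == 0))
})

test_that("selection matches the naive per-position reference end to end", {
  set.seed(1203)
  for (rep in 1:6) {
    R <- sample(1:3, 1)
    len <- sample(8000:20000, 1)
    base <- rpois(len, 1)
    covs <- lapply(seq_len(R), function(r) {
      v <- base + rpois(len, 1)
      for (k in 1:6) {
        s <- sample(len - 900, 1)
        v[s:(s + sample(200:800, 1))] <- rpois(1, 8) + 3
      }
      list(chr1 = as.integer(v))
    })
    tracks <- lapply(covs, vectorsToTrack)
    for (t in list("median", 2)) {
      ref <- naiveRegionSelection(covs, t, alpha = 1000L)
      th <- if (identical(t, "median"))
        chromosomeMedianThresholds(tracks)
      else c(chr1 = 2)
      ret <- retainedPositions(tracks, th)
      regs <- buildRegionSet(ret)
      if (is.null(ref$regions)) {
        expect_length(regs, 0L)
        next
      }
      expect_equal(GenomicRanges::start(regs) - 1L, ref$regions$start)
      expect_equal(GenomicRanges::end(regs), ref$regions$end)
      merged <- Reduce(`+`, tracks)
      segs <- extractSegments(regs, merged, alpha = 1000L)
      expect_equal(sort(GenomicRanges::start(segs) - 1L),
                   sort(ref$segments$start))
      expect_true(all(GenomicRanges::width(segs) == 1000L))
    }
  }
})

test_that("prepareSegments assembles a consistent PeakSegments object", {
  fx <- simulateFixture(genomeLength = 40000L, nChroms = 1L, nPeaks = 15L,
                        seed = 3)
  bl <- fx$truth[2]                        # blacklist one planted peak
  segs <- prepareSegments(fx$tracks, blacklist = bl, t = 2)
  expect_s4_class(segs, "PeakSegments")
  expect_true(validObject(segs))
  expect_true(all(GenomicRanges::width(segmentRanges(segs)) == 1000L))
  expect_false(any(IRanges::overlapsAny(segmentRanges(segs), bl)))
  expect_equal(dim(segTensor(segs))[2], 2L)
  # every region with segments is recoverable through the region ids
  expect_true(all(segmentRanges(segs)$region %in%
                    candidateRegions(segs)$region))
  # thresholds sidecar
  tf <- tempfile()
  segs2 <- prepareSegments(fx$tracks, t = "median", thresholdsFile = tf)
  expect_true(file.exists(tf))
  tab <- read.table(tf)
  expect_equal(tab$V2, unname(resolvedThresholds(segs2)))
})
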