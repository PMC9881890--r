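# Independent naive-loop oracles used to verify the package's vectorised /
# compiled implementations. These deliberately share no code with R/.

# replicate contrastive loss, direct double loop over the printed formula
naiveReplicateLoss <- function(X, tau) {
  S <- dim(X)[1L]; R <- dim(X)[2L]
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a)) / sqrt(sum(b * b))
  tot <- 0
  for (i in seq_len(S)) for (r in seq_len(R)) for (r2 in seq_len(r)) {
    num <- exp(cs(X[i, r, ], X[i, r2, ]) / tau)
    den <- 0
    for (j in setdiff(seq_len(S), i))
      den <- den + exp(cs(X[i, r, ], X[j, r2, ]) / tau)
    tot <- tot + log(num / den)
  }
  -tot / (S * R^2)
}

# class contrastive loss in its log-ratio form
naiveClassLossLogRatio <- function(q, tau) {
  S <- dim(q)[1L]; R <- dim(q)[2L]
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a)) / sqrt(sum(b * b))
  tot <- 0
  for (k in 1:2) for (r in seq_len(R)) for (r2 in seq_len(r)) {
    p1 <- q[, r, k]; p2 <- q[, r2, k]
    tot <- tot + log(exp(cs(p1, p2) / tau) / exp(cs(p1, 1 - p2) / tau))
  }
  -tot / (2 * R^2)
}

# the same loss in the closed difference form
naiveClassLossDifference <- function(q, tau) {
  S <- dim(q)[1L]; R <- dim(q)[2L]
  cs <- function(a, b) sum(a * b) / sqrt(sum(a * a)) / sqrt(sum(b * b))
  tot <- 0
  for (k in 1:2) for (r in seq_len(R)) for (r2 in seq_len(r)) {
    p1 <- q[, r, k]; p2 <- q[, r2, k]
    tot <- tot - (cs(p1, p2) - cs(p1, 1 - p2)) / tau
  }
  tot / (2 * R^2)
}

naiveAutoencoderLoss <- function(M, Mhat) {
  S <- dim(M)[1L]; R <- dim(M)[2L]
  tot <- 0
  for (i in seq_len(S)) for (r in seq_len(R))
    tot <- tot + mean((M[i, r, ] - Mhat[i, r, ])^2)
  tot / (S * R)
}

# random softmax-style probability array (rows sum to 1 over the 2 classes)
randomProbArray <- function(S, R) {
  a <- array(runif(S * R), c(S, R, 1))
  array(c(a, 1 - a), c(S, R, 2))
}

# naive per-fragment coverage accumulation over plain integer vectors
naiveFragmentCoverage <- function(starts, ends, len) {
  v <- integer(len)
  for (i in seq_along(starts))
    v[starts[i]:ends[i]] <- v[starts[i]:ends[i]] + 1L
  v
}

# Naive reference of the full region-selection procedure on plain vectors.
# covs: list (replicates) of lists (chromosomes) of integer vectors.
# Returns regions and segments in 0-based half-open coordinates.
naiveRegionSelection <- function(covs, t, alpha, mergeGap = 90L,
                                 minRegionLen = 100L, qprob = 0.95) {
  R <- length(covs)
  chroms <- names(covs[[1L]])
  thresholds <- sapply(chroms, function(ch) {
    if (identical(t, "median")) {
      meds <- sapply(seq_len(R), function(r) {
        v <- covs[[r]][[ch]]
        nz <- sort(v[v > 0])
        n <- length(nz)
        if (n == 0L) return(NA_real_)
        (nz[floor((n + 1) / 2)] + nz[ceiling((n + 1) / 2)]) / 2
      })
      if (anyNA(meds)) NA_real_ else min(meds)
    } else as.numeric(t)
  })
  regions <- list()
  segs <- list()
  half <- alpha %/% 2L
  for (ch in chroms) {
    tt <- thresholds[[ch]]
    if (is.na(tt)) next
    len <- length(covs[[1L]][[ch]])
    keep <- rep(TRUE, len)
    for (r in seq_len(R)) keep <- keep & (covs[[r]][[ch]] > tt)
    pos <- which(keep) - 1L                      # 0-based positions
    if (!length(pos)) next
    # contiguous runs
    runStart <- pos[c(TRUE, diff(pos) != 1L)]
    runEnd <- pos[c(diff(pos) != 1L, TRUE)] + 1L # half-open ends
    # transitive merge when gap <= mergeGap
    ms <- runStart[1L]; me <- runEnd[1L]
    regs <- NULL
    if (length(runStart) > 1L) for (j in 2:length(runStart)) {
      if (runStart[j] - me <= mergeGap) me <- runEnd[j]
      else { regs <- rbind(regs, c(ms, me)); ms <- runStart[j]; me <- runEnd[j] }
    }
    regs <- rbind(regs, c(ms, me))
    regs <- regs[regs[, 2L] - regs[, 1L] > minRegionLen, , drop = FALSE]
    if (!nrow(regs)) next
    merged <- Reduce(`+`, lapply(covs, function(x) x[[ch]]))
    for (j in seq_len(nrow(regs))) {
      s0 <- regs[j, 1L]; e0 <- regs[j, 2L]
      if (e0 - s0 <= alpha) {
        mids <- (s0 + e0) %/% 2L
      } else {
        v <- merged[(s0 + 1L):e0]
        qv <- stats::quantile(v, qprob, names = FALSE, type = 7)
        hi <- which(v >= qv)                     # 1-based within region
        cs <- hi[c(TRUE, diff(hi) > alpha + 1L)] # cluster when gap <= alpha
        ce <- hi[c(diff(hi) > alpha + 1L, TRUE)]
        a0 <- s0 + cs - 1L
        b0 <- s0 + ce
        mids <- (a0 + b0) %/% 2L
      }
      st <- pmin(pmax(mids - half, 0L), len - alpha)
      st <- unique(st)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = e0)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + alpha)
    }
  }
  list(regions = do.call(rbind, regions), segments = do.call(rbind, segs),
       thresholds = thresholds)
}

# Rle coverage list -> plain vector list, for feeding the naive reference
tracksToVectors <- function(tracks) {
  lapply(tracks, function(tr) lapply(as.list(tr), as.integer))
}

# build an RleList coverage track from a plain list of integer vectors
vectorsToTrack <- function(vl) {
  methods::as(lapply(vl, S4Vectors::Rle), "RleList")
}

# write a minimal SAM file from explicit fields (for hand-trace tests)
writeHandSam <- function(path, seqlines, records) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(seqlines, con)
  if (length(records)) writeLines(records, con)
  invisible(path)
}
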