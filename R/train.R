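#' Train the contrastive peak-calling model
#'
#' Jointly minimises the weighted sum of the replicate contrastive loss,
#' the segment-class contrastive loss and the autoencoder reconstruction
#' loss with Adam. Batches are formed over segments (all replicates of a
#' segment always travel together); the class loss couples the segments of
#' the current batch. A trailing batch with fewer than 2 segments is merged
#' into the previous batch, since the contrastive losses need at least two
#' segments. Training is deterministic given \code{seed}: the shuffling
#' order is a pure function of it.
#'
#' Before the first step (and only when \code{epochs > 0}) the initial
#' parameters are calibrated layer-sequentially to unit pre-activation
#' variance on a sample of the training tensor, so that every seed starts
#' the unnormalised convolutional stack at a comparable scale.
#'
#' After the final epoch the identity of the "peak" softmax column is
#' resolved by correlating each column's mean probability with mean segment
#' coverage (see \code{\link{segmentScores}}).
#'
#' @param model an untrained \code{\link{ContrastModel}}
#' @param segments a \code{\link{PeakSegments}} object (or bare
#'   S x R x alpha array)
#' @param epochs number of passes over the segments (default 25)
#' @param batchSize segments per batch (default 256)
#' @param learningRate Adam step size (default 1e-4)
#' @param seed integer seed controlling shuffling
#' @param shuffle reshuffle segment order each epoch (default TRUE)
#' @param verbose print per-epoch losses (default FALSE)
#' @return a \code{\link{ContrastFit}} with per-epoch loss history
#' @export
setMethod("trainModel", "ContrastModel",
function(model, segments, epochs = 25L, batchSize = 256L,
         learningRate = 1e-4, seed = 1L, shuffle = TRUE, verbose = FALSE) {
  X <- .checkTensor(model, segments)
  S <- dim(X)[1L]; R <- dim(X)[2L]
  if (S < 2L) stop("training needs at least 2 segments")
  stopifnot(epochs >= 0L, batchSize >= 2L, learningRate > 0)
  cfg <- model@config
  w <- cfg$lossWeights
  p <- model@params
  if (epochs > 0L) {
    # scale-calibrate the freshly initialised stack on (a sample of) the
    # training tensor so optimisation starts in a consistent regime
    calIdx <- seq_len(min(S, batchSize))
    p <- .calibrateInit(p, cfg, .tensorToCube(X[calIdx, , , drop = FALSE]))
  }

  adamM <- lapply(p, function(x) x * 0)
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  stepNo <- 0L

  history <- data.frame(epoch = integer(0), l1 = numeric(0),
                        l2 = numeric(0), l3 = numeric(0),
                        total = numeric(0))
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- if (shuffle) sample.int(S) else seq_len(S)
    splits <- split(ord, ceiling(seq_along(ord) / batchSize))
    if (length(splits) > 1L &&
        length(splits[[length(splits)]]) < 2L) {
      splits[[length(splits) - 1L]] <-
        c(splits[[length(splits) - 1L]], splits[[length(splits)]])
      splits[[length(splits)]] <- NULL
    }
    epLoss <- c(l1 = 0, l2 = 0, l3 = 0, total = 0)
    nSeg <- 0L
    for (bi in seq_along(splits)) {
      idx <- splits[[bi]]
      Sb <- length(idx)
      Xc <- .tensorToCube(X[idx, , , drop = FALSE])

      enc <- .encoderF(p, cfg, Xc)
      head <- .headF(p, enc$E)
      dec <- .decoderF(p, cfg, enc$E)

      g1 <- .l1Grad(enc$E, Sb, R, cfg$tau1)
      g2 <- .l2Grad(head$q, Sb, R, cfg$tau2)
      g3 <- .l3Grad(Xc, dec$Mhat)
      tot <- w[1L] * g1$value + w[2L] * g2$value + w[3L] * g3$value
      if (!is.finite(tot))
        stop("non-finite loss in epoch ", ep, ", batch ", bi)

      dq <- w[2L] * g2$dq
      dlogits <- head$q * (dq - rowSums(dq * head$q))
      hb <- .headB(p, head$cache, dlogits)
      db <- .decoderB(p, cfg, dec$cache, w[3L] * g3$dMhat)
      dE <- w[1L] * g1$dE + hb$dE + db$dE
      eb <- .encoderB(p, cfg, enc$cache, dE)
      grads <- c(eb$grads, hb$grads, db$grads)

      stepNo <- stepNo + 1L
      c1 <- 1 - b1^stepNo; c2 <- 1 - b2^stepNo
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g * g
        p[[nm]] <- p[[nm]] - learningRate *
          (adamM[[nm]] / c1) / (sqrt(adamV[[nm]] / c2) + eps)
      }
      epLoss <- epLoss + Sb * c(g1$value, g2$value, g3$value, tot)
      nSeg <- nSeg + Sb
    }
    epLoss <- epLoss / nSeg
    history <- rbind(history,
                     data.frame(epoch = ep, l1 = epLoss[1L], l2 = epLoss[2L],
                                l3 = epLoss[3L], total = epLoss[4L]))
    if (verbose)
      message(sprintf("epoch %d: l1=%.5f l2=%.5f l3=%.5f total=%.5f",
                      ep, epLoss[1L], epLoss[2L], epLoss[3L], epLoss[4L]))
  }
  rownames(history) <- NULL

  fit <- methods::new("ContrastFit", config = cfg, params = p,
                      history = history, peakClass = NA_integer_)
  fit@peakClass <- .resolvePeakClass(fit, X)
  fit
})

# Identify which softmax column is the peak class. The class losses are
# invariant to swapping the two columns, so the peak = column 1 convention
# seeded at initialisation can in principle be flipped by training; a flip
# is only identifiable (and only matters) when the classifier actually
# separates the segments into two groups. When it does, the group whose
# members have higher mean coverage is the peak class; otherwise the
# column-1 convention stands (candidate selection pre-enriches for peaks).
.resolvePeakClass <- function(fit, X) {
  S <- dim(X)[1L]; R <- dim(X)[2L]
  E <- .encoderF(fit@params, fit@config, .tensorToCube(X))$E
  q <- .headF(fit@params, E)$q
  qArr <- .unstackSR(q, S, R)
  qbar <- apply(qArr, c(1L, 3L), mean)       # S x 2, replicate-averaged
  covMean <- apply(X, 1L, mean)              # mean coverage per segment
  assign1 <- qbar[, 1L] >= 0.5
  minority <- min(sum(assign1), sum(!assign1)) / S
  cls <- 1L
  if (minority >= 0.1) {
    m1 <- mean(covMean[assign1]); m2 <- mean(covMean[!assign1])
    cls <- if (m1 >= m2) 1L else 2L
  }
  message("peak class resolved to softmax column ", cls,
          if (minority >= 0.1) " (two-group coverage comparison)"
          else " (no substantial class split; column-1 convention)")
  cls
}
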