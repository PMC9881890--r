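# a small configuration keeps the forward/backward tests fast while still
# exercising every layer type
tinyModel <- function(seed = 2) {
  contrastModel(alpha = 64L, embedDim = 8L, kernelSize = 7L, dilation = 2L,
                nModules = 2L, channels = 2L, seed = seed)
}

test_that("encoder, head and decoder obey the shape contracts", {
  m <- tinyModel()
  set.seed(4)
  X <- array(rpois(3 * 2 * 64, 2), c(3, 2, 64))
  E <- encode(m, X)
  expect_equal(dim(E), c(3L, 2L, 8L))
  q <- classify(m, E)
  expect_equal(dim(q), c(3L, 2L, 2L))
  expect_equal(apply(q, c(1, 2), sum), matrix(1, 3, 2), tolerance = 1e-6)
  Mhat <- decode(m, E)
  expect_equal(dim(Mhat), dim(X))
  expect_true(all(is.finite(Mhat)))

  # default geometry: 1000 bp in, 50-dimensional embedding out
  m50 <- contrastModel(seed = 1)
  X1 <- array(rpois(1 * 2 * 1000, 2), c(1, 2, 1000))
  expect_equal(dim(encode(m50, X1)), c(1L, 2L, 50L))
  expect_error(encode(m50, X), "alpha")
})

test_that("encoding is deterministic and shared across replicates", {
  m <- tinyModel()
  set.seed(5)
  x <- rpois(64, 3)
  X <- array(0, c(2, 2, 64))
  for (i in 1:2) for (r in 1:2) X[i, r, ] <- x
  E <- encode(m, X)
  # same function applied to the same input: all four embeddings identical
  expect_equal(E[1, 1, ], E[1, 2, ])
  expect_equal(E[1, 1, ], E[2, 1, ])
  expect_equal(encode(m, X), E)

  # perturbing any single parameter changes the output
  m2 <- m
  m2@params$enc_m1_c2_W[3] <- m2@params$enc_m1_c2_W[3] + 0.05
  expect_false(isTRUE(all.equal(encode(m2, X), E)))
})

test_that("a zero-weight head returns (0.5, 0.5)", {
  m <- tinyModel()
  for (nm in c("head_W1", "head_b1", "head_W2", "head_b2"))
    m@params[[nm]] <- m@params[[nm]] * 0
  set.seed(6)
  E <- array(rnorm(4 * 2 * 8), c(4, 2, 8))
  q <- classify(m, E)
  expect_equal(as.numeric(q), rep(0.5, 16))
})

test_that("loss worked examples evaluate as derived", {
  # identical unit embeddings: every log term is log(e^2/e^2) = 0
  X <- array(0, c(2, 2, 3))
  for (i in 1:2) for (r in 1:2) X[i, r, ] <- c(1, 0, 0)
  expect_equal(lossReplicateContrastive(X, 0.5), 0, tolerance = 1e-12)

  # cosine scale invariance: rescaling any embedding changes nothing
  set.seed(8)
  X <- array(rnorm(4 * 2 * 5), c(4, 2, 5))
  v <- lossReplicateContrastive(X, 0.5)
  X[2, 1, ] <- 7.3 * X[2, 1, ]
  expect_equal(lossReplicateContrastive(X, 0.5), v, tolerance = 1e-9)

  # hard assignments, R = 1, S = 2, tau2 = 0.5: l2 = -2
  q <- array(0, c(2, 1, 2))
  q[1, 1, ] <- c(1, 0); q[2, 1, ] <- c(0, 1)
  expect_equal(lossClass(q, 0.5), -2, tolerance = 1e-12)

  # identical class profiles across replicates score lower than flipped ones
  qsame <- array(0, c(2, 2, 2))
  qsame[, 1, ] <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  qsame[, 2, ] <- qsame[, 1, ]
  qflip <- qsame
  qflip[, 2, ] <- qsame[, 1, 2:1]
  expect_lt(lossClass(qsame, 0.5), lossClass(qflip, 0.5))

  # autoencoder examples
  M <- array(rpois(2 * 2 * 10, 3), c(2, 2, 10))
  expect_equal(lossAutoencoder(M, M), 0)
  expect_equal(lossAutoencoder(array(0, c(1, 1, 2)),
                               array(1, c(1, 1, 2))), 1)

  expect_equal(totalLoss(1, 2, 3), 6)
  expect_equal(totalLoss(1, 2, 3, weights = c(0, 0, 1)), 3)
})

test_that("losses match naive-loop oracles on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    S <- sample(2:8, 1); R <- sample(1:3, 1); d <- sample(2:5, 1)
    X <- array(rnorm(S * R * d), c(S, R, d))
    expect_equal(lossReplicateContrastive(X, 0.5),
                 naiveReplicateLoss(X, 0.5), tolerance = 1e-6)
    q <- randomProbArray(S, R)
    expect_equal(lossClass(q, 0.7), naiveClassLossLogRatio(q, 0.7),
                 tolerance = 1e-6)
    # the log-ratio and closed difference forms agree identically
    expect_equal(naiveClassLossLogRatio(q, 0.7),
                 naiveClassLossDifference(q, 0.7), tolerance = 1e-9)
    M <- array(rpois(S * R * 12, 4), c(S, R, 12))
    Mh <- M + array(rnorm(length(M)), dim(M))
    expect_equal(lossAutoencoder(M, Mh), naiveAutoencoderLoss(M, Mh),
                 tolerance = 1e-9)
  }
})

test_that("contrastive losses are invariant to consistent segment
           permutations", {
  set.seed(77)
  S <- 6; R <- 2
  X <- array(rnorm(S * R * 4), c(S, R, 4))
  q <- randomProbArray(S, R)
  perm <- sample(S)
  expect_equal(lossReplicateContrastive(X[perm, , ], 0.5),
               lossReplicateContrastive(X, 0.5), tolerance = 1e-9)
  expect_equal(lossClass(q[perm, , ], 0.5), lossClass(q, 0.5),
               tolerance = 1e-9)
})

test_that("loss error contracts hold", {
  X1 <- array(rnorm(1 * 2 * 4), c(1, 2, 4))
  expect_error(lossReplicateContrastive(X1), "2 segments")
  Xz <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  Xz[2, 1, ] <- 0
  expect_error(lossReplicateContrastive(Xz), "zero-norm")
  qz <- array(0, c(2, 1, 2))
  qz[, 1, 1] <- 0; qz[, 1, 2] <- 1
  expect_error(lossClass(qz), "zero-norm")
  expect_error(lossAutoencoder(array(0, c(1, 1, 3)), array(0, c(1, 1, 4))),
               "shape")
})

test_that("analytic gradients of the joint loss match finite differences", {
  ns <- asNamespace("contrastPeaks")
  cfg <- list(alpha = 32L, embedDim = 4L, kernelSize = 5L, dilation = 2L,
              nModules = 2L, channels = 2L, tau1 = 0.5, tau2 = 0.5,
              lossWeights = c(1, 1, 1))
  p <- ns$.initParams(cfg, 7)
  S <- 3; R <- 2
  set.seed(8)
  X <- array(rpois(S * R * 32, 3), c(S, R, 32))
  Xc <- ns$.tensorToCube(X)

  lossAll <- function(p) {
    enc <- ns$.encoderF(p, cfg, Xc)
    hd <- ns$.headF(p, enc$E)
    dec <- ns$.decoderF(p, cfg, enc$E)
    ns$.l1Grad(enc$E, S, R, 0.5, wantGrad = FALSE)$value +
      ns$.l2Grad(hd$q, S, R, 0.5, wantGrad = FALSE)$value +
      ns$.l3Grad(Xc, dec$Mhat)$value
  }
  enc <- ns$.encoderF(p, cfg, Xc)
  hd <- ns$.headF(p, enc$E)
  dec <- ns$.decoderF(p, cfg, enc$E)
  g1 <- ns$.l1Grad(enc$E, S, R, 0.5)
  g2 <- ns$.l2Grad(hd$q, S, R, 0.5)
  g3 <- ns$.l3Grad(Xc, dec$Mhat)
  dlog <- hd$q * (g2$dq - rowSums(g2$dq * hd$q))
  hb <- ns$.headB(p, hd$cache, dlog)
  db <- ns$.decoderB(p, cfg, dec$cache, g3$dMhat)
  eb <- ns$.encoderB(p, cfg, enc$cache, g1$dE + hb$dE + db$dE)
  grads <- c(eb$grads, hb$grads, db$grads)

  eps <- 1e-6
  set.seed(99)
  for (nm in sample(names(grads))) {
    i <- sample(length(p[[nm]]), 1)
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (lossAll(pp) - lossAll(pm)) / (2 * eps)
    rel <- abs(fd - grads[[nm]][i]) / max(1e-6, abs(fd) + abs(grads[[nm]][i]))
    expect_lt(rel, 1e-3)
  }
})
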