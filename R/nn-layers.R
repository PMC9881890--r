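# Internal neural-network primitives. Activations are 3-d arrays of
# dimension (length, channels, batch); the compiled conv1d kernels in src/
# do the dilated "same"-padding convolutions, everything else is plain
# vectorised R. Each forward returns list(y, cache); each backward takes
# the cache and upstream gradient and returns dx plus parameter gradients.

.convF <- function(x, W, b, dilation, relu = TRUE) {
  z <- .conv1dForward(x, W, b, as.integer(dilation))
  y <- if (relu) pmax(z, 0) else z
  list(y = y, cache = list(x = x, z = z, relu = relu))
}

.convB <- function(cache, W, dilation, dy) {
  dz <- if (cache$relu) dy * (cache$z > 0) else dy
  g <- .conv1dBackward(cache$x, W, dz, as.integer(dilation))
  list(dx = g$dX, dW = g$dW, db = g$db)
}

# residual block: y = relu(conv(x)) + x  (channel- and length-preserving)
.resF <- function(x, W, b, dilation) {
  z <- .conv1dForward(x, W, b, as.integer(dilation))
  list(y = pmax(z, 0) + x, cache = list(x = x, z = z))
}

.resB <- function(cache, W, dilation, dy) {
  dz <- dy * (cache$z > 0)
  g <- .conv1dBackward(cache$x, W, dz, as.integer(dilation))
  list(dx = g$dX + dy, dW = g$dW, db = g$db)
}

# average pooling with window 2 (last window may have size 1 when L is odd)
.poolF <- function(x) {
  L <- dim(x)[1L]
  Lo <- (L + 1L) %/% 2L
  odd <- L %% 2L == 1L
  i1 <- seq(1L, by = 2L, length.out = Lo)
  i2 <- pmin(i1 + 1L, L)
  y <- (x[i1, , , drop = FALSE] + x[i2, , , drop = FALSE]) / 2
  if (odd) y[Lo, , ] <- x[L, , ]
  list(y = y, cache = list(L = L))
}

.poolB <- function(cache, dy) {
  L <- cache$L
  Lo <- dim(dy)[1L]
  odd <- L %% 2L == 1L
  dx <- array(0, dim = c(L, dim(dy)[2L], dim(dy)[3L]))
  half <- dy / 2
  i1 <- seq(1L, by = 2L, length.out = Lo)
  dx[i1, , ] <- half
  full <- if (odd) seq_len(Lo - 1L) else seq_len(Lo)
  if (length(full)) dx[i1[full] + 1L, , ] <- half[full, , , drop = FALSE]
  if (odd) dx[L, , ] <- dy[Lo, , ]
  dx
}

# nearest-neighbour upsampling to an explicit target length
.upF <- function(x, Lt) {
  L <- dim(x)[1L]
  idx <- floor((seq_len(Lt) - 1L) * L / Lt) + 1L
  list(y = x[idx, , , drop = FALSE], cache = list(L = L, idx = idx))
}

.upB <- function(cache, dy) {
  d <- dim(dy)
  dx <- array(0, dim = c(cache$L, d[2L], d[3L]))
  agg <- rowsum(matrix(dy, nrow = d[1L]), group = cache$idx)
  dx[sort(unique(cache$idx)), , ] <- agg
  dx
}

# dense layer on row-major sample matrices: y = x W + b
.linF <- function(x, W, b) {
  list(y = sweep(x %*% W, 2L, b, `+`), cache = list(x = x))
}

.linB <- function(cache, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# (L, C, B) array <-> (B, L*C) matrix
.flatten <- function(x) {
  d <- dim(x)
  t(matrix(x, nrow = d[1L] * d[2L], ncol = d[3L]))
}

.unflatten <- function(m, L, C) {
  array(t(m), dim = c(L, C, nrow(m)))
}

# encoder module lengths: alpha halved (ceiling) once per ResNet module
.moduleLengths <- function(alpha, nModules) {
  Ls <- integer(nModules + 1L)
  Ls[1L] <- as.integer(alpha)
  for (m in seq_len(nModules)) Ls[m + 1L] <- (Ls[m] + 1L) %/% 2L
  Ls
}

.initConv <- function(K, cin, cout) {
  array(stats::rnorm(K * cin * cout, sd = sqrt(2 / (K * cin))),
        dim = c(K, cin, cout))
}

.initLin <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
}

# biases get small noise rather than zeros so that ReLU pre-activations
# have no point mass exactly at the kink
.initBias <- function(n) stats::rnorm(n, sd = 0.01)

# He-initialised parameter list for the full encoder/head/decoder stack
.initParams <- function(cfg, seed) {
  set.seed(seed)
  K <- cfg$kernelSize; C <- cfg$channels; M <- cfg$nModules
  d <- cfg$embedDim
  Ls <- .moduleLengths(cfg$alpha, M)
  Lend <- Ls[M + 1L]
  p <- list()
  for (m in seq_len(M)) {
    cin <- if (m == 1L) 1L else C
    p[[sprintf("enc_m%d_c1_W", m)]] <- .initConv(K, cin, C)
    p[[sprintf("enc_m%d_c1_b", m)]] <- .initBias(C)
    for (j in 2:4) {
      p[[sprintf("enc_m%d_c%d_W", m, j)]] <- .initConv(K, C, C)
      p[[sprintf("enc_m%d_c%d_b", m, j)]] <- .initBias(C)
    }
  }
  p$enc_fc_W <- .initLin(Lend * C, d)
  p$enc_fc_b <- .initBias(d)
  p$head_W1 <- .initLin(d, d)
  p$head_b1 <- .initBias(d)
  p$head_W2 <- .initLin(d, 2L)
  # label-symmetry breaking: the class losses are invariant to swapping the
  # two softmax columns, so the peak = column 1 convention is seeded with an
  # asymmetric output bias; candidate selection pre-enriches for peaks, and
  # the post-training coverage-correlation check still verifies the identity
  p$head_b2 <- c(1.5, -1.5) + .initBias(2L)
  p$dec_fc_W <- .initLin(d, Lend * C)
  p$dec_fc_b <- .initBias(Lend * C)
  for (m in seq_len(M)) {
    for (j in 1:4) {
      p[[sprintf("dec_m%d_c%d_W", m, j)]] <- .initConv(K, C, C)
      p[[sprintf("dec_m%d_c%d_b", m, j)]] <- .initBias(C)
    }
  }
  p$dec_out_W <- .initConv(K, C, 1L)
  p$dec_out_b <- .initBias(1L)
  p
}

# Layer-sequential unit-variance calibration of the initial parameters on
# (a sample of) the training tensor: each convolution / dense layer is
# rescaled so its pre-activation standard deviation is 1, and the decoder's
# output layer is rescaled to the data scale. Deep unnormalised ReLU stacks
# otherwise start with a seed-dependent gain that can differ by orders of
# magnitude; calibration puts every seed in the same scale regime without
# touching the raw-coverage inputs. Deterministic given parameters and data.
.calibrateInit <- function(p, cfg, X) {
  dil <- cfg$dilation; M <- cfg$nModules; C <- cfg$channels
  Ls <- .moduleLengths(cfg$alpha, M)
  rescale <- function(Wnm, bnm, z) {
    s <- max(stats::sd(z), 1e-8)
    p[[Wnm]] <<- p[[Wnm]] / s
    p[[bnm]] <<- p[[bnm]] / s
    z / s
  }
  h <- X
  for (m in seq_len(M)) {
    for (j in 1:3) {
      Wnm <- sprintf("enc_m%d_c%d_W", m, j)
      bnm <- sprintf("enc_m%d_c%d_b", m, j)
      z <- .conv1dForward(h, p[[Wnm]], p[[bnm]], dil)
      h <- pmax(rescale(Wnm, bnm, z), 0)
    }
    Wnm <- sprintf("enc_m%d_c4_W", m); bnm <- sprintf("enc_m%d_c4_b", m)
    z <- .conv1dForward(h, p[[Wnm]], p[[bnm]], dil)
    h <- .poolF(pmax(rescale(Wnm, bnm, z), 0) + h)$y
  }
  E <- .linF(.flatten(h), p$enc_fc_W, p$enc_fc_b)$y
  E <- rescale("enc_fc_W", "enc_fc_b", E)
  h1 <- .linF(E, p$head_W1, p$head_b1)$y
  rescale("head_W1", "head_b1", h1)
  # head_W2 / head_b2 keep their symmetry-breaking initialisation
  g <- .linF(E, p$dec_fc_W, p$dec_fc_b)$y
  h <- .unflatten(rescale("dec_fc_W", "dec_fc_b", g), Ls[M + 1L], C)
  for (m in seq_len(M)) {
    for (j in 1:3) {
      Wnm <- sprintf("dec_m%d_c%d_W", m, j)
      bnm <- sprintf("dec_m%d_c%d_b", m, j)
      z <- .conv1dForward(h, p[[Wnm]], p[[bnm]], dil)
      h <- pmax(rescale(Wnm, bnm, z), 0)
    }
    Wnm <- sprintf("dec_m%d_c4_W", m); bnm <- sprintf("dec_m%d_c4_b", m)
    z <- .conv1dForward(h, p[[Wnm]], p[[bnm]], dil)
    h <- .upF(pmax(rescale(Wnm, bnm, z), 0) + h, Ls[M + 1L - m])$y
  }
  z <- .conv1dForward(h, p$dec_out_W, p$dec_out_b, dil)
  s <- max(stats::sd(z), 1e-8) / max(stats::sd(X), 1e-8)
  p$dec_out_W <- p$dec_out_W / s
  p$dec_out_b <- p$dec_out_b / s
  p
}

.encoderF <- function(p, cfg, X) {
  M <- cfg$nModules; dil <- cfg$dilation; C <- cfg$channels
  caches <- vector("list", M)
  h <- X
  for (m in seq_len(M)) {
    cc <- list()
    for (j in 1:3) {
      f <- .convF(h, p[[sprintf("enc_m%d_c%d_W", m, j)]],
                  p[[sprintf("enc_m%d_c%d_b", m, j)]], dil)
      h <- f$y; cc[[j]] <- f$cache
    }
    f <- .resF(h, p[[sprintf("enc_m%d_c4_W", m)]],
               p[[sprintf("enc_m%d_c4_b", m)]], dil)
    h <- f$y; cc[[4L]] <- f$cache
    f <- .poolF(h)
    h <- f$y; cc[[5L]] <- f$cache
    caches[[m]] <- cc
  }
  flat <- .flatten(h)
  f <- .linF(flat, p$enc_fc_W, p$enc_fc_b)
  list(E = f$y, cache = list(modules = caches, fc = f$cache,
                             Lend = dim(h)[1L], C = C))
}

.encoderB <- function(p, cfg, cache, dE) {
  M <- cfg$nModules; dil <- cfg$dilation
  g <- list()
  lb <- .linB(cache$fc, p$enc_fc_W, dE)
  g$enc_fc_W <- lb$dW; g$enc_fc_b <- lb$db
  dh <- .unflatten(lb$dx, cache$Lend, cache$C)
  for (m in rev(seq_len(M))) {
    cc <- cache$modules[[m]]
    dh <- .poolB(cc[[5L]], dh)
    rb <- .resB(cc[[4L]], p[[sprintf("enc_m%d_c4_W", m)]], dil, dh)
    g[[sprintf("enc_m%d_c4_W", m)]] <- rb$dW
    g[[sprintf("enc_m%d_c4_b", m)]] <- rb$db
    dh <- rb$dx
    for (j in 3:1) {
      cb <- .convB(cc[[j]], p[[sprintf("enc_m%d_c%d_W", m, j)]], dil, dh)
      g[[sprintf("enc_m%d_c%d_W", m, j)]] <- cb$dW
      g[[sprintf("enc_m%d_c%d_b", m, j)]] <- cb$db
      dh <- cb$dx
    }
  }
  list(grads = g, dX = dh)
}

.headF <- function(p, E) {
  f1 <- .linF(E, p$head_W1, p$head_b1)
  h <- pmax(f1$y, 0)
  f2 <- .linF(h, p$head_W2, p$head_b2)
  logits <- f2$y
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  q <- ex / rowSums(ex)
  list(q = q, logits = logits,
       cache = list(f1 = f1$cache, z1 = f1$y, f2c = list(x = h)))
}

.headB <- function(p, cache, dlogits) {
  g <- list()
  l2 <- .linB(cache$f2c, p$head_W2, dlogits)
  g$head_W2 <- l2$dW; g$head_b2 <- l2$db
  dh <- l2$dx * (cache$z1 > 0)
  l1 <- .linB(cache$f1, p$head_W1, dh)
  g$head_W1 <- l1$dW; g$head_b1 <- l1$db
  list(grads = g, dE = l1$dx)
}

.decoderF <- function(p, cfg, E) {
  M <- cfg$nModules; dil <- cfg$dilation; C <- cfg$channels
  Ls <- .moduleLengths(cfg$alpha, M)
  f <- .linF(E, p$dec_fc_W, p$dec_fc_b)
  h <- .unflatten(f$y, Ls[M + 1L], C)
  caches <- vector("list", M)
  for (m in seq_len(M)) {
    cc <- list()
    for (j in 1:3) {
      ff <- .convF(h, p[[sprintf("dec_m%d_c%d_W", m, j)]],
                   p[[sprintf("dec_m%d_c%d_b", m, j)]], dil)
      h <- ff$y; cc[[j]] <- ff$cache
    }
    ff <- .resF(h, p[[sprintf("dec_m%d_c4_W", m)]],
                p[[sprintf("dec_m%d_c4_b", m)]], dil)
    h <- ff$y; cc[[4L]] <- ff$cache
    ff <- .upF(h, Ls[M + 1L - m])
    h <- ff$y; cc[[5L]] <- ff$cache
    caches[[m]] <- cc
  }
  ff <- .convF(h, p$dec_out_W, p$dec_out_b, dil, relu = FALSE)
  list(Mhat = ff$y, cache = list(fc = f$cache, modules = caches,
                                 out = ff$cache, C = C,
                                 Lend = Ls[M + 1L]))
}

.decoderB <- function(p, cfg, cache, dMhat) {
  M <- cfg$nModules; dil <- cfg$dilation
  g <- list()
  ob <- .convB(cache$out, p$dec_out_W, dil, dMhat)
  g$dec_out_W <- ob$dW; g$dec_out_b <- ob$db
  dh <- ob$dx
  for (m in rev(seq_len(M))) {
    cc <- cache$modules[[m]]
    dh <- .upB(cc[[5L]], dh)
    rb <- .resB(cc[[4L]], p[[sprintf("dec_m%d_c4_W", m)]], dil, dh)
    g[[sprintf("dec_m%d_c4_W", m)]] <- rb$dW
    g[[sprintf("dec_m%d_c4_b", m)]] <- rb$db
    dh <- rb$dx
    for (j in 3:1) {
      cb <- .convB(cc[[j]], p[[sprintf("dec_m%d_c%d_W", m, j)]], dil, dh)
      g[[sprintf("dec_m%d_c%d_W", m, j)]] <- cb$dW
      g[[sprintf("dec_m%d_c%d_b", m, j)]] <- cb$db
      dh <- cb$dx
    }
  }
  flat <- .flatten(dh)
  lb <- .linB(cache$fc, p$dec_fc_W, flat)
  g$dec_fc_W <- lb$dW; g$dec_fc_b <- lb$db
  list(grads = g, dE = lb$dx)
}
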