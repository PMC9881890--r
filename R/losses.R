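# The three jointly minimised losses. Exported functions take
# segments x replicates x dim arrays and return scalar values with strict
# input checking; the internal .l*Grad versions work on replicate-major
# stacked matrices and also return gradients for training.

# stack S x R x d array into (S*R) x d matrix, row b = (r-1)*S + i
.stackSR <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

.cosNorm <- function(x, floor = 1e-12) pmax(sqrt(sum(x * x)), floor)

#' Pairwise replicate contrastive loss
#'
#' Contrasts the embeddings of the same segment across replicates (positive
#' pairs, including replicate self-pairs) against the embeddings of all
#' other segments (negatives). For segment i and replicate pair (r, r'),
#' the per-term numerator is exp(cos(x_ri, x_r'i)/tau1) and the denominator
#' sums exp(cos(x_ri, x_r'j)/tau1) over segments j != i only; terms are
#' summed over all pairs 1 <= r' <= r <= R and scaled by -1/(S R^2).
#'
#' @param embeddings numeric array of dimension S x R x embedDim
#' @param tau1 temperature (> 0, default 0.5)
#' @param includeSelfPairs include r' = r pairs (default TRUE, the printed
#'   index set); set FALSE to restrict to r' < r
#' @return scalar loss value
#' @export
lossReplicateContrastive <- function(embeddings, tau1 = 0.5,
                                     includeSelfPairs = TRUE) {
  stopifnot(is.array(embeddings), length(dim(embeddings)) == 3L, tau1 > 0)
  S <- dim(embeddings)[1L]; R <- dim(embeddings)[2L]
  if (S < 2L)
    stop("replicate contrastive loss needs at least 2 segments")
  E <- .stackSR(embeddings)
  nrm <- sqrt(rowSums(E^2))
  if (any(nrm < 1e-12)) stop("zero-norm embedding")
  .l1Grad(E, S, R, tau1, includeSelfPairs, wantGrad = FALSE)$value
}

.l1Grad <- function(E, S, R, tau1, includeSelfPairs = TRUE,
                    wantGrad = TRUE) {
  nrm <- pmax(sqrt(rowSums(E^2)), 1e-12)
  N <- E / nrm
  cst <- 1 / (S * R^2)
  value <- 0
  dN <- if (wantGrad) matrix(0, nrow(E), ncol(E)) else NULL
  rows <- function(r) ((r - 1L) * S + 1L):(r * S)
  for (r in seq_len(R)) {
    r2max <- if (includeSelfPairs) r else r - 1L
    for (r2 in seq_len(r2max)) {
      U <- N[rows(r), , drop = FALSE]
      V <- N[rows(r2), , drop = FALSE]
      A <- tcrossprod(U, V) / tau1
      Aoff <- A; diag(Aoff) <- -Inf
      mx <- apply(Aoff, 1L, max)
      W <- exp(Aoff - mx)        # off-diagonal softmax weights (unnorm.)
      rs <- rowSums(W)
      lse <- mx + log(rs)
      value <- value + cst * sum(lse - diag(A))
      if (wantGrad) {
        dA <- cst * W / rs
        diag(dA) <- diag(dA) - cst
        dN[rows(r), ] <- dN[rows(r), ] + (dA %*% V) / tau1
        dN[rows(r2), ] <- dN[rows(r2), ] + crossprod(dA, U) / tau1
      }
    }
  }
  out <- list(value = value)
  if (wantGrad) {
    # through row normalisation u / |u|
    dot <- rowSums(dN * N)
    out$dE <- (dN - dot * N) / nrm
  }
  out
}

#' Segment-class contrastive loss
#'
#' Aligns the per-replicate class-probability profiles across segments.
#' With p_rk the length-S vector of class-k probabilities of replicate r,
#' each pair (r' <= r) and class k contributes
#' -log[exp(cos(p_rk, p_r'k)/tau2) / exp(cos(p_rk, 1 - p_r'k)/tau2)],
#' i.e. the closed form -(cos(p_rk, p_r'k) - cos(p_rk, 1 - p_r'k))/tau2,
#' scaled by 1/(2 R^2).
#'
#' @param probs numeric array of dimension S x R x 2 of per
#'   segment-replicate class probabilities (rows summing to 1)
#' @param tau2 temperature (> 0, default 0.5)
#' @return scalar loss value
#' @export
lossClass <- function(probs, tau2 = 0.5) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L,
            dim(probs)[3L] == 2L, tau2 > 0)
  S <- dim(probs)[1L]; R <- dim(probs)[2L]
  q <- .stackSR(probs)
  for (r in seq_len(R)) {
    rows <- ((r - 1L) * S + 1L):(r * S)
    for (k in 1:2) {
      if (sqrt(sum(q[rows, k]^2)) < 1e-12 ||
          sqrt(sum((1 - q[rows, k])^2)) < 1e-12)
        stop("zero-norm class-probability vector")
    }
  }
  .l2Grad(q, S, R, tau2, wantGrad = FALSE)$value
}

# cosine between vectors plus gradients wrt both arguments
.cosPair <- function(u, v) {
  nu <- .cosNorm(u); nv <- .cosNorm(v)
  uh <- u / nu; vh <- v / nv
  cs <- sum(uh * vh)
  list(cos = cs, du = (vh - cs * uh) / nu, dv = (uh - cs * vh) / nv)
}

.l2Grad <- function(q, S, R, tau2, wantGrad = TRUE) {
  cst <- 1 / (2 * R^2 * tau2)
  value <- 0
  dq <- if (wantGrad) matrix(0, nrow(q), 2L) else NULL
  rows <- function(r) ((r - 1L) * S + 1L):(r * S)
  for (r in seq_len(R)) for (r2 in seq_len(r)) for (k in 1:2) {
    u <- q[rows(r), k]
    v <- q[rows(r2), k]
    w <- 1 - v
    cp <- .cosPair(u, v)
    cm <- .cosPair(u, w)
    value <- value - cst * (cp$cos - cm$cos)
    if (wantGrad) {
      dq[rows(r), k] <- dq[rows(r), k] - cst * (cp$du - cm$du)
      # w = 1 - v, so d cos(u,w)/dv = -cm$dv
      dq[rows(r2), k] <- dq[rows(r2), k] - cst * (cp$dv + cm$dv)
    }
  }
  list(value = value, dq = dq)
}

#' Autoencoder reconstruction loss
#'
#' Mean over segments and replicates of the per-base mean squared error
#' between observed and reconstructed coverage.
#'
#' @param m observed coverage array (any shape)
#' @param mhat reconstructed coverage, same shape as \code{m}
#' @return scalar loss value
#' @export
lossAutoencoder <- function(m, mhat) {
  if (!identical(dim(m), dim(mhat)) || length(m) != length(mhat))
    stop("shape mismatch between m and mhat")
  mean((m - mhat)^2)
}

.l3Grad <- function(X, Mhat) {
  list(value = mean((X - Mhat)^2),
       dMhat = 2 * (Mhat - X) / length(X))
}

#' Total training loss
#'
#' Weighted sum of the three component losses; default weights are all 1
#' (the unweighted sum).
#'
#' @param l1 replicate contrastive loss value
#' @param l2 segment-class contrastive loss value
#' @param l3 autoencoder loss value
#' @param weights numeric triple of loss weights
#' @return scalar total loss
#' @export
totalLoss <- function(l1, l2, l3, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(is.finite(c(l1, l2, l3))))
  sum(weights * c(l1, l2, l3))
}
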