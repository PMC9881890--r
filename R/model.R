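#' Construct a contrastive peak-calling model
#'
#' Builds the untrained model state: a dilated 1-d convolutional ResNet
#' encoder (\code{nModules} modules of three basic convolution blocks plus
#' one identity-skip residual block, each followed by a factor-2 average
#' pooling), a final dense map to the \code{embedDim}-dimensional embedding,
#' a two-class softmax head with one hidden layer of width \code{embedDim},
#' and a decoder symmetric to the encoder (dense expansion, mirrored
#' modules with nearest-neighbour upsampling back through the encoder's
#' recorded lengths, final convolution to one channel). Parameters are
#' He-initialised from \code{seed}.
#'
#' @param alpha input segment length in bp (even; default 1000)
#' @param embedDim embedding dimension (default 50)
#' @param kernelSize convolution kernel size (odd; default 31)
#' @param dilation convolution dilation (default 8)
#' @param nModules number of ResNet modules (default 5)
#' @param channels channel width of every convolution (default 8)
#' @param tau1,tau2 temperatures of the two contrastive losses (default 0.5)
#' @param lossWeights optional triple of loss weights (default c(1,1,1))
#' @param seed integer seed for parameter initialisation
#' @return a \code{\link{ContrastModel}}
#' @export
contrastModel <- function(alpha = 1000L, embedDim = 50L, kernelSize = 31L,
                          dilation = 8L, nModules = 5L, channels = 8L,
                          tau1 = 0.5, tau2 = 0.5, lossWeights = c(1, 1, 1),
                          seed = 1L) {
  cfg <- list(alpha = as.integer(alpha), embedDim = as.integer(embedDim),
              kernelSize = as.integer(kernelSize),
              dilation = as.integer(dilation),
              nModules = as.integer(nModules),
              channels = as.integer(channels),
              tau1 = tau1, tau2 = tau2, lossWeights = lossWeights)
  methods::new("ContrastModel", config = cfg,
               params = .initParams(cfg, seed))
}

# S x R x alpha tensor -> (alpha, 1, S*R) input cube, replicate-major
.tensorToCube <- function(x) {
  d <- dim(x)
  array(aperm(x, c(3L, 1L, 2L)), dim = c(d[3L], 1L, d[1L] * d[2L]))
}

# (S*R) x k matrix -> S x R x k array
.unstackSR <- function(m, S, R) array(m, dim = c(S, R, ncol(m)))

.checkTensor <- function(model, x) {
  if (is(x, "PeakSegments")) x <- segTensor(x)
  d <- dim(x)
  if (length(d) != 3L || d[3L] != model@config$alpha)
    stop("input must be an S x R x alpha array with alpha = ",
         model@config$alpha)
  x
}

#' @describeIn contrastModel map a coverage tensor (S x R x alpha array, or
#'   a \code{PeakSegments}) to embeddings (S x R x embedDim array)
#' @param model a \code{ContrastModel}
#' @param x input tensor, \code{PeakSegments}, or embedding array
#' @export
setMethod("encode", "ContrastModel", function(model, x) {
  x <- .checkTensor(model, x)
  S <- dim(x)[1L]; R <- dim(x)[2L]
  E <- .encoderF(model@params, model@config, .tensorToCube(x))$E
  .unstackSR(E, S, R)
})

#' @describeIn contrastModel map embeddings (S x R x embedDim) to two-class
#'   probabilities (S x R x 2, rows summing to 1)
#' @export
setMethod("classify", "ContrastModel", function(model, x) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] != model@config$embedDim)
    stop("input must be an S x R x embedDim array with embedDim = ",
         model@config$embedDim)
  q <- .headF(model@params, .stackSR(x))$q
  .unstackSR(q, d[1L], d[2L])
})

#' @describeIn contrastModel map embeddings back to reconstructed coverage
#'   (S x R x alpha array)
#' @export
setMethod("decode", "ContrastModel", function(model, x) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] != model@config$embedDim)
    stop("input must be an S x R x embedDim array with embedDim = ",
         model@config$embedDim)
  Mhat <- .decoderF(model@params, model@config, .stackSR(x))$Mhat
  # cube (alpha, 1, S*R) -> S x R x alpha
  aperm(array(Mhat, dim = c(model@config$alpha, d[1L], d[2L])),
        c(2L, 3L, 1L))
})

#' Serialise / restore a model
#'
#' Checkpoints carry the configuration, all parameter arrays, and (for a
#' fit) the loss history and resolved peak class, serialised with R's
#' native format.
#'
#' @param model a \code{ContrastModel} or \code{ContrastFit}
#' @param path checkpoint path
#' @return \code{path} invisibly (\code{saveCheckpoint});
#'   the restored object (\code{loadCheckpoint})
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(config = model@config, params = model@params)
  if (is(model, "ContrastFit")) {
    obj$history <- model@history
    obj$peakClass <- model@peakClass
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.null(obj$history))
    methods::new("ContrastFit", config = obj$config, params = obj$params,
                 history = obj$history, peakClass = obj$peakClass)
  else
    methods::new("ContrastModel", config = obj$config, params = obj$params)
}
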