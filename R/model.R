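# The dual-branch convolutional network.
#
# Architecture per branch: `depth` 3x3 convolutions (padding 1) arranged in
# four blocks, each convolution followed by batch normalization and ReLU;
# 2x2 stride-2 max-pooling after the four designated layers takes the input
# from `inputSize` to `inputSize / 16`. At the designated sharing layers the
# layer input is the element-wise sum (or channel concatenation) of BOTH
# branches' previous feature maps, so low-level features are exchanged while
# each branch keeps its own weights (no weight tying: the two timepoints are
# distinct distributions). Each branch flattens and maps to an `fcWidth`
# feature vector (ReLU, then dropout in train mode); the two vectors are
# fused (weighted convex combination, sum, or concatenation) and a linear
# layer + softmax yields the class probabilities, ordered (pCR, non-pCR).
#
# Batch layout: a feature map batch is a (H*W*N x C) matrix ("pixel-major",
# chosen so a padded 3x3 convolution becomes nine shifted GEMMs); sample n
# owns rows (n-1)*H*W + 1 .. n*H*W, pixels column-major within a sample.
# Flattening a sample concatenates channels: flat index
# (channel - 1) * H*W + pixel.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1
.CLASSES <- c("pCR", "non-pCR")

# per-layer channel bookkeeping
.channelPlan <- function(config) {
  chans <- rep(config@channelsPerBlock, config@blockLayout)
  inBase <- c(1L, chans[-config@depth])
  shared <- seq_len(config@depth) %in% config@sharingLayers &
    config@sharing != "none" & config@nBranches == 2L
  inEff <- ifelse(shared & config@sharing == "concat", 2L * inBase, inBase)
  finalSide <- config@inputSize %/% 2L^length(config@poolLayers)
  list(chans = chans, inBase = inBase, inEff = as.integer(inEff),
       shared = shared, flatDim = chans[config@depth] * finalSide^2,
       fusedDim = if (config@nBranches == 1L) config@fcWidth
                  else switch(config@fusion, concat = 2L * config@fcWidth,
                              config@fcWidth))
}

#' Convolution weight layout helpers
#'
#' Convolution weights are stored as `(Cin*9 x Cout)` matrices for the GEMM
#' kernels (row `k*Cin + ci`, `k = 3*(dc+1) + (dr+1)`, zero-based); these
#' helpers convert to and from the natural
#' `array(dim = c(3, 3, Cin, Cout))` form, where element `[dr + 2, dc + 2,
#' ci, co]` is the tap applied to input channel `ci` at spatial offset
#' `(dr, dc)`.
#'
#' @param arr a `3 x 3 x Cin x Cout` array.
#' @param mat a `(Cin*9 x Cout)` weight matrix.
#' @return `convWeightMatrix()` returns the matrix form;
#'   `convWeightArray()` the array form.
#' @export
convWeightMatrix <- function(arr) {
  stopifnot(length(dim(arr)) == 4L, dim(arr)[1] == 3L, dim(arr)[2] == 3L)
  matrix(aperm(arr, c(3, 1, 2, 4)), nrow = 9L * dim(arr)[3])
}

#' @rdname convWeightMatrix
#' @param cin number of input channels of the layer.
#' @export
convWeightArray <- function(mat, cin) {
  cout <- ncol(mat)
  stopifnot(nrow(mat) == 9L * cin)
  aperm(array(mat, dim = c(cin, 3, 3, cout)), c(2, 3, 1, 4))
}

#' Build a dual-branch model
#'
#' Instantiates both branches with independent parameters: He-normal
#' convolution and fully connected weights, zero biases, unit-gamma /
#' zero-beta batch norm with running mean 0 and variance 1. Identical seeds
#' give identical initializations.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for the initialization draw.
#' @return A [DBNNModel-class] in `"train"` mode.
#' @examples
#' m <- buildModel(ModelConfig(channelsPerBlock = c(4, 8, 8, 8),
#'                             fcWidth = 16, inputSize = 16), seed = 1)
#' architectureSummary(m)$convLayerCount
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  plan <- .channelPlan(config)
  .withSeed(seed, {
    branches <- lapply(seq_len(config@nBranches), function(b) {
      conv <- lapply(seq_len(config@depth), function(i) {
        cin9 <- plan$inEff[i] * 9L
        cout <- plan$chans[i]
        list(W = matrix(rnorm(cout * cin9, sd = sqrt(2 / cin9)), cin9, cout),
             b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout))
      })
      fc <- list(W = matrix(rnorm(config@fcWidth * plan$flatDim,
                                  sd = sqrt(2 / plan$flatDim)),
                            config@fcWidth, plan$flatDim),
                 b = numeric(config@fcWidth))
      list(conv = conv, fc = fc)
    })
    head <- list(W = matrix(rnorm(config@nClasses * plan$fusedDim,
                                  sd = sqrt(2 / plan$fusedDim)),
                            config@nClasses, plan$fusedDim),
                 b = numeric(config@nClasses))
    state <- list(branches = lapply(seq_len(config@nBranches), function(b) {
      list(conv = lapply(seq_len(config@depth), function(i) {
        list(mean = numeric(plan$chans[i]), var = rep(1, plan$chans[i]))
      }))
    }))
    new("DBNNModel", config = config,
        params = list(branches = branches, head = head),
        state = state, mode = "train")
  })
}

#' Switch a model between train and eval mode
#'
#' Eval mode uses batch-norm running statistics and disables dropout, making
#' forward passes deterministic.
#'
#' @param model a [DBNNModel-class].
#' @return The model with its mode flag switched.
#' @export
evalMode <- function(model) { model@mode <- "eval"; model }

#' @rdname evalMode
#' @export
trainMode <- function(model) { model@mode <- "train"; model }

# pack a list of HxW matrices into the (H*W*N x 1) batch layout
.packBatch <- function(imgs, side) {
  for (im in imgs) {
    if (!is.matrix(im) || nrow(im) != side || ncol(im) != side) {
      stop(sprintf("input images must be %dx%d matrices", side, side),
           call. = FALSE)
    }
  }
  matrix(unlist(imgs, use.names = FALSE), ncol = 1L)
}

# (HW*N x C) activation -> (HW*C x N) per-sample flat features, and back
.flattenBatch <- function(A, HW, N) {
  C <- ncol(A)
  dim(A) <- c(HW, N, C)
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(HW * C, N)
  A
}

.unflattenBatch <- function(F0, HW, N) {
  C <- nrow(F0) / HW
  dim(F0) <- c(HW, C, N)
  F0 <- aperm(F0, c(1, 3, 2))
  dim(F0) <- c(HW * N, C)
  F0
}

.asBatchList <- function(x) {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  }
  if (is.list(x)) return(x)
  stop("batch must be a matrix, a HxWxN array, or a list of matrices",
       call. = FALSE)
}

# Full forward pass. `inputs`: list of per-branch (H*W*N x 1) matrices.
# Returns probs (N x 2), logp, the batch-norm state after the pass, and
# (optionally) the cache needed by the backward pass.
.forwardInternal <- function(model, inputs, train = FALSE,
                             keepCache = FALSE) {
  cfg <- model@config
  plan <- .channelPlan(cfg)
  nb <- cfg@nBranches
  H <- cfg@inputSize; W <- cfg@inputSize
  N <- nrow(inputs[[1]]) / (H * W)
  A <- inputs
  state <- model@state
  cache <- if (keepCache) list(layers = vector("list", cfg@depth)) else NULL
  for (i in seq_len(cfg@depth)) {
    lcache <- if (keepCache) list(H = H, W = W) else NULL
    if (plan$shared[i]) {
      Zin <- if (cfg@sharing == "sum") A[[1]] + A[[2]] else cbind(A[[1]], A[[2]])
      Xin <- list(Zin, Zin)
    } else {
      Xin <- A
    }
    newA <- vector("list", nb)
    for (b in seq_len(nb)) {
      p <- model@params$branches[[b]]$conv[[i]]
      S <- .conv3x3Forward(Xin[[b]], H, W, N, p$W, p$b)
      if (train) {
        bs <- .bnStats(S)
        mu <- as.numeric(bs$mean)
        v <- as.numeric(bs$var)
        st <- state$branches[[b]]$conv[[i]]
        st$mean <- (1 - .BN_MOMENTUM) * st$mean + .BN_MOMENTUM * mu
        st$var <- (1 - .BN_MOMENTUM) * st$var + .BN_MOMENTUM * v
        state$branches[[b]]$conv[[i]] <- st
      } else {
        st <- state$branches[[b]]$conv[[i]]
        mu <- st$mean
        v <- st$var
      }
      invstd <- 1 / sqrt(v + .BN_EPS)
      br <- .bnReluForward(S, mu, invstd, p$gamma, p$beta)
      if (keepCache) {
        lcache$branch[[b]] <- list(Xin = Xin[[b]], xhat = br$xhat,
                                   invstd = invstd, act = br$act)
      }
      newA[[b]] <- br$act
    }
    if (i %in% cfg@poolLayers) {
      for (b in seq_len(nb)) {
        pr <- .maxpool2Forward(newA[[b]], H, W, N)
        newA[[b]] <- pr$Y
        if (keepCache) lcache$branch[[b]]$argmax <- pr$argmax
      }
      H <- H %/% 2L; W <- W %/% 2L
    }
    A <- newA
    if (keepCache) cache$layers[[i]] <- lcache
  }
  # flatten + fully connected per branch
  feat <- vector("list", nb)
  for (b in seq_len(nb)) {
    F0 <- .flattenBatch(A[[b]], H * W, N)
    p <- model@params$branches[[b]]$fc
    pre <- p$W %*% F0 + p$b
    f <- pre * (pre > 0)
    drop <- NULL
    if (train && cfg@dropoutRate > 0) {
      drop <- (matrix(runif(length(f)), nrow(f), ncol(f)) >=
                 cfg@dropoutRate) / (1 - cfg@dropoutRate)
      f <- f * drop
    }
    if (keepCache) {
      cache$fc[[b]] <- list(F0 = F0, mask = (pre > 0), drop = drop)
    }
    feat[[b]] <- f
  }
  fused <- if (nb == 1L) feat[[1]]
           else switch(cfg@fusion,
                       weighted = cfg@alpha * feat[[1]] + cfg@beta * feat[[2]],
                       sum = feat[[1]] + feat[[2]],
                       concat = rbind(feat[[1]], feat[[2]]))
  hp <- model@params$head
  logits <- hp$W %*% fused + hp$b
  mx <- apply(logits, 2, max)
  z <- logits - rep(mx, each = nrow(logits))
  lse <- log(colSums(exp(z)))
  logp <- z - rep(lse, each = nrow(z))
  probs <- t(exp(logp))
  colnames(probs) <- .CLASSES
  if (keepCache) {
    cache$fused <- fused
    cache$feat <- feat
    cache$N <- N
  }
  list(probs = probs, logp = t(logp), state = state, cache = cache,
       features = feat)
}

# Backward pass for the mean cross-entropy over the batch.
# `targets` is an N x 2 soft-label matrix. Returns gradients shaped like
# model@params. Assumes the forward ran in train mode with keepCache = TRUE.
.backwardInternal <- function(model, fwd, targets) {
  cfg <- model@config
  plan <- .channelPlan(cfg)
  nb <- cfg@nBranches
  cache <- fwd$cache
  N <- cache$N
  grads <- list(branches = vector("list", nb), head = NULL)
  dlogits <- t(fwd$probs - targets) / N  # 2 x N
  grads$head <- list(W = dlogits %*% t(cache$fused), b = rowSums(dlogits))
  dfused <- t(model@params$head$W) %*% dlogits
  dfeat <- if (nb == 1L) list(dfused)
           else switch(cfg@fusion,
                       weighted = list(cfg@alpha * dfused, cfg@beta * dfused),
                       sum = list(dfused, dfused),
                       concat = list(dfused[seq_len(cfg@fcWidth), , drop = FALSE],
                                     dfused[cfg@fcWidth + seq_len(cfg@fcWidth), ,
                                            drop = FALSE]))
  dA <- vector("list", nb)
  for (b in seq_len(nb)) {
    fcc <- cache$fc[[b]]
    df <- dfeat[[b]]
    if (!is.null(fcc$drop)) df <- df * fcc$drop
    dpre <- df * fcc$mask
    p <- model@params$branches[[b]]$fc
    grads$branches[[b]]$fc <- list(W = dpre %*% t(fcc$F0), b = rowSums(dpre))
    dF0 <- t(p$W) %*% dpre
    lastSide <- cfg@inputSize %/% 2L^length(cfg@poolLayers)
    dA[[b]] <- .unflattenBatch(dF0, lastSide * lastSide, N)
    grads$branches[[b]]$conv <- vector("list", cfg@depth)
  }
  for (i in rev(seq_len(cfg@depth))) {
    lc <- cache$layers[[i]]
    H <- lc$H; W <- lc$W
    dXin <- vector("list", nb)
    for (b in seq_len(nb)) {
      bc <- lc$branch[[b]]
      dOut <- dA[[b]]
      if (i %in% cfg@poolLayers) {
        dOut <- .maxpool2Backward(dOut, bc$argmax, H, W, N)
      }
      p <- model@params$branches[[b]]$conv[[i]]
      bb <- .bnReluBackward(dOut, bc$act, bc$xhat, bc$invstd, p$gamma,
                            train = TRUE)
      cb <- .conv3x3Backward(bb$dS, bc$Xin, H, W, N, p$W,
                             needInputGrad = i > 1L)
      grads$branches[[b]]$conv[[i]] <- list(
        W = cb$dW, b = as.numeric(cb$db),
        gamma = as.numeric(bb$dgamma), beta = as.numeric(bb$dbeta))
      dXin[[b]] <- cb$dX
    }
    if (i > 1L) {
      if (plan$shared[i]) {
        if (cfg@sharing == "sum") {
          dZ <- dXin[[1]] + dXin[[2]]
          dA <- list(dZ, dZ)
        } else {
          cPrev <- plan$inBase[i]
          dZ <- dXin[[1]] + dXin[[2]]
          dA <- list(dZ[, seq_len(cPrev), drop = FALSE],
                     dZ[, cPrev + seq_len(cPrev), drop = FALSE])
        }
      } else {
        dA <- dXin
      }
    }
  }
  grads
}

#' Run the network forward on paired batches
#'
#' Respects the model's mode: in train mode batch statistics and dropout are
#' used (the returned probabilities are then stochastic); in eval mode the
#' pass is deterministic.
#'
#' @param model a [DBNNModel-class].
#' @param preBatch pre-treatment images: a matrix, an H x W x N array, or a
#'   list of matrices.
#' @param postBatch post-cycle-1 images, same size as `preBatch`; omit for
#'   single-branch models.
#' @return An N x 2 matrix of class probabilities, columns `pCR`, `non-pCR`;
#'   rows sum to 1.
#' @examples
#' cfg <- ModelConfig(channelsPerBlock = c(2, 2, 2, 2), fcWidth = 4,
#'                    inputSize = 16)
#' m <- evalMode(buildModel(cfg, seed = 1))
#' img <- matrix(runif(256), 16, 16)
#' rowSums(forwardPass(m, img, img))
#' @export
forwardPass <- function(model, preBatch, postBatch = NULL) {
  stopifnot(is(model, "DBNNModel"))
  cfg <- model@config
  side <- cfg@inputSize
  pre <- .asBatchList(preBatch)
  inputs <- list(.packBatch(pre, side))
  if (cfg@nBranches == 2L) {
    if (is.null(postBatch)) {
      stop("a dual-branch model needs both preBatch and postBatch",
           call. = FALSE)
    }
    post <- .asBatchList(postBatch)
    if (length(post) != length(pre)) {
      stop(sprintf("batch sizes differ: %d pre vs %d post images",
                   length(pre), length(post)), call. = FALSE)
    }
    inputs <- c(inputs, list(.packBatch(post, side)))
  }
  for (x in inputs) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("input intensities must be finite and in [0, 1]", call. = FALSE)
    }
  }
  fwd <- .forwardInternal(model, inputs, train = identical(model@mode, "train"))
  if (any(!is.finite(fwd$probs))) {
    stop("non-finite activations in the forward pass", call. = FALSE)
  }
  fwd$probs
}

#' Extract a branch's fully connected feature vector
#'
#' Returns F(X) (pre-treatment branch) or F(Y) (post-cycle-1 branch) before
#' fusion weighting, in eval mode. When feature sharing is enabled the
#' branches are not independent, so the companion stage image is required.
#'
#' @param model a [DBNNModel-class] in eval mode.
#' @param image the image of the requested branch.
#' @param branch `"pre"` or `"post"`.
#' @param companion the other stage's image (required unless
#'   `sharing == "none"` or the model is single-branch).
#' @return A numeric vector of length `fcWidth`.
#' @export
branchFeatures <- function(model, image, branch = c("pre", "post"),
                           companion = NULL) {
  stopifnot(is(model, "DBNNModel"))
  branch <- match.arg(branch)
  if (!identical(model@mode, "eval")) {
    stop("branchFeatures requires eval mode (see evalMode())", call. = FALSE)
  }
  cfg <- model@config
  side <- cfg@inputSize
  if (cfg@nBranches == 1L) {
    fwd <- .forwardInternal(model, list(.packBatch(list(image), side)))
    return(as.numeric(fwd$features[[1]]))
  }
  if (is.null(companion)) {
    if (cfg@sharing != "none") {
      stop("with feature sharing enabled the companion image is required: ",
           "branch features are not branch-local", call. = FALSE)
    }
    companion <- matrix(0, side, side)
  }
  imgs <- if (branch == "pre") list(image, companion) else
    list(companion, image)
  fwd <- .forwardInternal(model, list(.packBatch(imgs[1], side),
                                      .packBatch(imgs[2], side)))
  as.numeric(fwd$features[[if (branch == "pre") 1L else 2L]])
}

#' Summarize a model's architecture
#'
#' Counts are derived by traversing the parameter arrays (not echoed from
#' the configuration): convolution layers and per-layer channels from the
#' weight shapes, the pool count from the spatial size implied by the fully
#' connected fan-in, the fused dimension from the classifier fan-in.
#'
#' @param model a [DBNNModel-class].
#' @return A list with `convLayerCount`, `poolCount`, `blockCount`,
#'   `channels`, `fusedFeatureDim`, `totalParameterCount`.
#' @export
architectureSummary <- function(model) {
  stopifnot(is(model, "DBNNModel"))
  br <- model@params$branches[[1]]
  channels <- vapply(br$conv, function(l) ncol(l$W), integer(1))
  flatDim <- ncol(br$fc$W)
  lastC <- channels[length(channels)]
  finalSide <- sqrt(flatDim / lastC)
  poolCount <- as.integer(round(log2(model@config@inputSize / finalSide)))
  nParams <- sum(vapply(rapply(model@params, length, how = "unlist"),
                        identity, numeric(1)))
  list(convLayerCount = length(channels),
       poolCount = poolCount,
       blockCount = length(rle(channels)$lengths),
       channels = channels,
       fusedFeatureDim = ncol(model@params$head$W),
       totalParameterCount = as.numeric(nParams))
}

# one-hot (or pass-through soft) labels, ordered (pCR, non-pCR)
.softLabels <- function(labels) {
  if (is.matrix(labels)) {
    stopifnot(ncol(labels) == 2L)
    return(labels)
  }
  if (is.list(labels)) {
    return(do.call(rbind, lapply(labels, function(l) {
      if (is.numeric(l)) l else c(l == "pCR", l == "non-pCR") * 1
    })))
  }
  cbind(pCR = as.numeric(labels == "pCR"),
        `non-pCR` = as.numeric(labels == "non-pCR"))
}
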