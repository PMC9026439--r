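# Shared fixtures and independent brute-force oracles used across the suite.

# A small but fully featured model configuration (16x16 inputs, 4 layers,
# all four pooling stages) for oracle and gradient checks.
tinyConfig <- function(sharing = "sum", fusion = "weighted",
                       alpha = 0.2, beta = 0.8, dropoutRate = 0,
                       channels = c(2L, 3L, 2L, 2L), fcWidth = 5L) {
  ModelConfig(depth = 4L, blockLayout = c(1L, 1L, 1L, 1L),
              channelsPerBlock = channels, sharing = sharing,
              sharingLayers = c(2L, 4L), poolLayers = c(1L, 2L, 3L, 4L),
              fcWidth = fcWidth, dropoutRate = dropoutRate, fusion = fusion,
              alpha = alpha, beta = beta, inputSize = 16L)
}

# give a model non-trivial batch-norm state and affine parameters so that
# eval-mode normalization actually does something
randomizeBnState <- function(model) {
  for (b in seq_along(model@params$branches)) {
    for (i in seq_along(model@params$branches[[b]]$conv)) {
      nC <- length(model@state$branches[[b]]$conv[[i]]$mean)
      model@state$branches[[b]]$conv[[i]]$mean <- rnorm(nC, 0, 0.2)
      model@state$branches[[b]]$conv[[i]]$var <- runif(nC, 0.5, 2)
      model@params$branches[[b]]$conv[[i]]$gamma <- runif(nC, 0.5, 1.5)
      model@params$branches[[b]]$conv[[i]]$beta <- rnorm(nC, 0, 0.1)
    }
  }
  model
}

# Brute-force eval-mode forward pass by direct summation: nested loops over
# kernel taps, explicit batch-norm, ReLU, pooling, flattening, fc, fusion
# and softmax. Completely independent of the package's batched GEMM path.
oracleForward <- function(model, imgs) {
  cfg <- model@config
  chans <- rep(cfg@channelsPerBlock, cfg@blockLayout)
  nb <- cfg@nBranches
  A <- lapply(imgs, function(im) array(im, dim = c(nrow(im), ncol(im), 1)))
  H <- cfg@inputSize; W <- cfg@inputSize
  for (i in seq_len(cfg@depth)) {
    shared <- i %in% cfg@sharingLayers && cfg@sharing != "none" && nb == 2
    if (shared) {
      if (cfg@sharing == "sum") {
        Z <- A[[1]] + A[[2]]
      } else {
        Z <- array(0, dim = c(H, W, dim(A[[1]])[3] * 2))
        Z[, , seq_len(dim(A[[1]])[3])] <- A[[1]]
        Z[, , dim(A[[1]])[3] + seq_len(dim(A[[2]])[3])] <- A[[2]]
      }
      Xin <- list(Z, Z)
    } else Xin <- A
    newA <- vector("list", nb)
    for (b in seq_len(nb)) {
      p <- model@params$branches[[b]]$conv[[i]]
      cin <- dim(Xin[[b]])[3]
      Warr <- convWeightArray(p$W, cin)
      out <- array(0, dim = c(H, W, chans[i]))
      for (co in seq_len(chans[i])) {
        acc <- matrix(p$b[co], H, W)
        for (ci in seq_len(cin)) for (dr in -1:1) for (dc in -1:1) {
          for (r in 1:H) for (cl in 1:W) {
            sr <- r + dr; sc <- cl + dc
            if (sr >= 1 && sr <= H && sc >= 1 && sc <= W)
              acc[r, cl] <- acc[r, cl] +
                Warr[dr + 2, dc + 2, ci, co] * Xin[[b]][sr, sc, ci]
          }
        }
        st <- model@state$branches[[b]]$conv[[i]]
        xh <- (acc - st$mean[co]) / sqrt(st$var[co] + 1e-5)
        out[, , co] <- pmax(p$gamma[co] * xh + p$beta[co], 0)
      }
      newA[[b]] <- out
    }
    if (i %in% cfg@poolLayers) {
      for (b in seq_len(nb)) {
        H2 <- H / 2; W2 <- W / 2
        pooled <- array(0, dim = c(H2, W2, chans[i]))
        for (co in seq_len(chans[i])) for (r in 1:H2) for (cl in 1:W2) {
          pooled[r, cl, co] <-
            max(newA[[b]][(2 * r - 1):(2 * r), (2 * cl - 1):(2 * cl), co])
        }
        newA[[b]] <- pooled
      }
      H <- H / 2; W <- W / 2
    }
    A <- newA
  }
  feats <- vector("list", nb)
  for (b in seq_len(nb)) {
    C <- dim(A[[b]])[3]
    flat <- numeric(H * W * C)
    for (cl in 1:W) for (r in 1:H) for (co in 1:C) {
      p <- (cl - 1) * H + r
      flat[(co - 1) * H * W + p] <- A[[b]][r, cl, co]
    }
    fc <- model@params$branches[[b]]$fc
    feats[[b]] <- pmax(as.numeric(fc$W %*% flat + fc$b), 0)
  }
  fused <- if (nb == 1) feats[[1]] else switch(cfg@fusion,
    weighted = cfg@alpha * feats[[1]] + cfg@beta * feats[[2]],
    sum = feats[[1]] + feats[[2]],
    concat = c(feats[[1]], feats[[2]]))
  hd <- model@params$head
  lg <- as.numeric(hd$W %*% fused + hd$b)
  e <- exp(lg - max(lg))
  e / sum(e)
}

# O(H*W*k^2) per-pixel neighbourhood median with half-sample reflection
bruteMedian <- function(img, k) {
  H <- nrow(img); W <- ncol(img); h <- (k - 1) / 2
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- img
  for (r in 1:H) for (cl in 1:W) {
    vals <- numeric(0)
    for (dr in -h:h) for (dc in -h:h) {
      vals <- c(vals, img[refl(r + dr, H), refl(cl + dc, W)])
    }
    out[r, cl] <- median(vals)
  }
  out
}

# AUC by exhaustive pair enumeration
brutePairAuc <- function(scores, labels) {
  pos <- scores[labels == "pCR"]
  neg <- scores[labels != "pCR"]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# build a split manifest table directly (no images on disk needed)
makeManifestTable <- function(nPcrPairs, nNonPairs, split = "train",
                              framesPerPatient = 4L) {
  rows <- list()
  addClass <- function(label, nPairs, prefix) {
    nPat <- ceiling(nPairs / framesPerPatient)
    left <- nPairs
    for (i in seq_len(nPat)) {
      nf <- min(framesPerPatient, left)
      left <- left - nf
      for (f in seq_len(nf)) for (stage in c("pre", "post1")) {
        rows[[length(rows) + 1L]] <<- data.frame(
          patient_id = sprintf("%s%03d", prefix, i), label = label,
          stage = stage, frame_index = f - 1L,
          path = sprintf("%s%03d_%s_%d.pgm", prefix, i, stage, f),
          split = split, stringsAsFactors = FALSE)
      }
    }
  }
  addClass("pCR", nPcrPairs, "CP")
  addClass("non-pCR", nNonPairs, "CN")
  do.call(rbind, rows)
}

# tiny rendered dataset on disk for end-to-end structural tests
makeTinyDataset <- function(nPatients = 8L, seed = 1L,
                            framesPerPatient = c(2L, 2L)) {
  cfg <- SyntheticConfig(nPatients = nPatients, pcrFraction = 0.4,
                         framesPerPatient = framesPerPatient,
                         imageSize = 16L, lesionRadiusRange = c(2, 4),
                         pcrShrinkageRange = c(0, 0.3),
                         nonpcrShrinkageRange = c(0.8, 1.1), seed = seed)
  dir <- file.path(tempdir(), sprintf("tinyds_%d_%d", nPatients, seed))
  if (!dir.exists(dir)) {
    synthesizeDataset(cfg, dir, trainFraction = 0.75)
  } else {
    readManifest(file.path(dir, "manifest.csv"))
  }
}

tinyTrainSetup <- function(seed = 1L) {
  list(manifest = makeTinyDataset(seed = seed),
       config = ModelConfig(channelsPerBlock = c(2L, 2L, 2L, 2L),
                            fcWidth = 8L, inputSize = 16L),
       hp = Hyperparams(epochs = 1L, seed = seed))
}
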