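# Training: minibatch cross-entropy with Adam, per-epoch reshuffling, full
# seed control, optional patient-level validation monitor.

.treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      out[[i]] <- .treeMap2(f, a[[i]], bi)
    }
    return(out)
  }
  f(a, b)
}

.treeMap3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- a
    nms <- names(a)
    for (i in seq_along(a)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      out[[i]] <- .treeMap3(f, a[[i]], b[[key]], c[[key]])
    }
    return(out)
  }
  f(a, b, c)
}

.zeroLike <- function(tree) rapply(tree, function(x) x * 0, how = "replace")

# assemble packed network inputs + soft labels from a list of samples
.batchInputs <- function(samples, side, stage = "both") {
  pres <- lapply(samples, `[[`, "pre")
  posts <- lapply(samples, `[[`, "post")
  inputs <- switch(stage,
                   both = list(.packBatch(pres, side), .packBatch(posts, side)),
                   pre = list(.packBatch(pres, side)),
                   post = list(.packBatch(posts, side)))
  labels <- lapply(samples, `[[`, "label")
  list(inputs = inputs, Y = .softLabels(labels))
}

.checkStage <- function(model, stage) {
  nb <- model@config@nBranches
  if (nb == 2L && stage != "both") {
    stop("a dual-branch model consumes both stages; use stage = 'both'",
         call. = FALSE)
  }
  if (nb == 1L && stage == "both") {
    stop("a single-branch model needs stage = 'pre' or 'post'", call. = FALSE)
  }
}

#' Train a model
#'
#' Minibatch gradient descent on the mean cross-entropy (soft labels
#' accepted), Adam with default moments (0.9, 0.999), constant learning
#' rate, per-epoch reshuffling. Everything random (shuffling, dropout,
#' augmentation draws, Mixup) is governed by `hp@seed`, so identical calls
#' produce identical models. The trained model is returned in eval mode.
#'
#' @param model a [DBNNModel-class] (as built; mode is managed internally).
#' @param manifest a manifest with a nonempty `train` split.
#' @param hp a [Hyperparams-class].
#' @param augment an [AugmentConfig-class]; `"geometric"` draws a fresh
#'   transform per sample per epoch, `"mixup"` mixes each batch with a
#'   shuffled copy of itself, `"upsample_minority"` expects the manifest to
#'   have been balanced with [upsampleMinority()] first (flagged duplicate
#'   rows are transformed at load time).
#' @param baseDir optional base directory for relative manifest paths.
#' @param stage which stage feeds the network: `"both"` (dual-branch
#'   default), `"pre"` or `"post"` for single-branch models.
#' @param verbose print per-epoch losses.
#' @return A list with `model` (trained, eval mode) and `curve`, a
#'   `data.frame` with columns `epoch`, `train_loss` and (when
#'   `valFraction > 0`) `val_loss`.
#' @export
trainModel <- function(model, manifest, hp, augment = AugmentConfig(),
                       baseDir = NULL, stage = c("both", "pre", "post"),
                       verbose = FALSE) {
  stopifnot(is(model, "DBNNModel"), is(hp, "Hyperparams"))
  validObject(hp)
  stage <- match.arg(stage)
  .checkStage(model, stage)
  samples <- loadPairedSamples(manifest, "train", baseDir, augment = augment)
  side <- model@config@inputSize
  valSamples <- NULL
  if (hp@valFraction > 0) {
    pats <- unique(vapply(samples, `[[`, "", "patient_id"))
    nVal <- max(1L, as.integer(.roundHalfUp(hp@valFraction * length(pats), 0)))
    valPats <- .withSeed(.childSeed(hp@seed, 11L), sample(pats, nVal))
    isVal <- vapply(samples, function(s) s$patient_id %in% valPats, logical(1))
    valSamples <- samples[isVal]
    samples <- samples[!isVal]
  }
  if (length(samples) == 0L) stop("empty training split", call. = FALSE)
  if (hp@epochs == 0L) {
    return(list(model = evalMode(model),
                curve = data.frame(epoch = integer(0),
                                   train_loss = numeric(0))))
  }
  model <- trainMode(model)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  mTree <- .zeroLike(model@params)
  vTree <- .zeroLike(model@params)
  tStep <- 0L
  n <- length(samples)
  trainLoss <- numeric(hp@epochs)
  valLoss <- rep(NA_real_, hp@epochs)
  doGeom <- identical(augment@strategy, "geometric")
  doMixup <- identical(augment@strategy, "mixup")
  .withSeed(.childSeed(hp@seed, 13L), {
    for (epoch in seq_len(hp@epochs)) {
      ord <- sample.int(n)
      lossSum <- 0
      for (start in seq(1L, n, by = hp@batchSize)) {
        idx <- ord[start:min(start + hp@batchSize - 1L, n)]
        batch <- samples[idx]
        if (doGeom) batch <- lapply(batch, geometricAugment, config = augment)
        if (doMixup && length(batch) > 1L) {
          lam <- rbeta(1, augment@mixupAlpha, augment@mixupAlpha)
          perm <- sample.int(length(batch))
          batch <- lapply(seq_along(batch), function(j) {
            mixupSamples(batch[[j]], batch[[perm[j]]], lam)
          })
        }
        bi <- .batchInputs(batch, side, stage)
        fwd <- .forwardInternal(model, bi$inputs, train = TRUE,
                                keepCache = TRUE)
        loss <- -mean(rowSums(bi$Y * fwd$logp))
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        model@state <- fwd$state
        grads <- .backwardInternal(model, fwd, bi$Y)
        tStep <- tStep + 1L
        mTree <- .treeMap2(function(m, g) b1 * m + (1 - b1) * g, mTree, grads)
        vTree <- .treeMap2(function(v, g) b2 * v + (1 - b2) * g * g,
                           vTree, grads)
        c1 <- 1 - b1^tStep; c2 <- 1 - b2^tStep
        lr <- hp@learningRate
        model@params <- .treeMap3(function(p, m, v) {
          p - lr * (m / c1) / (sqrt(v / c2) + aeps)
        }, model@params, mTree, vTree)
        lossSum <- lossSum + loss * length(idx)
      }
      trainLoss[epoch] <- lossSum / n
      if (!is.null(valSamples) && length(valSamples) > 0L) {
        valLoss[epoch] <- evaluateLoss(evalMode(model), valSamples,
                                       stage = stage)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f%s", epoch, trainLoss[epoch],
                        if (is.na(valLoss[epoch])) "" else
                          sprintf("  val %.4f", valLoss[epoch])))
      }
    }
  })
  curve <- data.frame(epoch = seq_len(hp@epochs), train_loss = trainLoss)
  if (!is.null(valSamples)) curve$val_loss <- valLoss
  list(model = evalMode(model), curve = curve)
}

#' Mean cross-entropy of a model on a sample set
#'
#' Evaluates `-sum(y * log p)` averaged over samples, in eval mode, with no
#' parameter updates. Soft labels (from Mixup) are accepted.
#'
#' @param model a [DBNNModel-class].
#' @param samples a nonempty list of paired samples (see
#'   [loadPairedSamples()]).
#' @param stage `"both"`, `"pre"` or `"post"` (must match the model).
#' @return The mean cross-entropy (natural log).
#' @export
evaluateLoss <- function(model, samples, stage = c("both", "pre", "post")) {
  stopifnot(is(model, "DBNNModel"))
  stage <- match.arg(stage)
  .checkStage(model, stage)
  if (!is.list(samples) || length(samples) == 0L) {
    stop("'samples' must be a nonempty list", call. = FALSE)
  }
  model <- evalMode(model)
  side <- model@config@inputSize
  total <- 0
  for (start in seq(1L, length(samples), by = 64L)) {
    chunk <- samples[start:min(start + 63L, length(samples))]
    bi <- .batchInputs(chunk, side, stage)
    fwd <- .forwardInternal(model, bi$inputs, train = FALSE)
    total <- total + sum(-rowSums(bi$Y * fwd$logp))
  }
  total / length(samples)
}
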