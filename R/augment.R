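# Class-imbalance augmentation: geometric transforms, Mixup, minority
# upsampling. A geometric draw is applied IDENTICALLY to both stage images
# of a pair, preserving the cross-stage correspondence the dual-branch
# architecture exploits.

# Rotation convention: a positive angle rotates the content counterclockwise
# (rows increase downward); output pixel t takes the value at
# c + R(-theta) (t - c) / zoom, sampled bilinearly with half-sample
# reflection outside the image. Flips are exact index reversals applied
# before rotation/zoom.
.geomTransform <- function(img, angleDeg = 0, zoom = 1, hflip = FALSE,
                           vflip = FALSE) {
  if (hflip) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (vflip) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  if (angleDeg == 0 && zoom == 1) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angleDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  ccR <- (H + 1) / 2; ccC <- (W + 1) / 2
  u <- matrix(seq_len(H), H, W) - ccR
  v <- matrix(seq_len(W), H, W, byrow = TRUE) - ccC
  srcR <- ccR + (ct * u + st * v) / zoom
  srcC <- ccC + (-st * u + ct * v) / zoom
  out <- matrix(.bilinearSample(img, as.vector(srcR), as.vector(srcC)), H, W)
  .clip01(out)
}

#' Apply one random geometric transform to a paired sample
#'
#' Draws ONE rotation/flip/zoom combination from the configured ranges and
#' applies it identically to both stage images; the label is unchanged.
#' Uses the caller's RNG state (seed beforehand for reproducibility).
#'
#' @param sample a paired sample (fields `pre`, `post`, `label`, ...).
#' @param config an [AugmentConfig-class] providing `rotationRange`,
#'   flip toggles and `zoomRange`.
#' @return The transformed sample, same image dimensions, intensities still
#'   in `[0, 1]`.
#' @export
geometricAugment <- function(sample, config = AugmentConfig("geometric")) {
  stopifnot(is.list(sample), is(config, "AugmentConfig"))
  angle <- if (config@rotationRange > 0)
    runif(1, -config@rotationRange, config@rotationRange) else 0
  zoom <- runif(1, config@zoomRange[1], config@zoomRange[2])
  hflip <- config@allowHorizontalFlip && runif(1) < 0.5
  vflip <- config@allowVerticalFlip && runif(1) < 0.5
  sample$pre <- .geomTransform(sample$pre, angle, zoom, hflip, vflip)
  sample$post <- .geomTransform(sample$post, angle, zoom, hflip, vflip)
  sample
}

#' Mix two paired samples (Mixup)
#'
#' Convex combination of both stage images with the SAME lambda, and of the
#' one-hot labels: `label = lambda * onehot(a) + (1 - lambda) * onehot(b)`,
#' ordered (pCR, non-pCR). The training loss accepts the resulting soft
#' labels.
#'
#' @param a,b paired samples with equal image dimensions.
#' @param lambda mixing weight in `[0, 1]`.
#' @return The mixed sample; at `lambda` 1 (or 0) the original sample `a`
#'   (or `b`) is returned exactly, hard label included.
#' @export
mixupSamples <- function(a, b, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("'lambda' must lie in [0, 1]", call. = FALSE)
  }
  if (lambda == 1) return(a)
  if (lambda == 0) return(b)
  if (!identical(dim(a$pre), dim(b$pre))) {
    stop("samples must share image dimensions", call. = FALSE)
  }
  ya <- drop(.softLabels(list(a$label)))
  yb <- drop(.softLabels(list(b$label)))
  out <- a
  out$pre <- lambda * a$pre + (1 - lambda) * b$pre
  out$post <- lambda * a$post + (1 - lambda) * b$post
  out$label <- lambda * ya + (1 - lambda) * yb
  names(out$label) <- .CLASSES
  out
}

#' Balance the training split by upsampling the minority class
#'
#' Appends duplicated minority-class pairs (new rows with fresh
#' `frame_index` values and an `augment_seed` flag) until per-class pair
#' counts in the training split are equal. Duplicates are re-rendered
#' through a seeded geometric transform when loaded (see
#' [loadPairedSamples()]). The test split is untouched and every original
#' row survives.
#'
#' @param manifest a manifest `data.frame` with a nonempty train split.
#' @param config an [AugmentConfig-class] describing the transforms drawn
#'   for the duplicates (used at load time).
#' @param seed integer seed for duplicate selection and their transforms.
#' @return The augmented manifest.
#' @export
upsampleMinority <- function(manifest, config = AugmentConfig("geometric"),
                             seed = 1L) {
  validateManifest(manifest)
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(tr) == 0L) stop("empty training split", call. = FALSE)
  pairs <- tr[tr$stage == "pre", c("patient_id", "frame_index", "label")]
  counts <- table(factor(pairs$label, levels = c("pCR", "non-pCR")))
  if (any(counts == 0L)) {
    stop("both classes must be present in the training split", call. = FALSE)
  }
  if (!"augment_seed" %in% names(manifest)) {
    manifest$augment_seed <- NA_integer_
  }
  deficit <- abs(counts[["pCR"]] - counts[["non-pCR"]])
  if (deficit == 0L) return(manifest)
  minority <- if (counts[["pCR"]] < counts[["non-pCR"]]) "pCR" else "non-pCR"
  pool <- pairs[pairs$label == minority, , drop = FALSE]
  .withSeed(.childSeed(seed, 3L), {
    pick <- pool[rep(sample.int(nrow(pool)), length.out = deficit), ,
                 drop = FALSE]
    nextIdx <- vapply(unique(pick$patient_id), function(p) {
      max(manifest$frame_index[manifest$patient_id == p]) + 1L
    }, integer(1))
    names(nextIdx) <- unique(pick$patient_id)
    newRows <- vector("list", nrow(pick))
    for (d in seq_len(nrow(pick))) {
      pid <- pick$patient_id[d]
      src <- manifest[manifest$patient_id == pid &
                        manifest$frame_index == pick$frame_index[d] &
                        manifest$split == "train", , drop = FALSE]
      src$frame_index <- nextIdx[[pid]]
      nextIdx[[pid]] <- nextIdx[[pid]] + 1L
      src$augment_seed <- .childSeed(seed, 100L + d)
      newRows[[d]] <- src
    }
    manifest <- rbind(manifest, do.call(rbind, newRows))
  })
  rownames(manifest) <- NULL
  manifest
}
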