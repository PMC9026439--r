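# Preprocessing chain: frame extraction -> QC selection -> sequential
# cross-stage pairing -> ROI crop -> median denoising -> 128x128
# standardization.
#
# Images are numeric matrices in [0, 1], rows = image rows, top-left origin.
# All indices in these APIs are 1-based and inclusive (R convention); the
# manifest's frame_index column alone is 0-based.

.assertFrameSequence <- function(frames, name = "frames") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop(sprintf("'%s' must be a nonempty list of image matrices", name),
         call. = FALSE)
  }
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    .assertImage(frames[[i]], sprintf("%s[[%d]]", name, i))
    if (!identical(dim(frames[[i]]), d)) {
      stop(sprintf("'%s' frames must share dimensions", name), call. = FALSE)
    }
  }
  invisible(frames)
}

#' Extract frames at a fixed interval
#'
#' Models cutting a cine loop at a fixed frame interval: keeps frames
#' 1, 1 + interval, 1 + 2*interval, ... in order.
#'
#' @param frames a nonempty list of image matrices (one patient/stage).
#' @param interval positive integer frame interval (default 5).
#' @return The subsampled list of frames.
#' @examples
#' frames <- replicate(10, matrix(runif(16), 4, 4), simplify = FALSE)
#' length(extractFrames(frames, 3))  # frames 1, 4, 7, 10
#' @export
extractFrames <- function(frames, interval = 5L) {
  .assertFrameSequence(frames)
  if (!.isCount(interval) || interval < 1) {
    stop("'interval' must be a positive integer", call. = FALSE)
  }
  frames[seq(1L, length(frames), by = as.integer(interval))]
}

#' Select quality-controlled frames
#'
#' Radiologist QC (dropping frames with artifacts, blur or no lesion) is
#' modeled as an explicit, reproducible index list.
#'
#' @param frames a nonempty list of image matrices.
#' @param keep strictly increasing 1-based indices of frames to keep
#'   (at least one).
#' @return The selected frames, order preserved.
#' @export
selectFrames <- function(frames, keep) {
  .assertFrameSequence(frames)
  if (length(keep) == 0L) {
    stop("'keep' must select at least one frame", call. = FALSE)
  }
  if (!is.numeric(keep) || any(keep != round(keep)) || any(keep < 1) ||
      any(keep > length(frames))) {
    stop("'keep' indices must be integers in 1..", length(frames),
         call. = FALSE)
  }
  if (any(diff(keep) <= 0)) {
    stop("'keep' indices must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  frames[as.integer(keep)]
}

#' Pair two stages' frames sequentially
#'
#' Pairs frame k of the pre-treatment sequence with frame k of the
#' post-cycle-1 sequence, so paired images are closest in the video time
#' sequence. Both stages of a patient must hold the same number N of frames
#' (N may differ between patients).
#'
#' @param preFrames,postFrames equal-length lists of image matrices.
#' @param label `"pCR"` or `"non-pCR"`.
#' @param patientId patient identifier carried into each sample.
#' @return A list of N paired samples (fields `pre`, `post`, `label`,
#'   `patient_id`, `frame_index` with 0-based frame index).
#' @export
pairFrames <- function(preFrames, postFrames, label, patientId = "patient") {
  .assertFrameSequence(preFrames, "preFrames")
  .assertFrameSequence(postFrames, "postFrames")
  if (length(preFrames) != length(postFrames)) {
    stop(sprintf(paste0(
      "stage frame counts differ (%d vs %d): the N of the two stages of ",
      "each patient must be the same"),
      length(preFrames), length(postFrames)), call. = FALSE)
  }
  if (!label %in% c("pCR", "non-pCR")) {
    stop("label must be 'pCR' or 'non-pCR'", call. = FALSE)
  }
  lapply(seq_along(preFrames), function(k) {
    list(pre = preFrames[[k]], post = postFrames[[k]], label = label,
         patient_id = patientId, frame_index = k - 1L)
  })
}

#' Rectangular region of interest
#'
#' 1-based inclusive box: rows `row .. row + height - 1`, columns
#' `col .. col + width - 1`.
#'
#' @param row,col 1-based top-left corner.
#' @param height,width box dimensions (>= 1).
#' @return An object of class `roiBox`.
#' @export
roiBox <- function(row, col, height, width) {
  for (v in list(row = row, col = col, height = height, width = width)) {
    if (!.isCount(v) || v < 1) {
      stop("roiBox fields must be positive integers", call. = FALSE)
    }
  }
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roiBox")
}

#' @export
print.roiBox <- function(x, ...) {
  cat(sprintf("ROI box: rows %d..%d, cols %d..%d (%dx%d)\n", x$row,
              x$row + x$height - 1L, x$col, x$col + x$width - 1L,
              x$height, x$width))
  invisible(x)
}

#' Crop a region of interest
#'
#' @param image an image matrix.
#' @param box an [roiBox()].
#' @return The `height` x `width` sub-image.
#' @examples
#' img <- matrix(runif(800 * 608), 608, 800)
#' dim(cropRoi(img, roiBox(80, 170, 445, 445)))
#' @export
cropRoi <- function(image, box) {
  .assertImage(image)
  if (!inherits(box, "roiBox")) stop("'box' must be an roiBox", call. = FALSE)
  lastRow <- box$row + box$height - 1L
  lastCol <- box$col + box$width - 1L
  if (lastRow > nrow(image)) {
    stop(sprintf("ROI bottom row %d exceeds image height %d", lastRow,
                 nrow(image)), call. = FALSE)
  }
  if (lastCol > ncol(image)) {
    stop(sprintf("ROI right column %d exceeds image width %d", lastCol,
                 ncol(image)), call. = FALSE)
  }
  image[box$row:lastRow, box$col:lastCol, drop = FALSE]
}

#' Median-filter denoising
#'
#' Each output pixel is the median of its `kernel` x `kernel` neighbourhood
#' (half-sample symmetric reflection at the borders), the standard
#' edge-preserving speckle denoiser for B-mode images.
#'
#' @param image an image matrix.
#' @param kernel odd integer window side >= 3 (default 3).
#' @return The filtered image, same size.
#' @export
denoiseMedian <- function(image, kernel = 3L) {
  .assertImage(image)
  if (!.isCount(kernel) || kernel < 3 || kernel %% 2 == 0) {
    stop("'kernel' must be an odd integer >= 3", call. = FALSE)
  }
  .medianFilterCpp(image, as.integer(kernel))
}

# Bilinear resampling at arbitrary (fractional) source coordinates with
# half-sample reflection outside the image; rows/cols are equal-length
# coordinate vectors for the flattened (column-major) target.
.reflectIndex <- function(i, n) {
  # half-sample symmetric: 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1
  i <- ifelse(i < 1, 1 - i, i)
  i <- ifelse(i > n, 2 * n + 1 - i, i)
  pmin(n, pmax(1, i))
}

.bilinearSample <- function(image, rows, cols) {
  H <- nrow(image); W <- ncol(image)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r0i <- .reflectIndex(r0, H); r1i <- .reflectIndex(r0 + 1, H)
  c0i <- .reflectIndex(c0, W); c1i <- .reflectIndex(c0 + 1, W)
  v00 <- image[cbind(r0i, c0i)]; v10 <- image[cbind(r1i, c0i)]
  v01 <- image[cbind(r0i, c1i)]; v11 <- image[cbind(r1i, c1i)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

.resizeBilinear <- function(image, targetH, targetW) {
  H <- nrow(image); W <- ncol(image)
  if (H == targetH && W == targetW) return(image)
  # pixel-centre alignment: target centre i - 0.5 maps to source (i-0.5)*H/T
  rows <- (seq_len(targetH) - 0.5) * H / targetH + 0.5
  cols <- (seq_len(targetW) - 0.5) * W / targetW + 0.5
  rr <- matrix(rows, targetH, targetW)
  cc <- matrix(cols, targetH, targetW, byrow = TRUE)
  matrix(.bilinearSample(image, as.vector(rr), as.vector(cc)),
         targetH, targetW)
}

#' Standardize an image for the network
#'
#' Converts multi-channel inputs to grayscale by luminance, resamples to
#' `target` x `target` by bilinear interpolation (pixel-centre alignment),
#' and clips to `[0, 1]`. A `target`-sized input passes through unchanged.
#'
#' @param image an image matrix, or an H x W x 3 array.
#' @param target output side in pixels (default 128).
#' @return A `target` x `target` matrix in `[0, 1]`.
#' @export
standardize <- function(image, target = 128L) {
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] < 3L) {
      image <- image[, , 1]
    } else {
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
        0.114 * image[, , 3]
    }
  }
  .assertImage(image)
  if (!.isCount(target) || target < 8) {
    stop("'target' must be an integer >= 8", call. = FALSE)
  }
  .clip01(.resizeBilinear(image, as.integer(target), as.integer(target)))
}

#' Preprocess one paired sample
#'
#' Applies the same crop -> median denoise -> standardize chain to both
#' stage images of a pair (same box, same kernel), yielding the model input
#' pair.
#'
#' @param rawPair a paired sample (fields `pre`, `post`, `label`, ...).
#' @param params list with optional entries `box` (an [roiBox()]; default: a
#'   centred 445 x 445 box when the image is large enough, else the full
#'   image), `kernel` (median window, default 3) and `target` (output side,
#'   default 128).
#' @return The preprocessed paired sample with `target` x `target` images.
#' @export
preprocessPair <- function(rawPair, params = list()) {
  stopifnot(is.list(rawPair), !is.null(rawPair$pre), !is.null(rawPair$post))
  kernel <- params$kernel %||% 3L
  target <- params$target %||% 128L
  box <- params$box
  if (is.null(box)) {
    H <- nrow(rawPair$pre); W <- ncol(rawPair$pre)
    side <- 445L
    box <- if (H >= side && W >= side) {
      roiBox(floor((H - side) / 2) + 1L, floor((W - side) / 2) + 1L,
             side, side)
    } else {
      roiBox(1L, 1L, H, W)
    }
  }
  one <- function(img) standardize(denoiseMedian(cropRoi(img, box), kernel),
                                   target)
  out <- rawPair
  out$pre <- one(rawPair$pre)
  out$post <- one(rawPair$post)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
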