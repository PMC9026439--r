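#' Configuration of the synthetic paired-ultrasound phantom generator
#'
#' Describes a synthetic cohort of patients, each carrying a speckled
#' hypoechoic (darker-than-background) elliptical lesion imaged at two
#' treatment stages. The class-discriminative signal is deliberately placed
#' in the *between-stage* change: stage-1 lesion parameters are drawn from the
#' same priors for both classes, and only the stage-1 to stage-2 axis scale
#' factor depends on the response label (pCR lesions shrink strongly,
#' non-pCR lesions barely change).
#'
#' @slot nPatients number of patients in the cohort.
#' @slot pcrFraction fraction of patients achieving pCR (default 0.342, the
#'   prevalence of the clinical cohort the generator emulates).
#' @slot framesPerPatient inclusive integer range of frame pairs per patient
#'   (default 16--20, matching the clinical per-patient image counts).
#' @slot imageSize rendering canvas side in pixels (default 445, the ROI
#'   dimension before resizing; small values render model inputs directly).
#' @slot lesionRadiusRange range of the stage-1 lesion major semi-axis, px.
#' @slot lesionContrast mean intensity deficit of the lesion in `[0, 1]`.
#' @slot pcrShrinkageRange axis scale-factor interval for pCR patients
#'   (default `[0, 0.3]`).
#' @slot nonpcrShrinkageRange axis scale-factor interval for non-pCR patients
#'   (default `[0.8, 1.1]`).
#' @slot speckleScale dispersion of the multiplicative speckle texture.
#' @slot backgroundLevel mean background intensity in `(0, 1)`.
#' @slot seed integer seed; config + seed fully determine every pixel.
#' @seealso [SyntheticConfig()], [generateCohort()], [renderStageImage()]
#' @export
setClass("SyntheticConfig",
  representation(
    nPatients = "integer",
    pcrFraction = "numeric",
    framesPerPatient = "integer",
    imageSize = "integer",
    lesionRadiusRange = "numeric",
    lesionContrast = "numeric",
    pcrShrinkageRange = "numeric",
    nonpcrShrinkageRange = "numeric",
    speckleScale = "numeric",
    backgroundLevel = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  chk <- function(expr, text) if (!isTRUE(expr)) msg <<- c(msg, text)
  chk(.isCount(object@nPatients) && object@nPatients >= 1,
      "nPatients must be a positive integer")
  chk(length(object@pcrFraction) == 1 && is.finite(object@pcrFraction) &&
        object@pcrFraction >= 0 && object@pcrFraction <= 1,
      "pcrFraction must lie in [0, 1]")
  chk(length(object@framesPerPatient) == 2 &&
        all(is.finite(object@framesPerPatient)) &&
        object@framesPerPatient[1] <= object@framesPerPatient[2] &&
        object@framesPerPatient[1] >= 1,
      "framesPerPatient must be an increasing positive integer range")
  chk(.isCount(object@imageSize) && object@imageSize >= 16,
      "imageSize must be an integer >= 16")
  chk(length(object@lesionRadiusRange) == 2 &&
        all(is.finite(object@lesionRadiusRange)) &&
        object@lesionRadiusRange[1] <= object@lesionRadiusRange[2] &&
        object@lesionRadiusRange[1] > 0,
      "lesionRadiusRange must be a positive increasing interval")
  chk(length(object@lesionContrast) == 1 && is.finite(object@lesionContrast) &&
        object@lesionContrast >= 0 && object@lesionContrast <= 1,
      "lesionContrast must lie in [0, 1]")
  for (nm in c("pcrShrinkageRange", "nonpcrShrinkageRange")) {
    v <- slot(object, nm)
    chk(length(v) == 2 && all(is.finite(v)) && v[1] <= v[2] && all(v >= 0),
        paste(nm, "must be a non-negative interval with lower <= upper"))
  }
  chk(length(object@speckleScale) == 1 && is.finite(object@speckleScale) &&
        object@speckleScale >= 0, "speckleScale must be >= 0")
  chk(length(object@backgroundLevel) == 1 && is.finite(object@backgroundLevel) &&
        object@backgroundLevel > 0 && object@backgroundLevel < 1,
      "backgroundLevel must lie in (0, 1)")
  chk(length(object@seed) == 1 && !is.na(object@seed),
      "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-cohort configuration
#'
#' @param nPatients number of patients (default 114).
#' @param pcrFraction pCR prevalence in `[0, 1]` (default 0.342).
#' @param framesPerPatient integer range of frame pairs per patient
#'   (default `c(16, 20)`).
#' @param imageSize rendering canvas side in pixels (default 445).
#' @param lesionRadiusRange stage-1 lesion major semi-axis range in pixels.
#' @param lesionContrast lesion intensity deficit (default 0.25).
#' @param pcrShrinkageRange stage-2/stage-1 axis scale interval for pCR
#'   patients (default `c(0, 0.3)`).
#' @param nonpcrShrinkageRange scale interval for non-pCR patients
#'   (default `c(0.8, 1.1)`).
#' @param speckleScale speckle dispersion (default 0.35).
#' @param backgroundLevel mean background intensity (default 0.55).
#' @param seed integer seed (default 1).
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- SyntheticConfig(nPatients = 10, seed = 7)
#' cfg
#' @export
SyntheticConfig <- function(nPatients = 114L,
                            pcrFraction = 0.342,
                            framesPerPatient = c(16L, 20L),
                            imageSize = 445L,
                            lesionRadiusRange = c(40, 110),
                            lesionContrast = 0.25,
                            pcrShrinkageRange = c(0, 0.3),
                            nonpcrShrinkageRange = c(0.8, 1.1),
                            speckleScale = 0.35,
                            backgroundLevel = 0.55,
                            seed = 1L) {
  new("SyntheticConfig",
      nPatients = as.integer(nPatients),
      pcrFraction = as.numeric(pcrFraction),
      framesPerPatient = as.integer(framesPerPatient),
      imageSize = as.integer(imageSize),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      lesionContrast = as.numeric(lesionContrast),
      pcrShrinkageRange = as.numeric(pcrShrinkageRange),
      nonpcrShrinkageRange = as.numeric(nonpcrShrinkageRange),
      speckleScale = as.numeric(speckleScale),
      backgroundLevel = as.numeric(backgroundLevel),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  %d patients, pCR fraction %.3f, %d-%d frame pairs/patient\n",
              object@nPatients, object@pcrFraction,
              object@framesPerPatient[1], object@framesPerPatient[2]))
  cat(sprintf("  canvas %dpx, lesion radius [%g, %g]px, contrast %.2f\n",
              object@imageSize, object@lesionRadiusRange[1],
              object@lesionRadiusRange[2], object@lesionContrast))
  cat(sprintf("  shrinkage pCR [%g, %g], non-pCR [%g, %g]; speckle %.2f; seed %d\n",
              object@pcrShrinkageRange[1], object@pcrShrinkageRange[2],
              object@nonpcrShrinkageRange[1], object@nonpcrShrinkageRange[2],
              object@speckleScale, object@seed))
})

#' A drawn synthetic cohort
#'
#' One row per patient with the response label, frame count, and the stage-1
#' and stage-2 lesion geometry (centre, semi-axes, orientation, contrast).
#' Stage-2 semi-axes equal stage-1 semi-axes times the drawn response-dependent
#' scale factor.
#'
#' @slot patients a `data.frame`, one row per patient.
#' @slot config the [SyntheticConfig-class] the cohort was drawn from.
#' @seealso [generateCohort()]
#' @export
setClass("SyntheticCohort",
  representation(patients = "data.frame", config = "SyntheticConfig"))

setValidity("SyntheticCohort", function(object) {
  need <- c("patient_id", "label", "n_frames", "cx", "cy", "ax1", "ax2",
            "theta", "contrast", "scale", "ax1_2", "ax2_2")
  miss <- setdiff(need, names(object@patients))
  if (length(miss)) {
    return(paste("patients table is missing columns:",
                 paste(miss, collapse = ", ")))
  }
  p <- object@patients
  if (anyDuplicated(p$patient_id)) return("duplicate patient_id")
  if (!all(p$label %in% c("pCR", "non-pCR"))) {
    return("label must be 'pCR' or 'non-pCR'")
  }
  if (!isTRUE(all(abs(p$ax1_2 - p$ax1 * p$scale) < 1e-9) &&
              all(abs(p$ax2_2 - p$ax2 * p$scale) < 1e-9))) {
    return("stage-2 axes must equal stage-1 axes times the drawn scale")
  }
  TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  p <- object@patients
  cat(sprintf("SyntheticCohort: %d patients (%d pCR, %d non-pCR), %d frame pairs\n",
              nrow(p), sum(p$label == "pCR"), sum(p$label == "non-pCR"),
              sum(p$n_frames)))
})

#' Architecture configuration of the dual-branch network
#'
#' Hyper-structure of the network: per-branch depth and channel plan, where
#' the branches exchange features and how (element-wise sum or channel
#' concatenation), the max-pooling schedule, the fully connected width, and
#' the late-fusion rule for the two branch feature vectors. The reference
#' nine-layer configuration uses blocks of `[2, 2, 3, 2]` convolutions with
#' `[64, 128, 256, 512]` channels, sharing at layers `{2, 4, 6, 9}`, pooling
#' after layers `{2, 4, 7, 9}`, a 1024-unit fully connected layer with
#' dropout 0.5, and weighted fusion with `alpha = 0.2` (pre-treatment branch)
#' and `beta = 0.8` (post-cycle-1 branch).
#'
#' @slot depth convolutional layers per branch (8--12).
#' @slot blockLayout integer vector of per-block layer counts (length 4).
#' @slot channelsPerBlock integer vector of per-block channel counts (length 4).
#' @slot kernelSize convolution kernel side (always 3).
#' @slot sharing one of `"none"`, `"sum"`, `"concat"`.
#' @slot sharingLayers 1-based layer indices at which branches exchange
#'   features (the layer's input becomes the combination of both branches'
#'   previous feature maps).
#' @slot poolLayers 1-based layer indices after which 2x2 stride-2 max-pooling
#'   is applied (always 4 of them).
#' @slot fcWidth width of the per-branch fully connected layer.
#' @slot dropoutRate dropout probability after the fully connected layer.
#' @slot fusion one of `"concat"`, `"sum"`, `"weighted"`.
#' @slot alpha,beta non-negative fusion weights of the pre-treatment and
#'   post-cycle-1 branches; for weighted fusion they must sum to 1.
#' @slot nClasses number of output classes (2: pCR, non-pCR).
#' @slot inputSize input image side in pixels (must survive 4 halvings).
#' @slot nBranches 2 for the dual-branch model, 1 for a single-stage baseline.
#' @seealso [ModelConfig()], [buildModel()]
#' @export
setClass("ModelConfig",
  representation(
    depth = "integer",
    blockLayout = "integer",
    channelsPerBlock = "integer",
    kernelSize = "integer",
    sharing = "character",
    sharingLayers = "integer",
    poolLayers = "integer",
    fcWidth = "integer",
    dropoutRate = "numeric",
    fusion = "character",
    alpha = "numeric",
    beta = "numeric",
    nClasses = "integer",
    inputSize = "integer",
    nBranches = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  chk <- function(expr, text) if (!isTRUE(expr)) msg <<- c(msg, text)
  chk(length(object@depth) == 1 && object@depth >= 2,
      "depth must be an integer >= 2")
  chk(length(object@blockLayout) == 4 && all(object@blockLayout >= 1),
      "blockLayout must have 4 positive entries")
  chk(length(object@channelsPerBlock) == 4 && all(object@channelsPerBlock >= 1),
      "channelsPerBlock must have 4 positive entries")
  chk(sum(object@blockLayout) == object@depth,
      sprintf("sum(blockLayout) == %d must equal depth == %d",
              sum(object@blockLayout), object@depth))
  chk(identical(object@kernelSize, 3L), "kernelSize must be 3")
  chk(object@sharing %in% c("none", "sum", "concat"),
      "sharing must be 'none', 'sum' or 'concat'")
  chk(all(object@sharingLayers >= 1 & object@sharingLayers <= object@depth),
      "sharingLayers must be a subset of 1..depth")
  chk(all(object@poolLayers >= 1 & object@poolLayers <= object@depth),
      "poolLayers must be a subset of 1..depth")
  chk(length(object@poolLayers) == 4 && !anyDuplicated(object@poolLayers),
      "poolLayers must contain exactly 4 distinct layers")
  chk(length(object@fcWidth) == 1 && object@fcWidth >= 1,
      "fcWidth must be a positive integer")
  chk(object@dropoutRate >= 0 && object@dropoutRate < 1,
      "dropoutRate must lie in [0, 1)")
  chk(object@fusion %in% c("concat", "sum", "weighted"),
      "fusion must be 'concat', 'sum' or 'weighted'")
  chk(object@alpha >= 0 && object@beta >= 0,
      "alpha and beta must be non-negative")
  if (identical(object@fusion, "weighted")) {
    chk(abs(object@alpha + object@beta - 1) <= 1e-9,
        "weighted fusion requires alpha + beta == 1")
  }
  chk(identical(object@nClasses, 2L), "nClasses must be 2")
  chk(object@inputSize >= 16 && object@inputSize %% 16 == 0,
      "inputSize must be a positive multiple of 16 (four pooling halvings)")
  chk(object@nBranches %in% c(1L, 2L), "nBranches must be 1 or 2")
  if (length(msg)) msg else TRUE
})

# Default per-depth block layouts; the 9-layer reference layout is [2,2,3,2]
# and other depths fill blocks back-to-front.
.defaultBlockLayout <- function(depth) {
  switch(as.character(depth),
         "8"  = c(2L, 2L, 2L, 2L),
         "9"  = c(2L, 2L, 3L, 2L),
         "10" = c(2L, 2L, 3L, 3L),
         "11" = c(2L, 3L, 3L, 3L),
         "12" = c(3L, 3L, 3L, 3L),
         stop("no default block layout for depth ", depth,
              "; supply blockLayout explicitly", call. = FALSE))
}

#' Create a model configuration
#'
#' Defaults reproduce the reference nine-layer dual-branch network; other
#' depths (8--12) get block layouts that fill the four blocks back-to-front
#' and exchange/pool at each block boundary.
#'
#' @param depth convolutional layers per branch (default 9).
#' @param blockLayout per-block layer counts; default depends on `depth`.
#' @param channelsPerBlock per-block channel counts
#'   (default `c(64, 128, 256, 512)`).
#' @param sharing feature-sharing mode: `"none"`, `"sum"` (default) or
#'   `"concat"`.
#' @param sharingLayers layers at which branches exchange features; default
#'   `c(2, 4, 6, 9)` for depth 9, otherwise the last layer of each block.
#' @param poolLayers layers after which max-pooling runs; default
#'   `c(2, 4, 7, 9)` for depth 9, otherwise block boundaries.
#' @param fcWidth fully connected width (default 1024).
#' @param dropoutRate dropout after the fully connected layer (default 0.5).
#' @param fusion head fusion mode (default `"weighted"`).
#' @param alpha,beta fusion weights (default 0.2 / 0.8).
#' @param inputSize input side in pixels (default 128).
#' @param nBranches 2 (default) or 1 for a single-stage baseline.
#' @return A validated [ModelConfig-class].
#' @examples
#' ModelConfig()                      # the reference dual-branch network
#' ModelConfig(depth = 8)             # the CNN-8 ablation backbone
#' ModelConfig(sharing = "concat")    # feature sharing by concatenation
#' @export
ModelConfig <- function(depth = 9L,
                        blockLayout = NULL,
                        channelsPerBlock = c(64L, 128L, 256L, 512L),
                        sharing = c("sum", "none", "concat"),
                        sharingLayers = NULL,
                        poolLayers = NULL,
                        fcWidth = 1024L,
                        dropoutRate = 0.5,
                        fusion = c("weighted", "concat", "sum"),
                        alpha = 0.2,
                        beta = 0.8,
                        inputSize = 128L,
                        nBranches = 2L) {
  sharing <- match.arg(sharing)
  fusion <- match.arg(fusion)
  depth <- as.integer(depth)
  if (is.null(blockLayout)) blockLayout <- .defaultBlockLayout(depth)
  blockLayout <- as.integer(blockLayout)
  bounds <- cumsum(blockLayout)
  if (is.null(poolLayers)) {
    poolLayers <- if (depth == 9L && identical(blockLayout, c(2L, 2L, 3L, 2L)))
      c(2L, 4L, 7L, 9L) else bounds
  }
  if (is.null(sharingLayers)) {
    sharingLayers <- if (depth == 9L && identical(blockLayout, c(2L, 2L, 3L, 2L)))
      c(2L, 4L, 6L, 9L) else bounds
  }
  new("ModelConfig",
      depth = depth,
      blockLayout = blockLayout,
      channelsPerBlock = as.integer(channelsPerBlock),
      kernelSize = 3L,
      sharing = sharing,
      sharingLayers = as.integer(sort(sharingLayers)),
      poolLayers = as.integer(sort(poolLayers)),
      fcWidth = as.integer(fcWidth),
      dropoutRate = as.numeric(dropoutRate),
      fusion = fusion,
      alpha = as.numeric(alpha),
      beta = as.numeric(beta),
      nClasses = 2L,
      inputSize = as.integer(inputSize),
      nBranches = as.integer(nBranches))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d-layer %s network, input %dx%d\n",
              object@depth,
              if (object@nBranches == 2L) "dual-branch" else "single-branch",
              object@inputSize, object@inputSize))
  cat(sprintf("  blocks %s x channels %s\n",
              paste(object@blockLayout, collapse = "/"),
              paste(object@channelsPerBlock, collapse = "/")))
  cat(sprintf("  sharing '%s' at {%s}; pooling after {%s}\n",
              object@sharing, paste(object@sharingLayers, collapse = ","),
              paste(object@poolLayers, collapse = ",")))
  cat(sprintf("  fc %d, dropout %.2f, fusion '%s' (alpha %.2f, beta %.2f)\n",
              object@fcWidth, object@dropoutRate, object@fusion,
              object@alpha, object@beta))
})

#' A parameterized dual-branch network
#'
#' Holds per-branch, per-layer convolution weights and biases, batch-norm
#' affine parameters and running statistics, the per-branch fully connected
#' weights, and the final classifier, together with the train/eval mode flag.
#' Build one with [buildModel()]; do not construct directly.
#'
#' @slot config the [ModelConfig-class] the model was built from.
#' @slot params nested list of parameter arrays.
#' @slot state nested list of batch-norm running statistics.
#' @slot mode `"train"` or `"eval"`.
#' @seealso [buildModel()], [forwardPass()], [architectureSummary()]
#' @export
setClass("DBNNModel",
  representation(config = "ModelConfig", params = "list", state = "list",
                 mode = "character"))

setValidity("DBNNModel", function(object) {
  if (!object@mode %in% c("train", "eval")) return("mode must be train/eval")
  if (length(object@params$branches) != object@config@nBranches) {
    return("params must hold one branch per configured branch")
  }
  TRUE
})

setMethod("show", "DBNNModel", function(object) {
  s <- architectureSummary(object)
  cat(sprintf("DBNNModel (%s mode): %d branch(es) x %d conv layers, %d pools\n",
              object@mode, object@config@nBranches, s$convLayerCount,
              s$poolCount))
  cat(sprintf("  per-layer channels: %s\n",
              paste(s$channels, collapse = " ")))
  cat(sprintf("  fused feature dim %d; %s parameters\n",
              s$fusedFeatureDim, format(s$totalParameterCount, big.mark = ",")))
})

#' Training hyperparameters
#'
#' The training recipe: cross-entropy loss, Adam, learning rate 0.001, batch
#' size 8, 500 epochs (scale `epochs` down for desk-size experiments).
#'
#' @slot learningRate Adam step size (default 0.001).
#' @slot batchSize minibatch size (default 8).
#' @slot epochs training epochs (default 500).
#' @slot seed integer seed controlling initialization-independent training
#'   randomness (shuffling, dropout, augmentation draws).
#' @slot valFraction fraction of training *patients* carved out as a
#'   validation monitor (default 0 = none).
#' @seealso [Hyperparams()], [trainModel()]
#' @export
setClass("Hyperparams",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer",
                 valFraction = "numeric"))

setValidity("Hyperparams", function(object) {
  msg <- character(0)
  if (!(object@learningRate > 0)) msg <- c(msg, "learningRate must be > 0")
  if (!(object@batchSize >= 1)) msg <- c(msg, "batchSize must be >= 1")
  if (!(object@epochs >= 0)) msg <- c(msg, "epochs must be >= 0")
  if (!(object@valFraction >= 0 && object@valFraction < 1)) {
    msg <- c(msg, "valFraction must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @param learningRate,batchSize,epochs,seed,valFraction see slot docs.
#' @return A validated [Hyperparams-class].
#' @rdname Hyperparams-class
#' @examples
#' Hyperparams(epochs = 30, seed = 11)
#' @export
Hyperparams <- function(learningRate = 0.001, batchSize = 8L, epochs = 500L,
                        seed = 1L, valFraction = 0) {
  new("Hyperparams", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), valFraction = as.numeric(valFraction))
}

setMethod("show", "Hyperparams", function(object) {
  cat(sprintf(
    "Hyperparams: Adam lr %.4g, batch %d, %d epochs, seed %d, val %.2f\n",
    object@learningRate, object@batchSize, object@epochs, object@seed,
    object@valFraction))
})

#' Augmentation configuration
#'
#' The three class-imbalance strategies compared in the ablations: geometric
#' transformation (rotation/flip/zoom drawn once per sample and applied
#' identically to both stage images, preserving cross-stage correspondence),
#' Mixup (convex image and label mixing with `lambda ~ Beta(a, a)`), and
#' minority-class upsampling to per-class balance.
#'
#' @slot strategy one of `"none"`, `"geometric"`, `"mixup"`,
#'   `"upsample_minority"`.
#' @slot rotationRange maximum absolute rotation in degrees (default 15).
#' @slot allowHorizontalFlip,allowVerticalFlip flip toggles (defaults TRUE /
#'   FALSE; vertical flips invert the beam direction and are off by default).
#' @slot zoomRange multiplicative zoom interval (default `[0.9, 1.1]`).
#' @slot mixupAlpha Beta concentration for Mixup's lambda (default 0.2).
#' @seealso [AugmentConfig()], [geometricAugment()], [mixupSamples()],
#'   [upsampleMinority()]
#' @export
setClass("AugmentConfig",
  representation(strategy = "character", rotationRange = "numeric",
                 allowHorizontalFlip = "logical", allowVerticalFlip = "logical",
                 zoomRange = "numeric", mixupAlpha = "numeric"))

setValidity("AugmentConfig", function(object) {
  msg <- character(0)
  if (!object@strategy %in% c("none", "geometric", "mixup",
                              "upsample_minority")) {
    msg <- c(msg, "unknown augmentation strategy")
  }
  if (!(object@rotationRange >= 0)) msg <- c(msg, "rotationRange must be >= 0")
  if (!(length(object@zoomRange) == 2 && all(object@zoomRange > 0) &&
        object@zoomRange[1] <= object@zoomRange[2])) {
    msg <- c(msg, "zoomRange must be a positive increasing interval")
  }
  if (!(object@mixupAlpha > 0)) msg <- c(msg, "mixupAlpha must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param strategy,rotationRange,allowHorizontalFlip,allowVerticalFlip
#'   see slot docs.
#' @param zoomRange,mixupAlpha see slot docs.
#' @return A validated [AugmentConfig-class].
#' @rdname AugmentConfig-class
#' @examples
#' AugmentConfig("geometric", rotationRange = 10)
#' @export
AugmentConfig <- function(strategy = c("none", "geometric", "mixup",
                                       "upsample_minority"),
                          rotationRange = 15, allowHorizontalFlip = TRUE,
                          allowVerticalFlip = FALSE, zoomRange = c(0.9, 1.1),
                          mixupAlpha = 0.2) {
  strategy <- match.arg(strategy)
  new("AugmentConfig", strategy = strategy,
      rotationRange = as.numeric(rotationRange),
      allowHorizontalFlip = isTRUE(allowHorizontalFlip),
      allowVerticalFlip = isTRUE(allowVerticalFlip),
      zoomRange = as.numeric(zoomRange), mixupAlpha = as.numeric(mixupAlpha))
}

setMethod("show", "AugmentConfig", function(object) {
  cat(sprintf("AugmentConfig: strategy '%s'", object@strategy))
  if (object@strategy %in% c("geometric", "upsample_minority")) {
    cat(sprintf(" (rot +-%g deg, hflip %s, vflip %s, zoom [%g, %g])",
                object@rotationRange, object@allowHorizontalFlip,
                object@allowVerticalFlip, object@zoomRange[1],
                object@zoomRange[2]))
  }
  if (object@strategy == "mixup") {
    cat(sprintf(" (lambda ~ Beta(%g, %g))", object@mixupAlpha,
                object@mixupAlpha))
  }
  cat("\n")
})
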