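# Synthetic paired-ultrasound cohort generator.
#
# Each patient carries a speckled hypoechoic elliptical lesion imaged at two
# treatment stages. Stage-1 geometry is drawn from label-independent priors;
# the response label only enters through the stage-1 -> stage-2 axis scale
# factor, so the class signal lives in the between-stage change and a
# stage-1-only classifier is near chance by construction.

.dbnnCache <- new.env(parent = emptyenv())

# Banded row-stochastic smoothing matrix for a Gaussian kernel; cached per
# (size, sd). Smoothing S = K %*% G %*% t(K) gives a speckle correlation
# length of a few pixels.
.smoothMatrix <- function(n, sd = 1.2, halfwidth = 3L) {
  key <- sprintf("sm_%d_%g_%d", n, sd, halfwidth)
  if (!is.null(.dbnnCache[[key]])) return(.dbnnCache[[key]])
  K <- matrix(0, n, n)
  w <- exp(-((-halfwidth:halfwidth)^2) / (2 * sd^2))
  for (i in seq_len(n)) {
    j <- (i - halfwidth):(i + halfwidth)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  .dbnnCache[[key]] <- K
  K
}

# Smoothed complex-Gaussian envelope (Rayleigh-like), normalized to mean 1.
.speckleTexture <- function(n) {
  K <- .smoothMatrix(n)
  g1 <- K %*% matrix(rnorm(n * n), n, n) %*% t(K)
  g2 <- K %*% matrix(rnorm(n * n), n, n) %*% t(K)
  e <- sqrt(g1^2 + g2^2)
  e / mean(e)
}

# Elliptical lesion mask (TRUE inside), rows = y, cols = x.
.lesionMask <- function(lesion, n) {
  if (lesion$ax1 <= 0 || lesion$ax2 <= 0) return(matrix(FALSE, n, n))
  y <- matrix(seq_len(n), n, n) - lesion$cy
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - lesion$cx
  ct <- cos(lesion$theta); st <- sin(lesion$theta)
  u <- (x * ct + y * st) / lesion$ax1
  v <- (-x * st + y * ct) / lesion$ax2
  u^2 + v^2 <= 1
}

.lesionFits <- function(lesion, n) {
  if (lesion$ax1 <= 0) return(TRUE)
  ct <- cos(lesion$theta); st <- sin(lesion$theta)
  rx <- sqrt((lesion$ax1 * ct)^2 + (lesion$ax2 * st)^2)
  ry <- sqrt((lesion$ax1 * st)^2 + (lesion$ax2 * ct)^2)
  lesion$cx - rx >= 1 && lesion$cx + rx <= n &&
    lesion$cy - ry >= 1 && lesion$cy + ry <= n
}

#' Draw a synthetic cohort
#'
#' Samples per-patient response labels, frame counts, and stage-1 lesion
#' geometry from label-independent priors, then derives stage-2 geometry via
#' a label-dependent axis scale factor. The number of pCR patients is
#' `round(nPatients * pcrFraction)`. Identical config (including seed)
#' yields an identical cohort.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [SyntheticCohort-class]; its `patients` table carries the drawn
#'   geometry plus stage-1/stage-2 lesion areas (`area1`, `area2`).
#' @examples
#' cohort <- generateCohort(SyntheticConfig(nPatients = 6, imageSize = 64,
#'                                          lesionRadiusRange = c(5, 14),
#'                                          framesPerPatient = c(2, 3)))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  n <- config@nPatients
  S <- config@imageSize
  jitter <- 0.04 * S
  maxScale <- max(config@pcrShrinkageRange[2], config@nonpcrShrinkageRange[2])
  if (config@lesionRadiusRange[2] * max(1, maxScale) + jitter > S / 2 - 1) {
    stop("lesionRadiusRange too large for imageSize: a lesion could leave ",
         "the canvas", call. = FALSE)
  }
  .withSeed(config@seed, {
    nPcr <- as.integer(.roundHalfUp(n * config@pcrFraction, 0))
    label <- rep("non-pCR", n)
    if (nPcr > 0) label[sample.int(n, nPcr)] <- "pCR"
    rows <- lapply(seq_len(n), function(i) {
      nf <- config@framesPerPatient[1] +
        sample.int(config@framesPerPatient[2] - config@framesPerPatient[1] + 1L,
                   1L) - 1L
      ax1 <- runif(1, config@lesionRadiusRange[1], config@lesionRadiusRange[2])
      ax2 <- ax1 * runif(1, 0.6, 1.0)
      rng <- if (label[i] == "pCR") config@pcrShrinkageRange else
        config@nonpcrShrinkageRange
      sc <- runif(1, rng[1], rng[2])
      data.frame(
        patient_id = sprintf("P%03d", i),
        label = label[i],
        n_frames = nf,
        cx = S / 2 + runif(1, -jitter, jitter),
        cy = S / 2 + runif(1, -jitter, jitter),
        ax1 = ax1, ax2 = ax2,
        theta = runif(1, 0, pi),
        contrast = min(1, config@lesionContrast * runif(1, 0.85, 1.15)),
        scale = sc,
        stringsAsFactors = FALSE)
    })
    patients <- do.call(rbind, rows)
    patients$ax1_2 <- patients$ax1 * patients$scale
    patients$ax2_2 <- patients$ax2 * patients$scale
    patients$area1 <- pi * patients$ax1 * patients$ax2
    patients$area2 <- pi * patients$ax1_2 * patients$ax2_2
    new("SyntheticCohort", patients = patients, config = config)
  })
}

#' Render one speckled stage image
#'
#' The background is a multiplicative speckle field (smoothed
#' complex-Gaussian envelope normalized to mean 1) around
#' `backgroundLevel`; inside the lesion ellipse the local mean is lowered by
#' the lesion contrast. Intensities are clipped to `[0, 1]`. Uses the
#' caller's RNG state: seed before calling for reproducibility.
#'
#' @param lesion a list (or one-row data.frame) with fields `cx`, `cy`,
#'   `ax1`, `ax2`, `theta`, `contrast`; zero axes render no lesion.
#' @param canvasSize image side in pixels.
#' @param speckleScale speckle dispersion (0 = noise free).
#' @param backgroundLevel mean background intensity.
#' @return A `canvasSize` x `canvasSize` matrix in `[0, 1]`.
#' @examples
#' les <- list(cx = 32, cy = 32, ax1 = 10, ax2 = 7, theta = 0.4,
#'             contrast = 0.3)
#' set.seed(1); img <- renderStageImage(les, 64, 0.35)
#' mean(img[lesionMask(les, 64)]) < mean(img[!lesionMask(les, 64)])
#' @export
renderStageImage <- function(lesion, canvasSize, speckleScale = 0.35,
                             backgroundLevel = 0.55) {
  lesion <- as.list(lesion)
  .assertScalar(canvasSize, "canvasSize", lower = 8)
  .assertScalar(speckleScale, "speckleScale", lower = 0)
  .assertScalar(backgroundLevel, "backgroundLevel", lower = 0, upper = 1)
  if (!.lesionFits(lesion, canvasSize)) {
    stop(sprintf(
      "lesion does not fit in the %dx%d canvas (centre %.1f, %.1f; axes %.1f, %.1f)",
      canvasSize, canvasSize, lesion$cx, lesion$cy, lesion$ax1, lesion$ax2),
      call. = FALSE)
  }
  mask <- .lesionMask(lesion, canvasSize)
  mu <- matrix(backgroundLevel, canvasSize, canvasSize)
  mu[mask] <- backgroundLevel - lesion$contrast
  tex <- if (speckleScale > 0) 1 + speckleScale * (.speckleTexture(canvasSize) - 1)
         else matrix(1, canvasSize, canvasSize)
  .clip01(mu * tex)
}

#' @rdname renderStageImage
#' @export
lesionMask <- function(lesion, canvasSize) {
  .lesionMask(as.list(lesion), canvasSize)
}

.stageLesion <- function(p, stage) {
  if (stage == "pre") {
    list(cx = p$cx, cy = p$cy, ax1 = p$ax1, ax2 = p$ax2, theta = p$theta,
         contrast = p$contrast)
  } else {
    list(cx = p$cx, cy = p$cy, ax1 = p$ax1_2, ax2 = p$ax2_2, theta = p$theta,
         contrast = p$contrast)
  }
}

#' Render a cohort to disk as a paired dataset
#'
#' Writes `n_frames` image pairs per patient (stage 1 and stage 2 rendered
#' with independent speckle realizations of the same lesion mask) and returns
#' the manifest, which is also written to `manifest.csv` in `outDir`.
#' Deterministic given the cohort's config seed.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param outDir output directory (created if needed).
#' @param ascii write plain-text (P2) graymaps instead of binary P5.
#' @return The manifest `data.frame` (split column `"unassigned"`).
#' @examples
#' cfg <- SyntheticConfig(nPatients = 2, imageSize = 64,
#'                        lesionRadiusRange = c(5, 14),
#'                        framesPerPatient = c(2, 2))
#' man <- generatePairedDataset(generateCohort(cfg), tempfile("cohort"))
#' nrow(man)  # 2 patients x 2 frames x 2 stages
#' @export
generatePairedDataset <- function(cohort, outDir, ascii = FALSE) {
  stopifnot(is(cohort, "SyntheticCohort"))
  validObject(cohort)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE)) {
    stop("cannot create output directory: ", outDir, call. = FALSE)
  }
  cfg <- cohort@config
  pts <- cohort@patients
  rows <- vector("list", sum(pts$n_frames) * 2L)
  k <- 0L
  .withSeed(.childSeed(cfg@seed, 2L), {
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      for (f in seq_len(p$n_frames)) {
        for (stage in c("pre", "post1")) {
          img <- renderStageImage(
            .stageLesion(p, if (stage == "pre") "pre" else "post"),
            cfg@imageSize, cfg@speckleScale, cfg@backgroundLevel)
          fn <- sprintf("%s_%s_f%02d.pgm", p$patient_id, stage, f - 1L)
          path <- file.path(outDir, fn)
          ok <- tryCatch({writeGrayImage(img, path, ascii = ascii); TRUE},
                         error = function(e) e)
          if (!isTRUE(ok)) {
            stop("failed to write image ", path, ": ", conditionMessage(ok),
                 call. = FALSE)
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            patient_id = p$patient_id, label = p$label, stage = stage,
            frame_index = f - 1L, path = path, split = "unassigned",
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  manifest
}

#' Assign a patient-level train/test split
#'
#' Patients (never individual frames) are assigned to splits. Within each
#' class, `round(trainFraction * n_class)` patients go to training (rounding
#' half away from zero), so the pCR:non-pCR ratio of both splits matches the
#' overall ratio as closely as integer counts allow. No patient appears in
#' both splits.
#'
#' @param manifest a manifest `data.frame`.
#' @param trainFraction fraction of patients per class assigned to training,
#'   in `(0, 1]` (default 0.8, the 4:1 split).
#' @param seed integer seed for the within-class draw.
#' @return The manifest with its `split` column filled.
#' @examples
#' # 114 patients at 0.8 -> 91 train / 23 test
#' @export
splitPatients <- function(manifest, trainFraction = 0.8, seed = 1L) {
  validateManifest(manifest)
  if (!is.numeric(trainFraction) || length(trainFraction) != 1L ||
      !is.finite(trainFraction) || trainFraction <= 0 || trainFraction > 1) {
    stop("trainFraction must lie in (0, 1]", call. = FALSE)
  }
  pts <- unique(manifest[, c("patient_id", "label")])
  .withSeed(seed, {
    train <- character(0)
    for (cl in unique(pts$label)) {
      ids <- pts$patient_id[pts$label == cl]
      nTrain <- min(length(ids),
                    as.integer(.roundHalfUp(trainFraction * length(ids), 0)))
      train <- c(train, sample(ids, nTrain))
    }
    manifest$split <- ifelse(manifest$patient_id %in% train, "train", "test")
  })
  manifest
}

#' Class ratio of a split
#'
#' Ratio of pCR to non-pCR image *pairs* in a split (the clinical training
#' composition of 300 pCR / 476 non-pCR pairs gives 0.63).
#'
#' @param manifest a manifest `data.frame`.
#' @param split `"train"` or `"test"`.
#' @return The pCR:non-pCR pair-count ratio (numeric scalar).
#' @export
classRatio <- function(manifest, split = "train") {
  validateManifest(manifest)
  m <- manifest[manifest$split == split & manifest$stage == "pre", ,
                drop = FALSE]
  nPcr <- sum(m$label == "pCR")
  nNon <- sum(m$label == "non-pCR")
  if (nNon == 0L) stop("no non-pCR pairs in split '", split, "'",
                       call. = FALSE)
  nPcr / nNon
}
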