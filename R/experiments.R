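# Ablation sweep runners mirroring the published experiment grids: depth
# (CNN-8..CNN-12 plus sharing variants), head-fusion weights, augmentation
# strategies, and single- versus dual-stage inputs. Every result row records
# the seed and the resolved model configuration, so it can be regenerated
# from the row alone.

.metricRow <- function(name, scores, labels, seed, config) {
  mets <- metricsPanel(scores, labels)
  data.frame(model = name,
             accuracy = mets$accuracy, sensitivity = mets$sensitivity,
             specificity = mets$specificity, ppv = mets$ppv, npv = mets$npv,
             f1 = mets$f1, auc = mets$auc, auc_lo = mets$aucLower,
             auc_hi = mets$aucUpper, seed = seed, status = "ok",
             config = as.character(jsonlite::toJSON(configAsList(config),
                                                    auto_unbox = TRUE,
                                                    digits = NA)),
             stringsAsFactors = FALSE)
}

.failedRow <- function(name, seed, err) {
  data.frame(model = name, accuracy = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
             f1 = NA_real_, auc = NA_real_, auc_lo = NA_real_,
             auc_hi = NA_real_, seed = seed, status = paste("failed:", err),
             config = NA_character_, stringsAsFactors = FALSE)
}

# train + score one configuration; returns scores on the test split
.runOne <- function(config, manifest, hp, augment, baseDir, stage = "both") {
  if (identical(augment@strategy, "upsample_minority")) {
    manifest <- upsampleMinority(manifest, augment, seed = hp@seed)
  }
  model <- buildModel(config, seed = hp@seed)
  fit <- trainModel(model, manifest, hp, augment = augment,
                    baseDir = baseDir, stage = stage)
  preds <- predictPairs(fit$model, manifest, "test", baseDir, stage = stage)
  list(scores = preds$score, labels = preds$label, model = fit$model,
       preds = preds)
}

.sweep <- function(grid, manifest, hp, baseDir, seeds) {
  rows <- list()
  for (seed in seeds) {
    hpSeed <- hp
    hpSeed@seed <- as.integer(seed)
    for (g in grid) {
      row <- tryCatch({
        run <- .runOne(g$config, manifest, hpSeed, g$augment, baseDir,
                       g$stage %||% "both")
        .metricRow(g$name, run$scores, run$labels, seed, g$config)
      }, error = function(e) .failedRow(g$name, seed, conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Depth and sharing-mode sweep
#'
#' Trains dual-branch backbones of depth 8 to 12 (no feature sharing,
#' concatenation head) plus the 9-layer variants with feature sharing by
#' element-wise sum (FSS) and by concatenation (FSC) - seven rows.
#'
#' @param manifest a split manifest.
#' @param hp a [Hyperparams-class].
#' @param template a [ModelConfig-class] providing the channel plan, fc
#'   width and input size (depth/sharing/fusion fields are overridden by the
#'   grid).
#' @param depths integer depths to sweep (default 8:12).
#' @param seeds one or more training seeds; one row per (model, seed).
#' @param baseDir optional base directory for relative manifest paths.
#' @return A results `data.frame`, one row per grid point, in grid order.
#' @export
runDepthSweep <- function(manifest, hp, template = ModelConfig(),
                          depths = 8:12, seeds = hp@seed, baseDir = NULL) {
  mk <- function(depth, sharing, fusion) {
    ModelConfig(depth = depth, channelsPerBlock = template@channelsPerBlock,
                sharing = sharing, fcWidth = template@fcWidth,
                dropoutRate = template@dropoutRate, fusion = fusion,
                alpha = 1, beta = 1, inputSize = template@inputSize)
  }
  none <- AugmentConfig("none")
  grid <- lapply(depths, function(d) {
    list(name = sprintf("CNN-%d", d), config = mk(d, "none", "concat"),
         augment = none)
  })
  grid <- c(grid,
            list(list(name = "CNN-9 FSS", config = mk(9L, "sum", "concat"),
                      augment = none),
                 list(name = "CNN-9 FSC", config = mk(9L, "concat", "concat"),
                      augment = none)))
  .sweep(grid, manifest, hp, baseDir, seeds)
}

#' Head-fusion grid on the sum-sharing backbone
#'
#' Eleven rows: fused-vector concatenation, element-wise sum, and the nine
#' weighted convex combinations (0.9, 0.1) ... (0.1, 0.9) in steps of 0.1
#' (the (0.2, 0.8) row is the reference dual-branch model). The
#' highest-accuracy row is flagged in a `best` column.
#'
#' @inheritParams runDepthSweep
#' @return A results `data.frame` with 11 rows (per seed).
#' @export
runFusionGrid <- function(manifest, hp, template = ModelConfig(),
                          seeds = hp@seed, baseDir = NULL) {
  mk <- function(fusion, alpha = 1, beta = 1) {
    ModelConfig(depth = template@depth,
                channelsPerBlock = template@channelsPerBlock,
                sharing = "sum", fcWidth = template@fcWidth,
                dropoutRate = template@dropoutRate, fusion = fusion,
                alpha = alpha, beta = beta, inputSize = template@inputSize)
  }
  none <- AugmentConfig("none")
  grid <- list(
    list(name = "FSS_concat", config = mk("concat"), augment = none),
    list(name = "FSS_sum", config = mk("sum"), augment = none))
  for (a in seq(0.9, 0.1, by = -0.1)) {
    b <- round(1 - a, 1)
    grid[[length(grid) + 1L]] <- list(
      name = sprintf("FSS (%.1f, %.1f)", a, b),
      config = mk("weighted", a, b), augment = none)
  }
  out <- .sweep(grid, manifest, hp, baseDir, seeds)
  out$best <- !is.na(out$accuracy) &
    out$accuracy == max(out$accuracy, na.rm = TRUE)
  out
}

#' Augmentation-strategy sweep
#'
#' Four rows on a fixed model configuration: no augmentation, geometric
#' transformation, Mixup, and minority-class upsampling to balance.
#'
#' @inheritParams runDepthSweep
#' @param template the fixed [ModelConfig-class] to train under each
#'   strategy.
#' @param augmentBase an [AugmentConfig-class] whose geometric/Mixup knobs
#'   parameterize each strategy.
#' @return A results `data.frame` with 4 rows (per seed) and an
#'   `augment_strategy` column.
#' @export
runAugmentationSweep <- function(manifest, hp, template = ModelConfig(),
                                 augmentBase = AugmentConfig("geometric"),
                                 seeds = hp@seed, baseDir = NULL) {
  strategies <- c("none", "geometric", "mixup", "upsample_minority")
  grid <- lapply(strategies, function(s) {
    cfg <- augmentBase
    cfg@strategy <- s
    validObject(cfg)
    list(name = s, config = template, augment = cfg)
  })
  out <- .sweep(grid, manifest, hp, baseDir, seeds)
  out$augment_strategy <- rep(strategies, times = length(seeds))
  out
}

#' Single- versus dual-stage comparison
#'
#' Trains a single-branch backbone on pre-treatment images only, on
#' post-cycle-1 images only, and the dual-branch model on both, then runs
#' pairwise paired DeLong tests between the three AUCs on the shared test
#' pairs.
#'
#' @inheritParams runDepthSweep
#' @param template the dual-branch [ModelConfig-class]; single-branch runs
#'   reuse its backbone with `nBranches = 1`.
#' @return A list with `results` (3-row `data.frame`) and `tests`
#'   (pairwise `z`/`p` values).
#' @export
runSingleVsDual <- function(manifest, hp, template = ModelConfig(),
                            seeds = hp@seed, baseDir = NULL) {
  single <- ModelConfig(depth = template@depth,
                        channelsPerBlock = template@channelsPerBlock,
                        sharing = "none", fcWidth = template@fcWidth,
                        dropoutRate = template@dropoutRate, fusion = "sum",
                        alpha = 1, beta = 1, inputSize = template@inputSize,
                        nBranches = 1L)
  none <- AugmentConfig("none")
  rows <- list(); testsRows <- list()
  for (seed in seeds) {
    hpSeed <- hp; hpSeed@seed <- as.integer(seed)
    runs <- list(
      NAC_pre = list(config = single, stage = "pre"),
      NAC_1 = list(config = single, stage = "post"),
      `NAC_pre+NAC_1` = list(config = template, stage = "both"))
    scored <- list()
    for (nm in names(runs)) {
      r <- runs[[nm]]
      row <- tryCatch({
        run <- .runOne(r$config, manifest, hpSeed, none, baseDir, r$stage)
        scored[[nm]] <- run$preds
        .metricRow(nm, run$scores, run$labels, seed, r$config)
      }, error = function(e) .failedRow(nm, seed, conditionMessage(e)))
      rows[[length(rows) + 1L]] <- row
    }
    if (length(scored) == 3L) {
      cmb <- utils::combn(names(scored), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- scored[[cmb[1, k]]]; b <- scored[[cmb[2, k]]]
        dt <- delongTest(a$score, b$score, a$label)
        testsRows[[length(testsRows) + 1L]] <- data.frame(
          model_a = cmb[1, k], model_b = cmb[2, k], auc_a = dt$aucA,
          auc_b = dt$aucB, z = dt$z, p = dt$p, seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(results = do.call(rbind, rows),
       tests = if (length(testsRows)) do.call(rbind, testsRows) else NULL)
}

#' Desk-size profile for CPU-scale experiments
#'
#' A scaled-down but architecturally faithful profile: 64 x 64 inputs
#' rendered directly (no crop/resize needed), channels and fc width divided
#' by 8, 30 epochs, and a compact cohort (default 100 patients, 2 frame
#' pairs each, sized for single-CPU runtimes) with the standard shrinkage
#' effect sizes. The lesion radius
#' prior is wide so that the stage-2 size marginal overlaps between classes
#' while the between-stage shrinkage ratio stays separable - stage-1-only
#' models sit near chance and stage-2-only models stay clearly below the
#' dual-branch model.
#'
#' @param nPatients cohort size (default 100).
#' @param epochs training epochs (default 30).
#' @param seed master seed.
#' @return A list with elements `synth` ([SyntheticConfig-class]), `model`
#'   ([ModelConfig-class]) and `hp` ([Hyperparams-class]).
#' @export
deskProfile <- function(nPatients = 100L, epochs = 30L, seed = 1L) {
  list(
    synth = SyntheticConfig(
      nPatients = nPatients, pcrFraction = 0.342,
      framesPerPatient = c(2L, 2L), imageSize = 64L,
      lesionRadiusRange = c(5, 24), lesionContrast = 0.25,
      pcrShrinkageRange = c(0, 0.3), nonpcrShrinkageRange = c(0.8, 1.1),
      speckleScale = 0.35, seed = seed),
    model = ModelConfig(channelsPerBlock = c(8L, 16L, 32L, 64L),
                        fcWidth = 128L, inputSize = 64L),
    hp = Hyperparams(epochs = epochs, seed = seed))
}

#' Generate, render and split a synthetic dataset in one call
#'
#' Convenience wrapper: [generateCohort()] then [generatePairedDataset()]
#' then [splitPatients()].
#'
#' @param config a [SyntheticConfig-class].
#' @param outDir output directory for images and manifest.
#' @param trainFraction patient-level training fraction (default 0.8).
#' @return The split manifest.
#' @export
synthesizeDataset <- function(config, outDir, trainFraction = 0.8) {
  cohort <- generateCohort(config)
  manifest <- generatePairedDataset(cohort, outDir)
  manifest <- splitPatients(manifest, trainFraction,
                            seed = .childSeed(config@seed, 5L))
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  manifest
}
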