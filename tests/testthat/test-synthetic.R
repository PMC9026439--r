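# Synthetic paired-cohort generator: prevalence arithmetic, determinism,
# speckle rendering, dataset layout, patient-level splitting.

test_that("generateCohort allocates pCR patients by rounded prevalence", {
  cfg <- SyntheticConfig(nPatients = 114L, pcrFraction = 0.342,
                         framesPerPatient = c(16L, 20L), seed = 4L)
  co <- generateCohort(cfg)
  expect_equal(sum(co@patients$label == "pCR"), 39L)
  expect_true(all(co@patients$n_frames >= 16 & co@patients$n_frames <= 20))

  co0 <- generateCohort(SyntheticConfig(nPatients = 10L, pcrFraction = 0,
                                        seed = 1L))
  expect_equal(sum(co0@patients$label == "pCR"), 0L)
})

test_that("cohorts are deterministic in config + seed and respond to the seed", {
  cfg <- SyntheticConfig(nPatients = 12L, imageSize = 64L,
                         lesionRadiusRange = c(5, 14),
                         framesPerPatient = c(2L, 4L), seed = 7L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@patients, b@patients)
  cfg2 <- cfg; cfg2@seed <- 8L
  c2 <- generateCohort(cfg2)
  expect_false(isTRUE(all.equal(a@patients$ax1, c2@patients$ax1)))
  # stage-2 axes derive from stage-1 axes via the drawn scale
  expect_equal(a@patients$ax1_2, a@patients$ax1 * a@patients$scale)
})

test_that("invalid synthetic configs are rejected naming the field", {
  expect_error(SyntheticConfig(pcrFraction = 1.2), "pcrFraction")
  expect_error(SyntheticConfig(framesPerPatient = c(5L, 3L)),
               "framesPerPatient")
  expect_error(SyntheticConfig(pcrShrinkageRange = c(-0.2, 0.3)),
               "pcrShrinkageRange")
  # lesions that could leave the canvas are a geometry error
  expect_error(generateCohort(SyntheticConfig(imageSize = 64L,
                                              lesionRadiusRange = c(5, 40))),
               "canvas")
})

test_that("renderStageImage produces speckled hypoechoic lesions", {
  les <- list(cx = 32, cy = 32, ax1 = 11, ax2 = 8, theta = 0.7,
              contrast = 0.25)
  # degenerate case: no noise, no contrast -> constant background
  flat <- renderStageImage(list(cx = 32, cy = 32, ax1 = 11, ax2 = 8,
                                theta = 0.7, contrast = 0),
                           64, speckleScale = 0, backgroundLevel = 0.55)
  expect_equal(dim(flat), c(64L, 64L))
  expect_true(all(flat == 0.55))

  # lesion interior darker than background in >= 95% of renders
  mask <- lesionMask(les, 64)
  set.seed(11)
  darker <- vapply(1:100, function(i) {
    img <- renderStageImage(les, 64, speckleScale = 0.35)
    mean(img[mask]) < mean(img[!mask])
  }, logical(1))
  expect_gte(mean(darker), 0.95)

  # two frames of the same lesion share the mask, differ only by speckle
  set.seed(2)
  f1 <- renderStageImage(les, 64)
  f2 <- renderStageImage(les, 64)
  expect_false(identical(f1, f2))
  expect_lt(mean(f1[mask]), mean(f1[!mask]))
  expect_lt(mean(f2[mask]), mean(f2[!mask]))

  expect_error(renderStageImage(list(cx = 60, cy = 32, ax1 = 11, ax2 = 8,
                                     theta = 0, contrast = 0.2), 64),
               "does not fit")
})

test_that("generatePairedDataset writes equal per-stage frame counts and is byte-deterministic", {
  cfg <- SyntheticConfig(nPatients = 2L, imageSize = 64L,
                         lesionRadiusRange = c(5, 14),
                         framesPerPatient = c(3L, 3L), seed = 5L)
  d1 <- file.path(tempdir(), "detds1")
  man <- generatePairedDataset(generateCohort(cfg), d1)
  expect_equal(nrow(man), 2L * 3L * 2L)  # patients x frames x stages
  counts <- table(man$patient_id, man$stage)
  expect_true(all(counts[, "pre"] == counts[, "post1"]))
  expect_true(all(file.exists(man$path)))

  d2 <- file.path(tempdir(), "detds2")
  generatePairedDataset(generateCohort(cfg), d2)
  h1 <- tools::md5sum(sort(list.files(d1, "\\.pgm$", full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(d2, "\\.pgm$", full.names = TRUE)))
  expect_equal(unname(h1), unname(h2))
})

test_that("splitPatients preserves class ratios at the patient level", {
  # 114 patients at 0.8 -> 91 train / 23 test
  man <- makeManifestTable(39 * 2, 75 * 2, framesPerPatient = 2L)
  man$split <- "unassigned"
  sp <- splitPatients(man, 0.8, seed = 3)
  pts <- unique(sp[, c("patient_id", "label", "split")])
  expect_equal(sum(pts$split == "train"), 91L)
  expect_equal(sum(pts$split == "test"), 23L)
  expect_equal(sum(pts$split == "train" & pts$label == "pCR"), 31L)

  # fraction 1.0: everyone trains
  all1 <- splitPatients(man, 1.0, seed = 1)
  expect_true(all(all1$split == "train"))
  expect_error(splitPatients(man, 0), "trainFraction")
  expect_error(splitPatients(man, 1.2), "trainFraction")

  # 10 patients (4 pCR) at 0.8 -> 8 train with 3 pCR, for any seed
  man10 <- makeManifestTable(4, 6, framesPerPatient = 1L)
  for (seed in 1:10) {
    sp10 <- splitPatients(man10, 0.8, seed = seed)
    pts10 <- unique(sp10[, c("patient_id", "label", "split")])
    expect_equal(sum(pts10$split == "train"), 8L)
    expect_equal(sum(pts10$split == "train" & pts10$label == "pCR"), 3L)
  }
})

test_that("no patient ever straddles the train/test boundary", {
  man <- makeManifestTable(10, 16, framesPerPatient = 3L)
  man$split <- "unassigned"
  for (seed in 1:100) {
    sp <- splitPatients(man, 0.7, seed = seed)
    overlap <- intersect(sp$patient_id[sp$split == "train"],
                         sp$patient_id[sp$split == "test"])
    expect_length(overlap, 0)
  }
})

test_that("class signal lives in the between-stage change, not in stage 1", {
  cfg <- SyntheticConfig(nPatients = 200L, imageSize = 64L,
                         lesionRadiusRange = c(5, 24),
                         framesPerPatient = c(2L, 3L), seed = 42L)
  co <- generateCohort(cfg)
  p <- co@patients
  a1p <- p$area1[p$label == "pCR"]; a1n <- p$area1[p$label == "non-pCR"]
  a2p <- p$area2[p$label == "pCR"]; a2n <- p$area2[p$label == "non-pCR"]
  # stage-1 lesion areas indistinguishable between classes
  expect_gt(mannWhitneyU(a1p, a1n)$p, 0.01)
  # stage-2 areas sharply separated
  expect_lt(mannWhitneyU(a2p, a2n)$p, 1e-6)
})

test_that("classRatio reports the pair-count ratio of a split", {
  man <- makeManifestTable(300, 476)
  expect_equal(round(classRatio(man, "train"), 2), 0.63)
})
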