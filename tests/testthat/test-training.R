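# Training loop: no-op epochs, determinism, loss descent, cross-entropy
# evaluation, gradient sanity, dropout gating.

test_that("zero epochs is a no-op with an empty curve", {
  setup <- tinyTrainSetup()
  m <- buildModel(setup$config, seed = 1)
  hp <- setup$hp; hp@epochs <- 0L
  fit <- trainModel(m, setup$manifest, hp)
  expect_identical(fit$model@params, m@params)
  expect_equal(nrow(fit$curve), 0L)
  expect_identical(fit$model@mode, "eval")
})

test_that("identical data and seed reproduce the trained model exactly", {
  setup <- tinyTrainSetup()
  hp <- setup$hp; hp@epochs <- 2L
  f1 <- trainModel(buildModel(setup$config, seed = 2), setup$manifest, hp)
  f2 <- trainModel(buildModel(setup$config, seed = 2), setup$manifest, hp)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$curve, f2$curve)
  hp3 <- hp; hp3@seed <- 99L
  f3 <- trainModel(buildModel(setup$config, seed = 2), setup$manifest, hp3)
  expect_false(identical(f1$model@params, f3$model@params))
})

test_that("training reduces the loss on a separable synthetic cohort", {
  # scaled-down trend check: small cohort, short schedule, several seeds
  for (seed in 1:3) {
    cfg <- SyntheticConfig(nPatients = 16L, pcrFraction = 0.4,
                           framesPerPatient = c(2L, 2L), imageSize = 32L,
                           lesionRadiusRange = c(4, 10), seed = seed)
    dir <- file.path(tempdir(), paste0("trend", seed))
    man <- if (dir.exists(dir)) readManifest(file.path(dir, "manifest.csv"))
           else synthesizeDataset(cfg, dir, 0.75)
    mcfg <- ModelConfig(channelsPerBlock = c(4L, 8L, 8L, 16L), fcWidth = 32L,
                        inputSize = 32L)
    hp <- Hyperparams(epochs = 8L, seed = seed)
    fit <- trainModel(buildModel(mcfg, seed = seed), man, hp)
    expect_true(all(is.finite(fit$curve$train_loss)))
    expect_lt(fit$curve$train_loss[8], fit$curve$train_loss[1])
  }
})

test_that("evaluateLoss is the mean cross-entropy of the model's own probabilities", {
  setup <- tinyTrainSetup()
  m <- evalMode(buildModel(setup$config, seed = 3))
  samples <- loadPairedSamples(setup$manifest, "train")[1:3]
  got <- evaluateLoss(m, samples)
  probs <- forwardPass(m, lapply(samples, `[[`, "pre"),
                       lapply(samples, `[[`, "post"))
  y <- cbind(vapply(samples, function(s) s$label == "pCR", logical(1)),
             vapply(samples, function(s) s$label != "pCR", logical(1))) * 1
  expect_equal(got, -mean(rowSums(y * log(probs))), tolerance = 1e-10)
  expect_error(evaluateLoss(m, list()), "nonempty")
})

test_that("cross-entropy has its closed-form values at the extremes", {
  # a uniform predictor scores ln 2; a perfect one scores ~0. Check through
  # the loss identity -sum(y log p) on explicit probability rows.
  ce <- function(p, y) -mean(rowSums(y * log(p)))
  expect_equal(ce(matrix(0.5, 4, 2), cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))),
               log(2))
  expect_equal(ce(cbind(c(1, 0), c(0, 1)) * 0.999998 + 1e-6,
                  cbind(c(1, 0), c(0, 1))), 0, tolerance = 1e-5)
  # hand-computed three-sample batch
  p <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  y <- rbind(c(1, 0), c(0, 1), c(0.4, 0.6))
  manual <- -(log(0.7) + log(0.8) + 0.4 * log(0.5) + 0.6 * log(0.5)) / 3
  expect_equal(ce(p, y), manual)
})

test_that("backpropagation matches finite differences on a tiny model", {
  cfg <- tinyConfig(dropoutRate = 0)
  m <- buildModel(cfg, seed = 3)
  set.seed(9)
  pack <- function(l) matrix(unlist(l), ncol = 1)
  inputs <- list(pack(lapply(1:3, function(i) matrix(runif(256), 16, 16))),
                 pack(lapply(1:3, function(i) matrix(runif(256), 16, 16))))
  Y <- rbind(c(1, 0), c(0, 1), c(0.4, 0.6))
  fwd <- dbnn:::.forwardInternal(m, inputs, train = TRUE, keepCache = TRUE)
  grads <- dbnn:::.backwardInternal(m, fwd, Y)
  lossOf <- function(model) {
    f <- dbnn:::.forwardInternal(model, inputs, train = TRUE)
    -mean(rowSums(Y * f$logp))
  }
  eps <- 1e-5
  getLeaf <- function(tree, path) Reduce(function(t, k) t[[k]], path, tree)
  setLeaf <- function(tree, path, value) {
    if (length(path) == 1L) { tree[[path[[1]]]] <- value; return(tree) }
    tree[[path[[1]]]] <- setLeaf(tree[[path[[1]]]], path[-1], value)
    tree
  }
  paths <- list(list("branches", 1L, "conv", 2L, "W"),
                list("branches", 2L, "conv", 4L, "W"),
                list("branches", 1L, "conv", 3L, "gamma"),
                list("branches", 2L, "conv", 1L, "beta"),
                list("branches", 1L, "fc", "W"),
                list("head", "W"))
  nChecked <- 0L
  for (path in paths) {
    arr <- getLeaf(m@params, path)
    g <- getLeaf(grads, path)
    for (j in sample(length(arr), min(2L, length(arr)))) {
      m2 <- m
      arr2 <- arr; arr2[j] <- arr[j] + eps
      m2@params <- setLeaf(m@params, path, arr2)
      lp <- lossOf(m2)
      arr2[j] <- arr[j] - eps
      m2@params <- setLeaf(m@params, path, arr2)
      lm <- lossOf(m2)
      fd <- (lp - lm) / (2 * eps)
      rel <- abs(fd - g[j]) / max(1e-6, abs(fd) + abs(g[j]))
      expect_lt(rel, 1e-3)
      nChecked <- nChecked + 1L
    }
  }
  expect_gte(nChecked, 10L)
})

test_that("dropout acts only in train mode", {
  cfg <- tinyConfig(dropoutRate = 0.5)
  m <- buildModel(cfg, seed = 4)
  set.seed(5)
  img <- matrix(runif(256), 16, 16)
  mEval <- evalMode(m)
  p1 <- forwardPass(mEval, img, img)
  p2 <- forwardPass(mEval, img, img)
  expect_identical(p1, p2)
  mTrain <- trainMode(m)
  set.seed(6); q1 <- forwardPass(mTrain, img, img)
  set.seed(7); q2 <- forwardPass(mTrain, img, img)
  expect_false(identical(q1, q2))
})

test_that("training with mixup and geometric augmentation stays finite", {
  setup <- tinyTrainSetup()
  hp <- setup$hp; hp@epochs <- 1L
  for (strategy in c("geometric", "mixup")) {
    fit <- trainModel(buildModel(setup$config, seed = 1), setup$manifest, hp,
                      augment = AugmentConfig(strategy))
    expect_true(all(is.finite(fit$curve$train_loss)))
  }
  # patient-level validation monitor produces a finite second column
  hpv <- setup$hp; hpv@epochs <- 1L; hpv@valFraction <- 0.3
  fitv <- trainModel(buildModel(setup$config, seed = 1), setup$manifest, hpv)
  expect_true(is.finite(fitv$curve$val_loss[1]))
})
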