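# Dual-branch network: construction, architecture traversal, forward-pass
# oracle equivalence, fusion algebra, branch isolation, shape conservation.

test_that("buildModel is deterministic and validates its configuration", {
  cfg <- tinyConfig()
  m1 <- buildModel(cfg, seed = 5)
  m2 <- buildModel(cfg, seed = 5)
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(cfg, seed = 6)
  expect_false(identical(m1@params, m3@params))
  # the two branches are independently parameterized (no weight tying)
  expect_false(identical(m1@params$branches[[1]]$conv[[1]]$W,
                         m1@params$branches[[2]]$conv[[1]]$W))
  expect_error(ModelConfig(depth = 9, blockLayout = c(2, 2, 2, 2)),
               "depth")
  expect_error(ModelConfig(fusion = "weighted", alpha = 0.5, beta = 0.8),
               "alpha \\+ beta")
  expect_error(ModelConfig(poolLayers = c(1, 2, 3)), "4 distinct")
})

test_that("architecture traversal matches the depth-variant layer inventory", {
  cfg8 <- ModelConfig(depth = 8L, channelsPerBlock = c(2L, 2L, 2L, 2L),
                      fcWidth = 4L, inputSize = 16L)
  expect_equal(architectureSummary(buildModel(cfg8, 1))$convLayerCount, 8L)
  cfg12 <- ModelConfig(depth = 12L, channelsPerBlock = c(2L, 2L, 2L, 2L),
                       fcWidth = 4L, inputSize = 16L)
  expect_equal(ModelConfig(depth = 12L)@blockLayout, c(3L, 3L, 3L, 3L))
  expect_equal(architectureSummary(buildModel(cfg12, 1))$convLayerCount, 12L)
})

test_that("forward pass matches the direct-summation oracle in every mode", {
  set.seed(42)
  for (sharing in c("none", "sum", "concat")) {
    for (fusion in c("concat", "sum", "weighted")) {
      ab <- if (fusion == "weighted") c(0.2, 0.8) else c(1, 1)
      m <- buildModel(tinyConfig(sharing, fusion, ab[1], ab[2]), seed = 7)
      m <- evalMode(randomizeBnState(m))
      img1 <- matrix(runif(256), 16, 16)
      img2 <- matrix(runif(256), 16, 16)
      got <- as.numeric(forwardPass(m, img1, img2))
      want <- oracleForward(m, list(img1, img2))
      expect_equal(got, want, tolerance = 1e-5,
                   label = sprintf("sharing=%s fusion=%s", sharing, fusion))
    }
  }
  # single-branch model against the same oracle
  cfgS <- ModelConfig(depth = 4L, blockLayout = c(1L, 1L, 1L, 1L),
                      channelsPerBlock = c(2L, 3L, 2L, 2L), sharing = "none",
                      sharingLayers = integer(0),
                      poolLayers = c(1L, 2L, 3L, 4L), fcWidth = 5L,
                      dropoutRate = 0, fusion = "sum", alpha = 1, beta = 1,
                      inputSize = 16L, nBranches = 1L)
  mS <- evalMode(randomizeBnState(buildModel(cfgS, seed = 3)))
  img <- matrix(runif(256), 16, 16)
  expect_equal(as.numeric(forwardPass(mS, img)),
               oracleForward(mS, list(img)), tolerance = 1e-5)
})

test_that("softmax probabilities sum to one over many random inputs", {
  m <- evalMode(buildModel(tinyConfig(), seed = 1))
  set.seed(9)
  n <- 10000L
  pre <- array(runif(256 * n), dim = c(16, 16, n))
  post <- array(runif(256 * n), dim = c(16, 16, n))
  p <- forwardPass(m, pre, post)
  expect_equal(dim(p), c(n, 2L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("weighted (0.5, 0.5) fusion is half of sum fusion at the fused vector", {
  mW <- evalMode(buildModel(tinyConfig("sum", "weighted", 0.5, 0.5), seed = 2))
  cfgS <- tinyConfig("sum", "sum")
  mS <- buildModel(cfgS, seed = 99)
  mS@params <- mW@params; mS@state <- mW@state
  mS <- evalMode(mS)
  set.seed(3)
  img1 <- matrix(runif(256), 16, 16); img2 <- matrix(runif(256), 16, 16)
  pack <- function(x) matrix(as.vector(x), ncol = 1)
  fW <- dbnn:::.forwardInternal(mW, list(pack(img1), pack(img2)),
                                keepCache = TRUE)
  fS <- dbnn:::.forwardInternal(mS, list(pack(img1), pack(img2)),
                                keepCache = TRUE)
  expect_equal(fW$cache$fused, 0.5 * fS$cache$fused, tolerance = 1e-6)
})

test_that("branch features are symmetric for tied parameters and gated by sharing", {
  cfg <- tinyConfig("sum", "weighted", 0.2, 0.8)
  m <- buildModel(cfg, seed = 4)
  # tie the branches by copying branch 1 into branch 2
  m@params$branches[[2]] <- m@params$branches[[1]]
  m@state$branches[[2]] <- m@state$branches[[1]]
  m <- evalMode(m)
  set.seed(5)
  img <- matrix(runif(256), 16, 16)
  fx <- branchFeatures(m, img, "pre", companion = img)
  fy <- branchFeatures(m, img, "post", companion = img)
  expect_length(fx, cfg@fcWidth)
  expect_equal(fx, fy, tolerance = 1e-6)
  # companion mandatory whenever features are not branch-local
  expect_error(branchFeatures(m, img, "pre"), "companion")
  expect_error(branchFeatures(trainMode(m), img, "pre", companion = img),
               "eval mode")
})

test_that("a zero-weight branch is inert in the output and in the gradients", {
  cfg <- tinyConfig("none", "weighted", 1, 0)
  m <- evalMode(buildModel(cfg, seed = 6))
  set.seed(7)
  img <- matrix(runif(256), 16, 16)
  pA <- forwardPass(m, img, matrix(runif(256), 16, 16))
  pB <- forwardPass(m, img, matrix(runif(256), 16, 16))
  expect_equal(pA, pB, tolerance = 1e-12)
  # gradients of every post-branch parameter are exactly zero
  pack <- function(x) matrix(as.vector(x), ncol = 1)
  mT <- trainMode(m)
  fwd <- dbnn:::.forwardInternal(
    mT, list(pack(img), pack(matrix(runif(256), 16, 16))),
    train = TRUE, keepCache = TRUE)
  grads <- dbnn:::.backwardInternal(mT, fwd, rbind(c(1, 0)))
  flat <- unlist(grads$branches[[2]])
  expect_true(all(flat == 0))
})

test_that("spatial size halves exactly at each of the four pools", {
  cfg <- ModelConfig(channelsPerBlock = c(2L, 2L, 2L, 2L), fcWidth = 4L,
                     inputSize = 64L)
  m <- trainMode(buildModel(cfg, seed = 1))
  pack <- function(x) matrix(as.vector(x), ncol = 1)
  set.seed(8)
  img <- matrix(runif(64 * 64), 64, 64)
  fwd <- dbnn:::.forwardInternal(m, list(pack(img), pack(img)),
                                 train = TRUE, keepCache = TRUE)
  sides <- vapply(fwd$cache$layers, function(l) l$H, numeric(1))
  # layer-input sides: pooling after layers 2, 4, 7 shows up at 3, 5, 8
  expect_equal(sides, c(64, 64, 32, 32, 16, 16, 16, 8, 8))
  s <- architectureSummary(m)
  expect_equal(s$poolCount, 4L)
})

test_that("checkpoints round-trip through disk", {
  m <- evalMode(buildModel(tinyConfig(), seed = 11))
  path <- file.path(tempdir(), "ckpt.rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(m2@params, m@params)
  expect_identical(m2@mode, "eval")
  set.seed(1)
  img <- matrix(runif(256), 16, 16)
  expect_equal(forwardPass(m2, img, img), forwardPass(m, img, img))
})
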