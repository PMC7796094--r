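test_that("bidirectional ConvLSTM fusion has an exact zero fixed point", {
  a <- array(0, c(4, 4, 2))
  W0 <- array(0, c(3, 3, 4, 8)); b0 <- numeric(8)
  out <- bconvlstmFuse(a, a, W0, b0, W0, b0)
  expect_identical(dim(out), c(4L, 4L, 4L))
  expect_true(all(out == 0))
})

test_that("ConvLSTM fusion matches the hand-unrolled recurrence oracle", {
  set.seed(77)
  C <- 2
  x1 <- array(rnorm(6 * 5 * C), c(6, 5, C))
  x2 <- array(rnorm(6 * 5 * C), c(6, 5, C))
  Wf <- array(rnorm(3 * 3 * 2 * C * 4 * C, 0, 0.3), c(3, 3, 2 * C, 4 * C))
  bf <- rnorm(4 * C, 0, 0.2)
  Wb <- array(rnorm(3 * 3 * 2 * C * 4 * C, 0, 0.3), c(3, 3, 2 * C, 4 * C))
  bb <- rnorm(4 * C, 0, 0.2)
  got <- bconvlstmFuse(x1, x2, Wf, bf, Wb, bb)
  wantF <- oracleLSTMDir(x1, x2, Wf, bf)
  wantB <- oracleLSTMDir(x2, x1, Wb, bb)
  expect_equal(got[, , 1:C], wantF, tolerance = 1e-10)
  expect_equal(got[, , C + 1:C], wantB, tolerance = 1e-10)
  # spatial size preserved
  expect_identical(dim(got)[1:2], dim(x1)[1:2])
})

test_that("reversing the sequence swaps the role of the two parameter sets", {
  set.seed(78)
  C <- 2
  a <- array(rnorm(4 * 4 * C), c(4, 4, C))
  b <- array(rnorm(4 * 4 * C), c(4, 4, C))
  WF <- array(rnorm(144, 0, 0.3), c(3, 3, 4, 8)); bF <- rnorm(8, 0, 0.1)
  WB <- array(rnorm(144, 0, 0.3), c(3, 3, 4, 8)); bB <- rnorm(8, 0, 0.1)
  ab <- bconvlstmFuse(a, b, WF, bF, WB, bB)
  ba <- bconvlstmFuse(b, a, WB, bB, WF, bF)
  expect_equal(ab[, , 1:C], ba[, , C + 1:C], tolerance = 1e-12)
  expect_equal(ab[, , C + 1:C], ba[, , 1:C], tolerance = 1e-12)
})

test_that("fusion rejects mismatched shapes", {
  a <- array(0, c(4, 4, 2)); b <- array(0, c(4, 6, 2))
  W0 <- array(0, c(3, 3, 4, 8))
  expect_error(bconvlstmFuse(a, b, W0, numeric(8), W0, numeric(8)),
               "share spatial size")
})

test_that("the forward pass honours the shape/range contract", {
  cfg <- networkConfig(c(64, 64), baseFilters = 8)
  m <- buildModel(cfg, seed = 3)
  set.seed(1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  pr <- predictModel(m, x)
  expect_identical(dim(pr$prob), c(64L, 64L))
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_true(all(pr$mask@.Data %in% c(0L, 1L)))
  expect_error(predictModel(m, array(0, c(32, 32, 3))), "size")
})

test_that("encoder taps follow the doubling channel schedule", {
  cfg <- networkConfig(c(64, 64), baseFilters = 8)
  m <- buildModel(cfg, seed = 3)
  taps <- encoderFeatures(m, array(0.5, c(64, 64, 3)))
  expect_identical(vapply(taps, function(t) dim(t)[3], 1),
                   c(8, 16, 32, 64))
  expect_identical(vapply(taps, function(t) dim(t)[1], 1),
                   c(16, 8, 4, 2))
})

test_that("architecture construction is deterministic", {
  cfg <- networkConfig(c(64, 64), baseFilters = 8)
  a <- buildModel(cfg, seed = 5)
  b <- buildModel(cfg, seed = 5)
  expect_identical(nParameters(a), nParameters(b))
  expect_identical(a@params, b@params)
  c <- buildModel(cfg, seed = 6)
  expect_identical(nParameters(a), nParameters(c))
  expect_false(identical(a@params$stem.W, c@params$stem.W))
})

test_that("invalid configurations are rejected before any work", {
  expect_error(networkConfig(c(60, 64)), "divisible by 32")
  expect_error(buildModel(networkConfig(c(64, 64), encoderPretrained = TRUE)),
               "pretrainedWeights")
})

test_that("pretrained encoder weights load from an explicit file only", {
  cfg <- networkConfig(c(64, 64), baseFilters = 8, encoderPretrained = TRUE)
  ref <- buildModel(networkConfig(c(64, 64), baseFilters = 8), seed = 42)
  wf <- tempfile(fileext = ".rds")
  saveRDS(ref@params[grep("^(stem|enc)", names(ref@params), value = TRUE)], wf)
  m <- buildModel(cfg, seed = 1, pretrainedWeights = wf)
  expect_identical(m@params$stem.W, ref@params$stem.W)
  expect_identical(m@params$enc4.blk3.c2.W, ref@params$enc4.blk3.c2.W)
  # decoder params still come from this build's seed, not the file
  expect_false(identical(m@params$decS.c1.W, ref@params$decS.c1.W))
})

test_that("one training epoch runs, records history and is deterministic", {
  pairs <- phantomPairs(4, seed = 301)
  cfg <- networkConfig(c(64, 64), baseFilters = 4)
  tc <- trainConfig(epochs = 1, batchSize = 2, learningRate = 1e-3, seed = 9)
  m <- buildModel(cfg, seed = 9)
  f1 <- trainModel(m, pairs[1:2], pairs[3:4], tc)
  expect_identical(nrow(f1$history), 1L)
  expect_true(is.finite(f1$history$trainLoss))
  expect_true(is.finite(f1$history$valDice))
  f2 <- trainModel(m, pairs[1:2], pairs[3:4], tc)
  expect_equal(f1$history$trainLoss, f2$history$trainLoss, tolerance = 1e-12)
  expect_equal(f1$model@params$head.out.W, f2$model@params$head.out.W,
               tolerance = 1e-12)
  expect_error(trainModel(m, list(), pairs[3:4], tc), "empty")
})

test_that("predicted masks are monotone in the threshold", {
  pairs <- phantomPairs(1, seed = 302)
  m <- buildModel(networkConfig(c(64, 64), baseFilters = 4), seed = 2)
  lo <- predictModel(m, pairs[[1]]$x, threshold = 0.05)
  hi <- predictModel(m, pairs[[1]]$x, threshold = 0.95)
  expect_true(all(hi$mask@.Data <= lo$mask@.Data))
})

test_that("every ablation flag combination builds, trains and predicts", {
  pairs <- phantomPairs(2, seed = 303)
  tc <- trainConfig(epochs = 1, batchSize = 2, learningRate = 1e-3, seed = 4)
  for (lstm in c(TRUE, FALSE)) for (dense in c(TRUE, FALSE)) {
    cfg <- networkConfig(c(64, 64), baseFilters = 4, useBConvLSTM = lstm,
                         useDenseBottleneck = dense)
    m <- buildModel(cfg, seed = 4)
    fit <- trainModel(m, pairs, list(), tc)
    expect_true(is.finite(fit$history$trainLoss),
                label = sprintf("lstm=%s dense=%s", lstm, dense))
    pr <- predictModel(fit$model, pairs[[1]]$x)
    expect_identical(dim(pr$prob), c(64L, 64L))
  }
})
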