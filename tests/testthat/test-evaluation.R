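test_that("confusion counts enumerate pixels correctly", {
  ones <- BinaryMask(matrix(1L, 3, 3))
  expect_identical(confusionCounts(ones, ones),
                   c(TP = 9L, FP = 0L, TN = 0L, FN = 0L))
  z <- BinaryMask(matrix(0L, 3, 3))
  cc <- confusionCounts(z, ones)
  expect_identical(cc[["TP"]], 0L)
  expect_identical(cc[["TN"]], 0L)
  # 4x4 with 4 predicted, 4 true, 2 overlapping
  pred <- matrix(0L, 4, 4); pred[1, 1:4] <- 1L
  truth <- matrix(0L, 4, 4); truth[1, 1:2] <- 1L; truth[2, 1:2] <- 1L
  cc <- confusionCounts(BinaryMask(pred), BinaryMask(truth))
  expect_identical(cc, c(TP = 2L, FP = 2L, TN = 10L, FN = 2L))
  expect_identical(sum(cc), 16L)
  expect_error(confusionCounts(ones, BinaryMask(matrix(1L, 2, 2))),
               "dimensions")
})

test_that("accuracy/precision/recall/F1 follow their closed forms", {
  m <- pixelMetrics(c(TP = 2, FP = 2, TN = 10, FN = 2))
  expect_equal(unname(m), c(0.75, 0.5, 0.5, 0.5))
  perfect <- pixelMetrics(c(TP = 5, FP = 0, TN = 0, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  undef <- pixelMetrics(c(TP = 0, FP = 0, TN = 9, FN = 0))
  expect_true(is.na(undef[["precision"]]))
  expect_true(is.na(undef[["recall"]]))
  expect_equal(undef[["accuracy"]], 1)
})

test_that("Dice matches its overlap definition and conventions", {
  a <- BinaryMask(matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4))
  b <- BinaryMask(matrix(c(0, 0, 1, 1, 1, 1, 0, 0), 2, 4))
  expect_equal(diceCoef(a, b), 0.5)  # |E|=|Q|=4, overlap 2
  expect_equal(diceCoef(a, a), 1)
  disj <- BinaryMask(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4))
  expect_equal(diceCoef(a, disj), 0)
  empty <- BinaryMask(matrix(0L, 2, 4))
  expect_equal(diceCoef(empty, empty), 1)
  expect_equal(diceCoef(a, b), diceCoef(b, a))
})

test_that("F1 and Dice coincide on random mask pairs", {
  set.seed(55)
  for (i in 1:100) {
    p <- randomMask(8, 9, runif(1, 0.1, 0.9))
    t <- randomMask(8, 9, runif(1, 0.1, 0.9))
    f1 <- pixelMetrics(confusionCounts(p, t))[["f1"]]
    d <- diceCoef(p, t)
    if (!is.na(f1)) expect_equal(f1, d, tolerance = 1e-12)
  }
})

test_that("AUC reproduces the worked pooled example", {
  p <- matrix(c(.9, .8, .7, .4, .3, .2), 2, 3)
  y <- BinaryMask(matrix(c(1, 1, 0, 1, 0, 0), 2, 3))
  r <- rocAuc(p, y)
  expect_equal(r$auc, 8 / 9)
  expect_equal(max(r$curve$tpr), 1)
  expect_equal(max(r$curve$fpr), 1)
})

test_that("AUC is 1 for perfect separation and 0 for inverted scores", {
  y <- BinaryMask(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(rocAuc(matrix(c(1, 0, 1, 0), 2, 2), y)$auc, 1)
  expect_equal(rocAuc(matrix(c(0, 1, 0, 1), 2, 2), y)$auc, 0)
  onecls <- BinaryMask(matrix(1L, 2, 2))
  expect_true(is.na(rocAuc(matrix(runif(4), 2, 2), onecls)$auc))
})

test_that("AUC equals the pairwise concordance statistic (with pROC check)", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (all(lb == lb[1])) lb[1] <- 1 - lb[1]
    got <- rocAuc(matrix(sc, 1), BinaryMask(matrix(lb, 1)))$auc
    expect_equal(got, oracleAUC(sc, lb), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(67)
    sc <- runif(200); lb <- rbinom(200, 1, 0.4)
    got <- rocAuc(matrix(sc, 1), BinaryMask(matrix(lb, 1)))$auc
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("dataset-level evaluation pools pixels into one confusion matrix", {
  set.seed(68)
  preds <- lapply(1:3, function(i) randomMask(10, 10))
  truths <- lapply(1:3, function(i) randomMask(10, 10))
  probs <- lapply(preds, function(p) {
    pr <- p@.Data * 0.6 + 0.2 + matrix(runif(100, -0.1, 0.1), 10, 10)
    pmin(pmax(pr, 0), 1)
  })
  rep <- evaluateMasks(preds, truths, probs = probs)
  expect_identical(rep@TP + rep@FP + rep@TN + rep@FN, 300)
  ccsum <- Reduce(`+`, Map(confusionCounts, preds, truths))
  expect_identical(c(rep@TP, rep@FP, rep@TN, rep@FN),
                   as.numeric(ccsum[c("TP", "FP", "TN", "FN")]))
  expect_true(rep@auc >= 0 && rep@auc <= 1)
  both <- evaluateMasks(preds, truths, perImage = TRUE)
  expect_identical(nrow(both$perImage), 3L)
})
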