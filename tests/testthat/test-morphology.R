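test_that("HU binarization is a strict threshold", {
  s <- CTSlice(matrix(c(-1000, 0, -604, -604.001), 2, 2))
  m <- binarizeHU(s)
  expect_identical(as.vector(m@.Data), c(1L, 0L, 0L, 1L))
})

test_that("binarization is monotone in the threshold", {
  set.seed(31)
  s <- CTSlice(matrix(runif(400, -1200, 200), 20, 20))
  m1 <- binarizeHU(s, -800)
  m2 <- binarizeHU(s, -400)
  expect_true(all(m1@.Data <= m2@.Data))
})

test_that("border clearing removes exactly the border-connected blobs", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_identical(clearBorder(BinaryMask(m))@.Data, m)
  expect_identical(sum(clearBorder(BinaryMask(matrix(1L, 5, 5)))@.Data), 0L)
  # one border blob, one interior blob
  m <- matrix(0L, 7, 7); m[1:2, 1:2] <- 1L; m[4:5, 4:5] <- 1L
  out <- clearBorder(BinaryMask(m))
  expect_identical(out@.Data, oracleClearBorder(m))
  expect_identical(sum(out@.Data), 4L)
})

test_that("component labelling respects connectivity", {
  expect_identical(nLabels(labelComponents(BinaryMask(matrix(0L, 4, 4)))), 0L)
  m <- matrix(0L, 5, 5); m[1, 1] <- 1L; m[5, 5] <- 1L
  expect_identical(nLabels(labelComponents(BinaryMask(m))), 2L)
  d <- matrix(0L, 4, 4); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_identical(nLabels(labelComponents(BinaryMask(d), 8)), 1L)
  expect_identical(nLabels(labelComponents(BinaryMask(d), 4)), 2L)
})

test_that("labels form connected regions matching a flood-fill oracle", {
  set.seed(41)
  for (conn in c(4, 8)) for (i in 1:10) {
    m <- randomMask(12, 15, 0.45)
    lab <- labelComponents(m, conn)
    expect_identical(nLabels(lab), oracleComponentCount(m@.Data, conn))
    # every label is one flood-fill component
    for (l in seq_len(nLabels(lab))) {
      seed <- which(lab@.Data == l, arr.ind = TRUE)[1, , drop = FALSE]
      comp <- oracleFlood(m@.Data == 1, seed, conn)
      expect_identical(unname(which(lab@.Data == l)), unname(which(comp)))
    }
  }
})

test_that("keepLargestK selects components by area with deterministic ties", {
  m <- matrix(0L, 12, 20)
  m[2:6, 2:11] <- 1L      # area 50
  m[8:11, 2:11] <- 1L     # area 40
  m[2:4, 18] <- 1L        # area 3
  lab <- labelComponents(BinaryMask(m))
  out <- keepLargestK(lab, 2)
  expect_identical(sum(out@.Data), 90L)
  expect_identical(sum(out@.Data[, 18]), 0L)
  # single component unchanged; empty map empty
  single <- labelComponents(BinaryMask(matrix(c(0L, 1L, 1L, 0L), 2, 2)))
  expect_identical(keepLargestK(single, 2)@.Data,
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_identical(sum(keepLargestK(labelComponents(
    BinaryMask(matrix(0L, 3, 3))), 2)@.Data), 0L)
})

test_that("erosion and dilation match their set definitions", {
  all5 <- BinaryMask(matrix(1L, 5, 5))
  expect_identical(maskErode(all5, diskElement(2))@.Data,
                   oracleErode(all5@.Data, 2))
  lone <- matrix(0L, 5, 5); lone[3, 3] <- 1L
  expect_identical(sum(maskErode(BinaryMask(lone), diskElement(2))@.Data), 0L)
  # single pixel dilation with r=1 is the cross
  d <- maskDilate(BinaryMask(lone), diskElement(1))
  expect_identical(which(d@.Data == 1L),
                   c(which(lone == 1L) + c(-5L, -1L, 0L, 1L, 5L)))
  empty <- BinaryMask(matrix(0L, 6, 6))
  expect_identical(sum(maskErode(empty, diskElement(2))@.Data), 0L)
  expect_identical(sum(maskDilate(empty, diskElement(2))@.Data), 0L)
})

test_that("morphology operators equal brute-force oracles on random masks", {
  set.seed(99)
  for (i in 1:25) {
    h <- sample(5:20, 1); w <- sample(5:20, 1)
    m <- randomMask(h, w, runif(1, 0.2, 0.7))
    r <- sample(1:3, 1)
    expect_identical(maskErode(m, diskElement(r))@.Data, oracleErode(m@.Data, r))
    expect_identical(maskDilate(m, diskElement(r))@.Data, oracleDilate(m@.Data, r))
    expect_identical(maskClose(m, diskElement(r))@.Data, oracleClose(m@.Data, r))
    expect_identical(fillHoles(m)@.Data, oracleFillHoles(m@.Data))
    expect_identical(clearBorder(m)@.Data, oracleClearBorder(m@.Data))
  }
})

test_that("erosion/dilation satisfy duality, extensivity and idempotence", {
  set.seed(17)
  selem <- diskElement(2)
  for (i in 1:10) {
    m <- randomMask(15, 15, 0.5)
    er <- maskErode(m, selem); di <- maskDilate(m, selem)
    expect_true(all(er@.Data <= m@.Data))          # anti-extensive
    expect_true(all(m@.Data <= di@.Data))          # extensive
    cl <- maskClose(m, selem)
    expect_true(all(m@.Data <= cl@.Data))
    expect_identical(maskClose(cl, selem)@.Data, cl@.Data)  # idempotent
    fh <- fillHoles(m)
    expect_identical(fillHoles(fh)@.Data, fh@.Data)
    # duality on the padded interior: dilation of m = complement of erosion
    # of the complement (checked away from the frame border, where the
    # out-of-frame background convention breaks the identity)
    comp <- BinaryMask(1L - m@.Data)
    dual <- 1L - maskErode(comp, selem)@.Data
    inner <- 3:13
    expect_identical(di@.Data[inner, inner], dual[inner, inner])
  }
})

test_that("closing bridges a narrow slit in a block", {
  m <- matrix(1L, 30, 30)
  m[, 14:16] <- 0L  # 3-px slit, open at both frame edges
  out <- maskClose(BinaryMask(m), diskElement(10))
  # the slit is sealed everywhere except the open mouths at the frame edge,
  # where the disk cannot be covered on the infinite canvas
  expect_true(all(out@.Data[2:29, ] == 1L))
  expect_true(all(m <= out@.Data))
  expect_identical(out@.Data, oracleClose(m, 10))
})

test_that("hole filling turns a hollow ring solid and is conservative", {
  ring <- matrix(0L, 7, 7)
  ring[2:6, 2:6] <- 1L; ring[3:5, 3:5] <- 0L
  filled <- fillHoles(BinaryMask(ring))
  want <- matrix(0L, 7, 7); want[2:6, 2:6] <- 1L
  expect_identical(filled@.Data, want)
  open <- matrix(0L, 5, 5); open[2:3, 2:3] <- 1L
  expect_identical(fillHoles(BinaryMask(open))@.Data, open)
})

test_that("the seven-step pipeline is pure and flags empty outcomes", {
  pm <- generatePhantom(PhantomSpec(seed = 8))
  a <- extractLungMask(pm$slice)
  b <- extractLungMask(pm$slice)
  expect_identical(a@.Data, b@.Data)
  expect_false(attr(a, "needsReview"))
  air <- CTSlice(matrix(-1000, 64, 64))
  expect_warning(empty <- extractLungMask(air), "manual review")
  expect_identical(sum(empty@.Data), 0L)
  expect_true(attr(empty, "needsReview"))
})

test_that("wall-attached nodules survive only through the closing step", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, attachNodule = TRUE,
                                    noduleRadius = 6, seed = 14))
  m <- extractLungMask(pm$slice)
  expect_true(all(m@.Data[pm$nodule] == 1L))
  p <- maskPipelineParams(); p$closeRadius <- 1
  weak <- extractLungMask(pm$slice, p)
  expect_true(any(weak@.Data[pm$nodule] == 0L))
})

test_that("extra border blobs do not disturb the lungs", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, seed = 4))
  hu <- huPixels(pm$slice)
  hu[1:6, 100:140] <- -900  # a dark blob touching the frame
  m <- extractLungMask(CTSlice(hu))
  expect_gte(diceCoef(m, pm$mask), 0.95)
  expect_identical(sum(m@.Data[1:6, ]), 0L)
})
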