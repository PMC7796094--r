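test_that("channel binarization is the polarity complement of Eq.-style masks", {
  s <- CTSlice(matrix(c(-1000, 40, -604, -700), 2, 2))
  b <- binarizeForChannels(s)
  expect_identical(b@.Data, 1L - binarizeHU(s)@.Data)
  expect_identical(b@.Data[1, 1], 0L)  # lung is black
  expect_identical(b@.Data[2, 1], 1L)
})

test_that("white dilation removes black specks and only shrinks the lungs", {
  m <- matrix(1L, 11, 11)
  m[6, 6] <- 0L  # isolated black noise pixel
  out <- dilationChannel(BinaryMask(m), diskElement(2))
  expect_identical(sum(out@.Data), 121L)
  allw <- BinaryMask(matrix(1L, 8, 8))
  expect_identical(dilationChannel(allw)@.Data, allw@.Data)
  set.seed(5)
  b <- randomMask(16, 16, 0.6)
  out <- dilationChannel(b, diskElement(2))
  expect_lte(sum(out@.Data == 0L), sum(b@.Data == 0L))
})

test_that("Canny finds nothing on a constant image", {
  expect_identical(sum(cannyEdges(CTSlice(matrix(7, 20, 20)))@.Data), 0L)
})

test_that("Canny thins a strong vertical step to about one pixel", {
  img <- matrix(-1000, 32, 32); img[, 17:32] <- 200
  e <- cannyEdges(CTSlice(img), sigma = 1.4)
  widths <- rowSums(e@.Data)
  expect_true(all(widths <= 2))
  expect_true(all(widths >= 1))
  cols <- which(colSums(e@.Data) > 0)
  expect_true(all(abs(cols - 16.5) <= 2))
})

test_that("Canny hysteresis validates its thresholds", {
  img <- matrix(rnorm(400), 20, 20)
  expect_error(cannyEdges(CTSlice(img), 1, low = 5, high = 2), "low <= high")
})

test_that("phantom lung boundaries are traced by the edge channel", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, nVessels = 0, seed = 6))
  e <- cannyEdges(pm$slice)
  boundary <- pm$mask@.Data - maskErode(pm$mask, diskElement(1))@.Data
  near <- maskDilate(e, diskElement(2))@.Data
  coverage <- sum(near[boundary == 1L]) / sum(boundary)
  expect_gte(coverage, 0.9)
})

test_that("assembled channels satisfy their per-channel contracts", {
  pm <- generatePhantom(PhantomSpec(seed = 3))
  x <- assembleChannels(pm$slice)
  ch <- imageChannels(x)
  expect_identical(dim(ch), c(256L, 256L, 3L))
  expect_true(all(ch >= 0 & ch <= 1))
  expect_true(all(ch[, , 2] %in% c(0, 1)))
  expect_true(all(ch[, , 3] %in% c(0, 1)))
  # channel 1 is the windowed original: lungs darker than the body wall
  expect_lt(mean(ch[, , 1][pm$mask@.Data == 1L]),
            mean(ch[, , 1][huPixels(pm$slice) > -100]))
  # deterministic
  y <- assembleChannels(pm$slice)
  expect_identical(imageChannels(y), ch)
})

test_that("a constant slice yields uniform/empty channels", {
  s <- CTSlice(matrix(-1000, 32, 32))
  x <- imageChannels(assembleChannels(s))
  expect_identical(length(unique(as.vector(x[, , 1]))), 1L)
  expect_identical(sum(x[, , 2]), 0)
})

test_that("a degenerate normalization window warns and zeroes channel 1", {
  s <- CTSlice(matrix(c(-1000, 0), 16, 16))
  p <- channelParams(); p$window <- c(100, 100)
  expect_warning(x <- assembleChannels(s, p), "degenerate")
  expect_identical(sum(imageChannels(x)[, , 1]), 0)
})

test_that("default-channel replication mirrors the original in all channels", {
  pm <- generatePhantom(PhantomSpec(seed = 12))
  x <- assembleChannels(pm$slice, defaultChannels = TRUE)
  ch <- imageChannels(x)
  expect_identical(ch[, , 1], ch[, , 2])
  expect_identical(ch[, , 1], ch[, , 3])
  expect_false(x@engineered)
})
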