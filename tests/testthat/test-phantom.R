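test_that("noiseless vessel-free phantom has an exact lung field", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, nVessels = 0,
                                    attachNodule = FALSE, seed = 2))
  hu <- huPixels(pm$slice)
  expect_true(all(hu[pm$mask@.Data == 1L] == -800))
  expect_true(all(hu[pm$mask@.Data == 0L] %in% c(-1000, 40)))
})

test_that("phantom generation is bit-identical for equal seeds", {
  a <- generatePhantom(PhantomSpec(seed = 7, attachNodule = TRUE))
  b <- generatePhantom(PhantomSpec(seed = 7, attachNodule = TRUE))
  expect_identical(huPixels(a$slice), huPixels(b$slice))
  expect_identical(a$mask@.Data, b$mask@.Data)
})

test_that("attached nodule lies against the lung wall inside the truth mask", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, attachNodule = TRUE,
                                    noduleRadius = 6, seed = 5))
  expect_true(any(pm$nodule))
  expect_true(all(pm$mask@.Data[pm$nodule] == 1L))
  # nodule pixels are above the threshold, so thresholding carves them out
  expect_true(all(huPixels(pm$slice)[pm$nodule] > -604))
  # attached: some nodule pixel within a few pixels of the mask boundary
  interior <- maskErode(pm$mask, diskElement(6))
  expect_true(any(pm$nodule & interior@.Data == 0L))
})

test_that("ground-truth masks never touch the image border", {
  for (s in 1:5) {
    pm <- generateCohort(1, PhantomSpec(seed = s, attachNodule = TRUE),
                         jitter = 0.3)[[1]]
    m <- pm$mask@.Data
    expect_identical(sum(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]), 0L)
  }
})

test_that("invalid phantom specs fail validity naming the constraint", {
  expect_error(PhantomSpec(lungHU = -500), "-604")
  expect_error(PhantomSpec(noduleHU = -700), "-604")
  expect_error(PhantomSpec(noiseSD = -1), "noiseSD")
  expect_error(PhantomSpec(height = 16, width = 16), "32x32")
})

test_that("a degenerate cohort equals the single phantom", {
  spec <- PhantomSpec(seed = 21, attachNodule = TRUE)
  coh <- generateCohort(1, spec, jitter = 0)
  one <- generatePhantom(spec)
  expect_identical(huPixels(coh[[1]]$slice), huPixels(one$slice))
  expect_identical(coh[[1]]$mask@.Data, one$mask@.Data)
})

test_that("a jittered cohort is reproducible and pairwise distinct", {
  spec <- PhantomSpec(height = 128, width = 128, seed = 3)
  a <- generateCohort(50, spec, jitter = 0.2)
  b <- generateCohort(50, spec, jitter = 0.2)
  for (i in c(1, 25, 50))
    expect_identical(huPixels(a[[i]]$slice), huPixels(b[[i]]$slice))
  # exhaustive pairwise comparison of all 50 masks
  dup <- FALSE
  for (i in 1:49) for (j in (i + 1):50)
    if (identical(a[[i]]$mask@.Data, a[[j]]$mask@.Data)) dup <- TRUE
  expect_false(dup)
})

test_that("the extraction pipeline recovers the phantom ground truth", {
  pm <- generatePhantom(PhantomSpec(noiseSD = 0, seed = 13))
  m <- extractLungMask(pm$slice)
  expect_gte(diceCoef(m, pm$mask), 0.95)
})
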