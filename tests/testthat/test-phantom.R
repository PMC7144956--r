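test_that("sampleFatMask selects an exact pixel count", {
  region <- matrix(FALSE, 20, 20)
  region[3:12, 5:24 - 4] <- TRUE  # 10 x 20 block, N = 200
  expect_equal(sum(region), 200)
  set.seed(1)
  expect_equal(sum(sampleFatMask(region, 0.137)), 27)  # round(27.4)
  expect_equal(sum(sampleFatMask(region, 0)), 0)
  expect_true(all(sampleFatMask(region, 1)[region]))
  expect_equal(sum(sampleFatMask(region, 1)), 200)
  m <- sampleFatMask(region, 0.3, marblingScale = 4, spacing = 1)
  expect_equal(sum(m), 60)
  expect_true(all(region[m]))
  expect_error(sampleFatMask(matrix(FALSE, 5, 5), 0.5), "empty region")
})

test_that("fat masks are deterministic under a seed and vary across seeds", {
  region <- matrix(TRUE, 30, 30)
  m1 <- withr::with_seed(7, sampleFatMask(region, 0.2, 3))
  m2 <- withr::with_seed(7, sampleFatMask(region, 0.2, 3))
  m3 <- withr::with_seed(8, sampleFatMask(region, 0.2, 3))
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
})

test_that("phantom with no fat, noise or bias is flat inside muscles", {
  spec <- smallSpec(noiseSD = 0, biasAmplitude = 0, partialVolumeWidth = 0,
                    fatFraction = c(VL = 0, AM = 0, BFL = 0), seed = 2)
  ph <- makePhantom(spec)
  for (m in c("VL", "VI", "AM", "BFL")) {
    vals <- imageData(ph@t1w)[compartmentMask(ph, m)]
    expect_true(all(vals == 100), info = m)
  }
  expect_equal(unname(truthP(ph)), c(0, 0, 0, 0))
})

test_that("realized fat fractions match targets within one pixel quantum", {
  spec <- smallSpec(noiseSD = 0, biasAmplitude = 0, partialVolumeWidth = 0,
                    fatFraction = c(VL = 0.25, AM = 0.1, BFL = 0.4),
                    seed = 5)
  ph <- makePhantom(spec)
  for (m in c("VL", "AM", "BFL")) {
    msk <- compartmentMask(ph, m)
    p <- spec@fatFraction[[m]]
    frac <- sum(imageData(ph@t1w)[msk] == 200) / sum(msk)
    expect_lte(abs(frac - p), 1 / sum(msk))
    expect_lte(abs(truthP(ph)[[m]] - p), 1 / sum(msk))
  }
  # vastus intermedius is the fat-free reference by construction
  expect_identical(truthP(ph)[["VI"]], 0)
})

test_that("phantom generation is bit-reproducible under its seed", {
  spec <- smallSpec(seed = 11)
  ph1 <- makePhantom(spec)
  ph2 <- makePhantom(spec)
  expect_identical(imageData(ph1@t1w), imageData(ph2@t1w))
  expect_identical(imageData(ph1@water), imageData(ph2@water))
  expect_identical(imageData(ph1@fat), imageData(ph2@fat))
  expect_identical(truthP(ph1), truthP(ph2))
})

test_that("noiseless Dixon channels conserve the proton signal", {
  spec <- smallSpec(noiseSD = 0, partialVolumeWidth = 2, seed = 4)
  ph <- makePhantom(spec)
  tot <- imageData(ph@water) + imageData(ph@fat)
  tissue <- imageData(ph@labels) != 0
  cortex <- imageData(ph@t1w) == 0 & tissue  # signal-free bone shell
  expect_true(all(abs(tot[tissue & !cortex] - 100) < 1e-9))
  expect_true(all(tot[!tissue] == 0))
  ff <- imageData(ph@truthFatFraction)
  expect_true(all(ff >= 0 & ff <= 1))
})

test_that("partial-volume band carries mixed intensity and fat fraction", {
  spec <- smallSpec(noiseSD = 0, biasAmplitude = 0, partialVolumeWidth = 2,
                    fatFraction = c(VL = 0.2, AM = 0.1, BFL = 0.1),
                    seed = 9)
  ph <- makePhantom(spec)
  vl <- compartmentMask(ph, "VL")
  ff <- imageData(ph@truthFatFraction)[vl]
  t1 <- imageData(ph@t1w)[vl]
  band <- ff > 0 & ff < 1
  expect_gt(sum(band), 0)
  # linear mixing: intensity = 100 + 100 * ff on band pixels
  expect_equal(t1[band], 100 + 100 * ff[band], tolerance = 1e-12)
})

test_that("applyBiasField honors its normalization contract", {
  img <- matrix(100, 64, 64)
  out0 <- applyBiasField(img, 0, 40)
  expect_identical(out0$image, img)
  expect_true(all(out0$field == 1))
  set.seed(3)
  out <- applyBiasField(img, 0.3, 20)
  expect_lt(abs(mean(out$field) - 1), 1e-6)
  expect_lt(abs(max(abs(out$field - 1)) - 0.3), 1e-6)
  expect_true(all(out$field > 0))
  expect_equal(out$image, img * out$field)
  expect_error(applyBiasField(img, 1.2, 20), "amplitude")
})

test_that("phantom spec validity rejects impossible parameters", {
  expect_error(phantomSpec(fatFraction = c(VL = 1.2, AM = 0, BFL = 0)),
               "0, 1")
  expect_error(phantomSpec(muscleMeanIntensity = 300),
               "exceed")
  expect_error(phantomSpec(noiseSD = -1), "noiseSD")
  bad <- thighGeometry(256)
  bad$VL$radii <- c(200, 200)
  expect_error(makePhantom(phantomSpec(geometry = bad)), "overflow")
})
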