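test_that("reference ROIs are 25 mm^2 squares inside their labels", {
  spec <- fullSpec(seed = 31)
  ph <- makePhantom(spec)
  rois <- placeROIs(ph@labels, seed = 41)
  expect_identical(rois@side, 5L)  # sqrt(25 mm^2) at 1 mm spacing
  expect_identical(sort(table(rois@tag), decreasing = TRUE),
                   sort(table(c(rep("muscle_reference", 3),
                                rep("fat_reference", 3))), decreasing = TRUE))
  lab <- imageData(ph@labels)
  tab <- compartmentTable(ph)
  for (i in seq_len(nrow(rois@topLeft))) {
    tl <- rois@topLeft[i, ]
    block <- lab[tl[1]:(tl[1] + 4), tl[2]:(tl[2] + 4)]
    want <- if (rois@tag[i] == "muscle_reference") tab[["VI"]]
            else tab[["subcutaneous_fat"]]
    expect_true(all(block == want))
  }
  # non-overlap
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(all(abs(rois@topLeft[i, ] - rois@topLeft[j, ]) < 5))
  }
  # determinism under seed
  rois2 <- placeROIs(ph@labels, seed = 41)
  expect_identical(rois@topLeft, rois2@topLeft)
})

test_that("ROI placement fails on labels too small to host three ROIs", {
  lab <- matrix(0L, 40, 40)
  lab[2:9, 2:9] <- 2L   # VI: only 8x8, cannot host three 5x5 squares
  lab[20:39, 20:39] <- 5L
  lm <- LabelMask(lab, spacing = 1)
  expect_error(placeROIs(lm, seed = 1), "VI")
})

test_that("pooled reference histogram conserves pixel counts", {
  spec <- fullSpec(noiseSD = 0, biasAmplitude = 0, seed = 32)
  ph <- makePhantom(spec)
  rois <- placeROIs(ph@labels, seed = 42)
  h <- buildReferenceHistogram(ph@t1w, rois)
  expect_identical(h@n, 150L)  # 6 ROIs x 25 pixels
  expect_equal(sum(h@counts), 150)
  # noiseless two-intensity image: exactly two nonempty bins, 75 each
  expect_identical(sum(h@counts > 0), 2L)
  expect_equal(unname(h@counts[h@counts > 0]), c(75, 75))
  flat <- MRImage2D(matrix(100, 256, 256))
  expect_error(buildReferenceHistogram(flat, rois), "degenerate")
})

test_that("otsuThreshold matches an exhaustive search with low-tie rule", {
  # two delta peaks at 100 and 200 a.u.: threshold separates them
  counts <- rep(0, 256)
  breaks <- seq(50, 250, length.out = 257)
  counts[findInterval(c(100, 200), breaks)] <- 75
  h2 <- new("HistogramModel", breaks = breaks, counts = counts, n = 150L)
  thr <- otsuThreshold(h2)
  expect_gt(thr, 100)
  expect_lt(thr, 200)
  # worked example on unit bins
  h5 <- new("HistogramModel", breaks = 0:5,
            counts = c(4, 4, 0, 4, 4), n = 16L)
  expect_equal(otsuThreshold(h5), bruteOtsu(0:5, c(4, 4, 0, 4, 4)))
  # randomized oracle agreement
  set.seed(77)
  for (i in 1:200) {
    h <- randomHistogram()
    expect_identical(otsuThreshold(h), bruteOtsu(h@breaks, h@counts))
  }
  # count-scale invariance
  h10 <- new("HistogramModel", breaks = h5@breaks, counts = h5@counts * 10,
             n = 160L)
  expect_identical(otsuThreshold(h10), otsuThreshold(h5))
  h1 <- new("HistogramModel", breaks = 0:3, counts = c(5, 0, 0), n = 5L)
  expect_error(otsuThreshold(h1), "nonempty")
})

test_that("threshold trials average repeated random placements", {
  spec <- fullSpec(noiseSD = 0, biasAmplitude = 0, seed = 33)
  ph <- makePhantom(spec)
  tr <- thresholdTrials(ph@t1w, ph@labels, seed = 51)
  expect_length(trialThresholds(tr), 3L)
  # noiseless two-intensity phantom: every trial sees the same histogram
  expect_true(all(trialThresholds(tr) == trialThresholds(tr)[1]))
  expect_equal(thresholdMean(tr), trialThresholds(tr)[1])
  one <- thresholdTrials(ph@t1w, ph@labels, nTrials = 1, seed = 52)
  expect_equal(thresholdMean(one), trialThresholds(one)[1])
  # reproducible under seed on noisy data
  phn <- makePhantom(fullSpec(seed = 34))
  a <- thresholdTrials(phn@t1w, phn@labels, seed = 53)
  b <- thresholdTrials(phn@t1w, phn@labels, seed = 53)
  expect_identical(trialThresholds(a), trialThresholds(b))
})

test_that("T1W quantification counts pixels by the at-threshold rule", {
  img <- matrix(c(rep(100, 80), rep(200, 20)), 10, 10)
  msk <- matrix(TRUE, 10, 10)
  q <- quantifyT1W(img, msk, 150, spacing = 1)
  expect_equal(q$intramatPercent, 20)
  expect_equal(q$nMuscle + q$nFat, 100)
  # pixels exactly at the threshold count as muscle
  expect_equal(quantifyT1W(img, msk, 200, spacing = 1)$intramatPercent, 0)
  expect_equal(quantifyT1W(img, msk, 250, spacing = 1)$intramatPercent, 0)
  expect_error(quantifyT1W(img, matrix(FALSE, 10, 10), 150, spacing = 1),
               "empty")
})

test_that("IntraMAT percent is non-decreasing as the threshold drops", {
  ph <- makePhantom(fullSpec(seed = 35))
  msk <- compartmentMask(ph, "BFL")
  thr <- seq(250, 50, by = -10)
  pct <- vapply(thr, function(t)
    quantifyT1W(ph@t1w, msk, t)$intramatPercent, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("noiseless clean phantoms are recovered exactly by T1W", {
  spec <- fullSpec(noiseSD = 0, biasAmplitude = 0, partialVolumeWidth = 0,
                   fatFraction = c(VL = 0.25, AM = 0.05, BFL = 0.4),
                   seed = 36)
  ph <- makePhantom(spec)
  tr <- thresholdTrials(ph@t1w, ph@labels, seed = 54)
  for (m in c("VL", "AM", "BFL")) {
    msk <- compartmentMask(ph, m)
    q <- quantifyT1W(ph@t1w, msk, thresholdMean(tr), muscle = m)
    expect_lte(abs(q$intramatPercent - 100 * truthP(ph)[[m]]),
               100 / sum(msk))
  }
})

test_that("cross-sectional area converts pixel counts to cm^2", {
  msk <- matrix(FALSE, 20, 20)
  msk[1:10, 1:10] <- TRUE
  expect_equal(computeCSA(msk, 1), 1)
  expect_equal(computeCSA(msk, 2), 4)
  expect_error(computeCSA(matrix(FALSE, 2, 2), 1), "empty")
  expect_error(computeCSA(msk, 0), "positive")
  # elliptical thigh mask vs analytic area
  g <- thighGeometry(256)
  thigh <- imatQuant:::ellipseMask(c(256L, 256L), 1, g$thigh$center,
                                   g$thigh$radii)
  analytic <- pi * g$thigh$radii[1] * g$thigh$radii[2] / 100
  expect_lt(abs(computeCSA(thigh, 1) - analytic) / analytic, 0.02)
})
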