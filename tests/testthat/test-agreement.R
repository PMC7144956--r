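test_that("pooled t-test matches the closed form and its symmetries", {
  same <- unpairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sh <- unpairedTTest(c(1, 2, 3), c(11, 12, 13))
  expect_equal(sh$t, -10 / sqrt(2 / 3), tolerance = 1e-12)  # sp = 1
  expect_equal(sh$df, 4)
  expect_lt(sh$p, 0.05)
  sw <- unpairedTTest(c(11, 12, 13), c(1, 2, 3))
  expect_equal(sw$t, -sh$t)
  expect_equal(sw$p, sh$p)
  expect_error(unpairedTTest(c(5, 5), c(5, 5)), "degenerate")
})

test_that("Bland-Altman fields follow the 2PD - T1W convention", {
  # identical methods
  ba0 <- blandAltman(c(5, 10, 15), c(5, 10, 15))
  expect_equal(ba0$meanDiff, 0)
  expect_equal(c(ba0$loaLow, ba0$loaHigh), c(0, 0))
  expect_true(is.na(ba0$propBiasR))
  # hand-checked arithmetic: d = (2, -2, -6)
  ba <- blandAltman(t1w = c(10, 20, 30), dixon = c(12, 18, 24))
  expect_equal(ba$meanDiff, -2)
  expect_equal(ba$sdDiff, 4)
  expect_equal(ba$loaLow, -2 - 1.96 * 4)
  expect_equal(ba$loaHigh, -2 + 1.96 * 4)
  # proportional pairs: t1w = 2 * dixon makes d shrink as the mean grows
  dx <- seq(5, 24, length.out = 20)
  bap <- blandAltman(t1w = 2 * dx, dixon = dx)
  expect_equal(bap$propBiasR, -1, tolerance = 1e-12)
  expect_lt(bap$propBiasP, 1e-6)
  expect_true(bap$proportionalBias)
  expect_error(blandAltman(c(1, 2), c(1, 2)), "three")
})

test_that("ICC(2,1) equals the ANOVA mean-squares oracle", {
  # worked 4 x 2 example against stats::aov
  set.seed(71)
  for (i in 1:25) {
    n <- sample(4:8, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, 10, 3), n, k) +
      rnorm(n) %o% rep(1, k)  # subject effects
    df <- data.frame(y = as.vector(x),
                     subj = factor(rep(seq_len(n), k)),
                     sess = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + sess, df))[[1]][["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    expect_equal(icc21(x)$value, oracle, tolerance = 1e-10)
  }
})

test_that("ICC(2,1) is exactly 1 for identical sessions and punishes offsets", {
  x <- cbind(c(3, 8, 21, 34), c(3, 8, 21, 34))
  expect_identical(icc21(x)$value, 1)
  # large systematic offset, small subject spread: absolute agreement drops
  y <- cbind(c(10, 11, 12, 13), c(10, 11, 12, 13) + 20)
  expect_lt(icc21(y)$value, 0.2)
  expect_error(icc21(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc21(matrix(1:4, 4, 1)), "sessions")
})

test_that("boundary value is the strict-exceedance quantile", {
  img <- matrix(as.numeric(1:100), 10)
  msk <- matrix(TRUE, 10, 10)
  expect_equal(boundaryValue(img, msk, 0), 100)     # target 0: the max
  expect_equal(boundaryValue(img, msk, 20), 80)     # exactly 20 above
  expect_equal(boundaryValue(img, msk, 100), 1)
  # brute-force scan oracle on small random data
  set.seed(72)
  for (i in 1:20) {
    v <- matrix(sample(1:50, 36, replace = TRUE), 6)
    tgt <- runif(1, 0, 100)
    cand <- sort(unique(as.vector(v)))
    ok <- cand[vapply(cand, function(t)
      mean(v > t) <= tgt / 100, logical(1))]
    expect_equal(boundaryValue(v, matrix(TRUE, 6, 6), tgt), min(ok))
  }
})

test_that("re-thresholding at the boundary value recovers the target", {
  set.seed(73)
  for (i in 1:50) {
    v <- matrix(runif(400, 0, 200), 20)
    msk <- matrix(runif(400) < 0.8, 20)
    if (!any(msk)) next
    tgt <- runif(1, 0, 100)
    bv <- boundaryValue(v, msk, tgt)
    got <- quantifyT1W(v, msk, bv, spacing = 1)$intramatPercent
    expect_lte(got, tgt + 1e-9)
    expect_gte(got, tgt - 100 / sum(msk) - 1e-9)
  }
  # monotone: higher target, lower (or equal) boundary
  v <- matrix(runif(400, 0, 200), 20)
  msk <- matrix(TRUE, 20, 20)
  bv <- vapply(seq(0, 100, by = 5), function(t)
    boundaryValue(v, msk, t), numeric(1))
  expect_true(all(diff(bv) <= 0))
})

test_that("discrepancy correlation behaves under negation and degeneracy", {
  rec <- data.frame(deltaIntramat = c(-1, -4, -9, -13),
                    deltaIntensity = c(1, 3, 8, 12))
  d <- discrepancyAnalysis(rec)
  expect_lt(d$r, -0.9)
  rec2 <- rec; rec2$deltaIntensity <- -rec2$deltaIntensity
  expect_equal(discrepancyAnalysis(rec2)$r, -d$r)
  rec3 <- rec; rec3$deltaIntensity <- rep(2, 4)
  expect_error(discrepancyAnalysis(rec3), "zero variance")
})

test_that("subtraction SNR honors its sentinels and invariances", {
  set.seed(74)
  a <- matrix(rnorm(400, 50, 5), 20)
  rois <- cornerROIs(c(20L, 20L), sizePx = 6L, marginPx = 2L)
  same <- snrSubtraction(a, a, rois)
  expect_true(all(is.infinite(same$snr)))
  b <- matrix(rnorm(400, 50, 5), 20)
  sn <- snrSubtraction(a, b, rois)
  sn3 <- snrSubtraction(3 * a, 3 * b, rois)
  expect_equal(sn3$signalMean, 3 * sn$signalMean)
  expect_equal(sn3$diffSD, 3 * sn$diffSD)
  expect_equal(sn3$snr, sn$snr)
  expect_identical(sn$roi, c("ROI1", "ROI2", "ROI3", "ROI4"))
})

test_that("group comparison mirrors the study table layout", {
  set.seed(75)
  df <- expand.grid(subject = 1:10, muscle = c("VL", "AM", "BFL"),
                    method = c("T1W", "2PD"), stringsAsFactors = FALSE)
  df$group <- ifelse(df$subject <= 5, "younger", "older")
  base <- ifelse(df$group == "older", 16, 8)
  df$intramatPercent <- rnorm(nrow(df), base, 1.5)
  tab <- compareGroups(df)
  expect_equal(nrow(tab), 6)  # muscles x methods
  expect_true(all(tab$p < 0.05))
  expect_true(all(tab$mean2 > tab$mean1 | tab$group2 == "younger"))
  # identical groups: no significance
  df$intramatPercent <- rep(rep(rnorm(5, 10, 2), 2), 6)
  tab0 <- compareGroups(df)
  expect_true(all(tab0$p == 1))
  expect_true(all(tab0$t == 0))
})

test_that("repeated segmentations of one subject are highly concordant", {
  # reproducibility design: two ROI-placement sessions per subject
  pcts <- matrix(0, 6, 2)
  for (s in 1:6) {
    ph <- makePhantom(fullSpec(noiseSD = 2, biasAmplitude = 0,
                               fatFraction = c(VL = 0.05 * s, AM = 0.1,
                                               BFL = 0.3),
                               seed = 80 + s))
    for (sess in 1:2) {
      thr <- thresholdTrials(ph@t1w, ph@labels, seed = 90 + 10 * s + sess)
      pcts[s, sess] <- quantifyT1W(ph@t1w, compartmentMask(ph, "VL"),
                                   thresholdMean(thr))$intramatPercent
    }
  }
  expect_gt(icc21(pcts)$value, 0.9)
})

test_that("the Bland-Altman plot renders and returns its statistics", {
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 400, height = 400)
  ba <- plotBlandAltman(c(10, 20, 30), c(12, 18, 24))
  grDevices::dev.off()
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_equal(ba$meanDiff, -2)
})
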