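test_that("OLS R-squared behaves like squared correlation", {
  expect_equal(r2OLS(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r2OLS(-c(0, 1, 2), c(0, 1, 2)), 1)  # slope absorbs sign
  set.seed(1)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(r2OLS(a, b), 0.01)
  expect_error(r2OLS(1:3, c(2, 2, 2)), "constant truth")
  expect_equal(r2OLS(rep(1, 5), 1:5), 0)
  # agreement with lm()
  set.seed(2)
  p <- rnorm(50); t <- 0.4 * p + rnorm(50)
  expect_equal(r2OLS(p, t), summary(lm(t ~ p))$r.squared)
})

idealSetup <- function() {
  g <- toyGrid(c(10L, 10L, 10L))
  rois <- roiSet(g, lo = rbind(c(1, 1, 1), c(6, 6, 6)), size = c(2, 2, 2))
  mask <- array(TRUE, c(10, 10, 10))
  ind <- array(0, c(10, 10, 10))
  ind[roiMask(rois)] <- 1
  attr <- wmhlsm:::attributionMap(ind, g, "group", "occlusion")
  list(g = g, rois = rois, mask = mask, attr = attr)
}

test_that("the ROI indicator attains every metric's ideal value", {
  s <- idealSetup()
  expect_equal(prAUC(s$attr, s$rois, s$mask)$auc, 1.0)
  ar <- attributionRatio(s$attr, s$rois)
  expect_identical(ar$ratio, Inf)
  df <- diceAndFalseNegatives(s$attr, s$rois)
  expect_equal(df$dice, 1.0)
  expect_length(df$falseNegative, 0)
})

test_that("PR-AUC is invariant to monotone transforms and has the right null", {
  s <- idealSetup()
  set.seed(3)
  vals <- array(runif(1000), c(10, 10, 10))
  a1 <- wmhlsm:::attributionMap(vals, s$g, "group", "occlusion")
  a2 <- wmhlsm:::attributionMap(vals^3 + 2 * vals, s$g, "group", "occlusion")
  expect_equal(prAUC(a1, s$rois, s$mask)$auc,
               prAUC(a2, s$rois, s$mask)$auc, tolerance = 1e-12)
  # constant attribution: single point, precision = ROI fraction of mask
  ac <- wmhlsm:::attributionMap(array(1, c(10, 10, 10)), s$g, "group",
                                "occlusion")
  prev <- sum(roiMask(s$rois)) / 1000
  expect_equal(prAUC(ac, s$rois, s$mask)$auc, prev)
  # random-attribution null: mean AUC near the in-mask ROI prevalence
  aucs <- replicate(50, {
    a <- wmhlsm:::attributionMap(array(runif(1000), c(10, 10, 10)), s$g,
                                 "group", "occlusion")
    prAUC(a, s$rois, s$mask)$auc
  })
  expect_lt(abs(mean(aucs) - prev), 3 * sd(aucs) / sqrt(50) + 0.01)
})

test_that("attribution ratios are scale-invariant and dilation-aware", {
  s <- idealSetup()
  set.seed(4)
  vals <- array(runif(1000), c(10, 10, 10))
  a <- wmhlsm:::attributionMap(vals, s$g, "group", "occlusion")
  r1 <- attributionRatio(a, s$rois)
  r2 <- attributionRatio(wmhlsm:::attributionMap(5 * vals, s$g, "group",
                                                 "occlusion"), s$rois)
  expect_equal(r1$ratio, r2$ratio)
  expect_equal(r1$dilatedRatio, r2$dilatedRatio)
  # simple mass ratio: 10 inside, 100 outside
  g2 <- volumeGrid(c(10L, 1L, 1L))
  rois2 <- roiSet(g2, lo = rbind(c(0, 0, 0)), size = c(1, 1, 1))
  av <- c(10, rep(100 / 9, 9))
  a2 <- wmhlsm:::attributionMap(av, g2, "group", "occlusion")
  expect_equal(attributionRatio(a2, rois2, thresholdFrac = 0)$ratio, 0.1)
  # mass on a rim just outside the ROI flips under 5 mm dilation
  g3 <- volumeGrid(c(12L, 12L, 12L), 2)  # 2 mm voxels
  rois3 <- roiSet(g3, lo = rbind(c(4, 4, 4)), size = c(3, 3, 3))
  rim <- array(0, c(12, 12, 12))
  rim[3:9, 3:9, 3:9] <- 1          # 2-voxel (4 mm) rim around the ROI
  rim[5:7, 5:7, 5:7] <- 0.2        # weak attribution inside the ROI
  a3 <- wmhlsm:::attributionMap(rim, g3, "group", "occlusion")
  r3 <- attributionRatio(a3, rois3, thresholdFrac = 0.1, dilationMm = 5)
  expect_lt(r3$ratio, 0.2)
  expect_gt(r3$factor, 1)
  expect_gt(r3$dilatedRatio, 10 * r3$ratio)
  expect_error(attributionRatio(
    wmhlsm:::attributionMap(array(0, c(10, 10, 10)), s$g, "group",
                            "occlusion"), s$rois), "all-zero")
})

test_that("Dice and false-negative ROIs follow the thresholded overlap", {
  s <- idealSetup()
  # attribution covering only the first ROI leaves the second as FN
  half <- array(0, c(10, 10, 10))
  half[2:3, 2:3, 2:3] <- 1
  a <- wmhlsm:::attributionMap(half, s$g, "group", "occlusion")
  df <- diceAndFalseNegatives(a, s$rois)
  expect_equal(df$falseNegative, "roi2")
  expect_equal(df$dice, 2 * 8 / (8 + 16))
  # disjoint attribution: dice 0, all ROIs FN
  off <- array(0, c(10, 10, 10)); off[9:10, 1:2, 9:10] <- 1
  df2 <- diceAndFalseNegatives(
    wmhlsm:::attributionMap(off, s$g, "group", "occlusion"), s$rois)
  expect_equal(df2$dice, 0)
  expect_setequal(df2$falseNegative, c("roi1", "roi2"))
})
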