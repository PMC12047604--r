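test_that("prevalence maps count lesioned subjects per voxel", {
  g <- toyGrid()
  a <- array(0, c(8, 8, 8)); a[1:2, 1, 1] <- 1
  co <- wmhlsm:::newCohort(cbind(as.numeric(a), as.numeric(a)), g,
                           c("a", "b"))
  pm <- buildPrevalenceMap(co)
  expect_equal(as.array(pm), 2 * a)
  # disjoint maps give counts in {0, 1}
  b <- array(0, c(8, 8, 8)); b[5, 5, 5] <- 1
  co2 <- wmhlsm:::newCohort(cbind(as.numeric(a), as.numeric(b)), g,
                            c("a", "b"))
  expect_true(all(as.array(buildPrevalenceMap(co2)) %in% 0:1))
  # single empty map
  co3 <- wmhlsm:::newCohort(matrix(0, 512, 1), g, "a")
  expect_true(all(as.array(buildPrevalenceMap(co3)) == 0))
})

test_that("ROI placement enforces the per-voxel prevalence constraint", {
  g <- toyGrid()
  cnt <- array(0L, c(8, 8, 8))
  cnt[3:5, 3:5, 3:5] <- 12L  # exactly one feasible 3^3 cube
  pm <- new("PrevalenceMap", grid = g, counts = cnt, nSubjects = 20L)
  r <- placeROIs(pm, 1, 3, minPrevalence = 10, seed = 1)
  expect_equal(unname(r@lo[1, ]), c(2L, 2L, 2L))
  # all-zero prevalence is infeasible
  pm0 <- new("PrevalenceMap", grid = g, counts = array(0L, c(8, 8, 8)),
             nSubjects = 20L)
  expect_error(placeROIs(pm0, 1, 3, 10, 1), "infeasible")
  # determinism of the random draw
  cnt2 <- array(15L, c(8, 8, 8))
  pm2 <- new("PrevalenceMap", grid = g, counts = cnt2, nSubjects = 20L)
  r1 <- placeROIs(pm2, 3, 2, 10, seed = 9)
  r2 <- placeROIs(pm2, 3, 2, 10, seed = 9)
  expect_identical(r1@lo, r2@lo)
})

test_that("lesion load is the lesioned fraction of the ROI", {
  g <- toyGrid(c(10L, 10L, 10L))
  rois <- roiSet(g, lo = rbind(c(0, 0, 0)), size = c(10, 10, 10))
  a <- array(0, c(10, 10, 10)); a[seq_len(86)] <- 1
  expect_equal(unname(lesionLoad(lesionMap(a, g), rois)), 0.086)
  expect_equal(unname(lesionLoad(lesionMap(array(0, c(10, 10, 10)), g),
                                 rois)), 0)
  expect_equal(unname(lesionLoad(lesionMap(array(1, c(10, 10, 10)), g),
                                 rois)), 1)
})

test_that("weighted scores follow the w_k * LL_k sum", {
  loads <- matrix(c(0.1, 0.2, 0.3), 1)
  expect_equal(weightedRawScore(loads, c(1, 1, 1)), 0.6)
  expect_equal(weightedRawScore(loads, c(1, 2, 1)), 0.8)
  expect_equal(weightedRawScore(matrix(c(0, 0.25, 0), 1), c(1, 4, 1)), 1.0)
  expect_error(weightedRawScore(loads, c(1, 1)), "length")
})

test_that("adding an ROI lesion voxel never lowers the raw score", {
  g <- toyGrid()
  rois <- roiSet(g, lo = rbind(c(1, 1, 1), c(5, 5, 5)), size = c(2, 2, 2),
                 weights = c(1, 4))
  set.seed(1)
  for (rep in 1:20) {
    a <- array(rbinom(512, 1, 0.3), c(8, 8, 8))
    l0 <- lesionLoad(lesionMap(a, g), rois)
    s0 <- weightedRawScore(matrix(l0, 1), rois@weights)
    roiVox <- which(roiMask(rois) & a == 0)
    if (!length(roiVox)) next
    a[sample(roiVox, 1)] <- 1
    l1 <- lesionLoad(lesionMap(a, g), rois)
    s1 <- weightedRawScore(matrix(l1, 1), rois@weights)
    expect_gt(s1, s0)
  }
})

test_that("min-max normalization maps the population onto [0, 1]", {
  s <- minmaxNormalize(c(0.2, 0.5, 0.8))
  expect_equal(scoreValues(s), c(0, 0.5, 1))
  expect_true(s@normalized)
  expect_equal(scoreValues(minmaxNormalize(c(0, 1))), c(0, 1))
  expect_error(minmaxNormalize(c(3, 3, 3)), "degenerate")
  set.seed(2)
  x <- rnorm(50)
  n <- scoreValues(minmaxNormalize(x))
  expect_identical(min(n), 0); expect_identical(max(n), 1)
})

test_that("noise injection follows the (1-nf)*basic + nf*noise mixture", {
  basic <- minmaxNormalize(seq(0, 1, length.out = 200))
  # nf = 0 leaves an already-normalized vector unchanged
  expect_equal(scoreValues(addNoise(basic, 0, seed = 1)),
               scoreValues(basic))
  # nf = 1 output carries no signal: correlation near zero at large n
  big <- minmaxNormalize(runif(50000))
  noisy1 <- addNoise(big, 1, seed = 2)
  expect_lt(abs(cor(scoreValues(big), scoreValues(noisy1))), 0.02)
  expect_error(addNoise(basic, 1.2, seed = 1), "nf")
  # reproducibility and metadata
  n1 <- addNoise(basic, 0.5, seed = 9)
  expect_identical(scoreValues(n1), scoreValues(addNoise(basic, 0.5, 9)))
  expect_equal(n1@noiseFraction, 0.5)
  expect_true(n1@normalized)
})
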