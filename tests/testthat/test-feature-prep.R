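test_that("volume correction scales lesioned voxels by 1/sqrt(V)", {
  g <- toyGrid(c(10L, 10L, 10L))
  a <- array(0, c(10, 10, 10)); a[seq_len(100)] <- 1
  cm <- volumeCorrect(lesionMap(a, g))
  expect_equal(unique(cm[cm > 0]), 0.1)
  expect_equal(sum(cm), sqrt(100))
  # empty map stays all-zero
  expect_true(all(volumeCorrect(lesionMap(array(0, c(10, 10, 10)), g)) == 0))
  # conservation property across random maps: sum == sqrt(V)
  co <- toyCohort(n = 8, seed = 4)
  cc <- volumeCorrect(co)
  expect_equal(colSums(cc), sqrt(colSums(co@voxels)))
})

test_that("mass-univariate selection finds score-associated voxels", {
  g <- toyGrid(c(6L, 6L, 6L))
  n <- 200
  set.seed(7)
  X <- matrix(rbinom(216 * n, 1, 0.3), 216, n)
  scores <- runif(n)
  # voxel 10 lesioned exactly in the 50 highest-scoring subjects
  X[10, ] <- 0
  X[10, order(scores, decreasing = TRUE)[1:50]] <- 1
  # voxel 20 lesioned in too few subjects to be tested
  X[20, ] <- 0; X[20, 1:2] <- 1
  co <- wmhlsm:::newCohort(X, g, sprintf("s%03d", 1:n))
  sel <- massUnivariateSelect(co, scores, minLesionCount = 10, alpha = 0.05)
  expect_true(sel@selected[10])
  expect_false(sel@tested[20])
  expect_false(sel@selected[20])
  # agreement with stats::t.test on a tested voxel
  v <- 30
  les <- X[v, ] == 1
  ref <- t.test(scores[les], scores[!les], alternative = "greater")
  expect_equal(sel@p[v], ref$p.value, tolerance = 1e-12)
  expect_error(massUnivariateSelect(co, rep(1, n)), "constant")
})

test_that("selection under a permuted-score null runs at the alpha rate", {
  g <- toyGrid(c(6L, 6L, 6L))
  n <- 80
  set.seed(11)
  X <- matrix(rbinom(216 * n, 1, 0.4), 216, n)
  co <- wmhlsm:::newCohort(X, g, sprintf("s%03d", 1:n))
  scores <- rnorm(n)
  rates <- replicate(40, {
    s <- sample(scores)
    sel <- massUnivariateSelect(co, s, 10, 0.05)
    sum(sel@selected) / sum(sel@tested)
  })
  nTested <- sum(massUnivariateSelect(co, scores, 10, 0.05)@tested)
  se <- sqrt(0.05 * 0.95 / (nTested * 40))
  expect_lt(abs(mean(rates) - 0.05), 3 * se + 0.005)
})

test_that("nulling keeps selected voxels and zeroes the rest", {
  g <- toyGrid(c(5L, 5L, 5L))
  a <- array(0, c(5, 5, 5)); a[c(1, 2)] <- 1
  m <- lesionMap(a, g)
  selAll <- array(TRUE, c(5, 5, 5))
  selNone <- array(FALSE, c(5, 5, 5))
  sel1 <- array(FALSE, c(5, 5, 5)); sel1[1] <- TRUE
  mk <- function(sel) new("VoxelSelectionMask", grid = g, selected = sel,
                          tested = sel | TRUE,
                          stat = array(NA_real_, c(5, 5, 5)),
                          p = array(NA_real_, c(5, 5, 5)))
  expect_identical(as.array(applyNulling(m, mk(selAll))), a)
  expect_true(all(as.array(applyNulling(m, mk(selNone))) == 0))
  kept <- as.array(applyNulling(m, mk(sel1)))
  expect_equal(kept[1], 1); expect_equal(kept[2], 0)
})

test_that("flattening is shape-stable and invertible", {
  g <- toyGrid(c(5L, 5L, 5L))
  sel <- array(FALSE, c(5, 5, 5)); sel[c(3, 10, 100)] <- TRUE
  mask <- new("VoxelSelectionMask", grid = g, selected = sel, tested = sel,
              stat = array(NA_real_, c(5, 5, 5)),
              p = array(NA_real_, c(5, 5, 5)))
  X <- matrix(0, 125, 2)
  X[3, 1] <- 0.5; X[100, 2] <- 0.25
  fm <- flattenSelected(X, mask)
  expect_equal(dim(fm@values), c(2L, 3L))
  expect_equal(fm@voxelIndex, c(3L, 10L, 100L))
  # round-trip: column values land back on their voxels
  back <- unflatten(fm@values[1, ], fm)
  expect_equal(back[3], 0.5)
  expect_equal(sum(back != 0), 1)
  # subject with empty map flattens to an all-zero row
  expect_true(all(fm@values[2, 1:2] == 0))
  emptySel <- mask; emptySel@selected <- array(FALSE, c(5, 5, 5))
  expect_error(flattenSelected(X, emptySel), "empty selection")
  # column order is deterministic
  fm2 <- flattenSelected(X, mask)
  expect_identical(fm@values, fm2@values)
})
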