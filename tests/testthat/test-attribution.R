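test_that("occlusion on a linear model equals the covering-window oracle", {
  g <- toyGrid(c(16L, 16L, 16L))
  set.seed(5)
  w <- rnorm(16^3)
  lin <- function(X) as.numeric(crossprod(X, w))
  x <- rbinom(16^3, 1, 0.3)
  attr <- occlusionAttribution(lin, lesionMap(x, g), c(5, 5, 5), c(3, 3, 3))
  # oracle: delta(W) = sum_{v in W} w_v x_v, averaged over covering windows
  d <- c(16L, 16L, 16L)
  starts <- expand.grid(seq(0, 15, 3), seq(0, 15, 3), seq(0, 15, 3))
  sumD <- numeric(16^3); cov <- numeric(16^3)
  for (i in seq_len(nrow(starts))) {
    lo <- as.integer(starts[i, ]); size <- pmin(c(5L, 5L, 5L), d - lo)
    idx <- wmhlsm:::cuboidIndices(lo, size, d)
    sumD[idx] <- sumD[idx] + sum(w[idx] * x[idx])
    cov[idx] <- cov[idx] + 1
  }
  expect_lt(max(abs(as.numeric(as.array(attr)) - sumD / cov)), 1e-6)
})

test_that("occlusion degenerate cases behave analytically", {
  g <- toyGrid(c(16L, 16L, 16L))
  x <- rbinom(16^3, 1, 0.2)
  # constant model: all-zero attribution
  constAttr <- occlusionAttribution(function(X) rep(2, ncol(X)),
                                    lesionMap(x, g))
  expect_true(all(as.array(constAttr) == 0))
  # single lesioned voxel under a linear model: attribution there is w_u
  set.seed(6)
  w <- rnorm(16^3)
  lin <- function(X) as.numeric(crossprod(X, w))
  x1 <- numeric(16^3); x1[777] <- 1
  a1 <- occlusionAttribution(lin, lesionMap(x1, g))
  expect_equal(as.numeric(as.array(a1))[777], w[777], tolerance = 1e-9)
  # away from the lesion every window's delta is exactly 0, so the
  # attribution support is confined to windows covering the lesion
  # (at most 2 start positions per axis, union well under 10^3 voxels)
  expect_lte(sum(as.numeric(as.array(a1)) != 0), 1000)
  expect_error(occlusionAttribution(lin, lesionMap(x, g), c(20, 20, 20)),
               "window larger")
  expect_error(occlusionAttribution(lin, lesionMap(x, g), c(2, 2, 2),
                                    c(3, 3, 3)), "stride")
})

test_that("positive part clips negatives and is idempotent", {
  g <- toyGrid(c(3L, 1L, 1L))
  a <- wmhlsm:::attributionMap(c(-1, 0, 2), volumeGrid(c(3L, 1L, 1L)),
                               "s", "occlusion")
  p <- positivePart(a)
  expect_equal(as.numeric(as.array(p)), c(0, 0, 2))
  expect_identical(as.array(positivePart(p)), as.array(p))
  allNeg <- wmhlsm:::attributionMap(c(-3, -1, -2), volumeGrid(c(3L, 1L, 1L)),
                                    "s", "occlusion")
  expect_true(all(as.array(positivePart(allNeg)) == 0))
})

test_that("SVR beta-maps back-project the dual coefficients", {
  g <- toyGrid(c(4L, 4L, 4L))
  # linear-kernel sanity: beta equals the primal weight vector, verified
  # through predictions f(x) = beta.x + b
  set.seed(9)
  n <- 40
  X <- matrix(runif(n * 5), n, 5)
  y <- X %*% c(1, -0.5, 0.3, 0, 0.7) + 0.01 * rnorm(n)
  fit <- e1071::svm(X, as.numeric(y), type = "eps-regression",
                    kernel = "linear", cost = 10, epsilon = 0.01,
                    scale = FALSE)
  sel <- array(FALSE, c(4, 4, 4)); sel[1:5] <- TRUE
  model <- new("SVRModel", family = "svr", config = list(), fit = fit,
               voxelIndex = which(sel), grid = g,
               tuning = data.frame())
  bm <- svrBetaMap(model)
  beta <- as.numeric(as.array(bm))[1:5]
  predManual <- X %*% beta - fit$rho
  expect_equal(as.numeric(predManual), as.numeric(predict(fit, X)),
               tolerance = 1e-8)
  # zero outside selected voxels
  expect_true(all(as.numeric(as.array(bm))[-(1:5)] == 0))
})

test_that("FNN weight maps place weights on their voxels", {
  g <- toyGrid(c(4L, 4L, 4L))
  m <- new("FNNModel", family = "fnn", config = list(),
           weights = c(0.7, -0.2), bias = 0,
           voxelIndex = c(5L, 20L), grid = g, history = numeric(0))
  wm <- fnnWeightMap(m)
  v <- as.numeric(as.array(wm))
  expect_equal(v[5], 0.7)
  expect_equal(v[20], -0.2)
  expect_true(all(v[-c(5, 20)] == 0))
})

test_that("group attribution takes the positive part before the mean", {
  g <- volumeGrid(c(2L, 1L, 1L))
  mk <- function(vals) wmhlsm:::attributionMap(vals, g, "s", "occlusion")
  gm <- groupAttribution(list(mk(c(0, -2)), mk(c(2, 2))))
  expect_equal(as.numeric(as.array(gm)), c(1, 1))
  # identical maps average to themselves
  gm2 <- groupAttribution(list(mk(c(1, 2)), mk(c(1, 2))))
  expect_equal(as.numeric(as.array(gm2)), c(1, 2))
  expect_error(groupAttribution(list()), "empty")
  expect_error(groupAttribution(list(mk(c(1, 1)),
    wmhlsm:::attributionMap(1:2, g, "s", "svr_beta"))), "mixed")
})
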