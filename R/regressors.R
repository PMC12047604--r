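#' Training configuration for the neural models
#'
#' Captures every tunable of FNN/CNN training. The reference configuration
#' is 200 epochs, batch size 2, AdamW, learning
#' rate 5e-5 for simulation runs (1e-4 with reduce-on-plateau on real
#' data), MSE loss for simulations and `2*MSE + L1` on real data. Reduced
#' desk-scale presets change epochs/batch/learning rate for CPU runs; the
#' config snapshot is stored on every trained model.
#'
#' @param epochs number of passes over the training set.
#' @param batchSize minibatch size.
#' @param lr learning rate.
#' @param loss `"mse"` or `"mse2_plus_l1"` (2*MSE + mean |error|).
#' @param weightDecay decoupled (AdamW) weight decay.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param channels conv channel counts (CNN), length 2.
#' @param hidden hidden width of the second linear layer (regularized CNN).
#' @param dropout dropout probability (regularized CNN conv blocks).
#' @param lrSchedule `"none"` or `"reduce_on_plateau"` (halve the rate
#'   when the epoch loss has not improved for `patience` epochs).
#' @param patience plateau patience in epochs.
#' @return A named list with class `"trainingConfig"`.
#' @export
trainingConfig <- function(epochs = 200, batchSize = 2, lr = 5e-5,
                           loss = c("mse", "mse2_plus_l1"),
                           weightDecay = 0.01, seed = 1L,
                           channels = c(8L, 16L), hidden = 16L,
                           dropout = 0.2,
                           lrSchedule = c("none", "reduce_on_plateau"),
                           patience = 10L) {
  loss <- match.arg(loss)
  lrSchedule <- match.arg(lrSchedule)
  stopifnot(epochs >= 1, lr > 0, batchSize >= 1)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), lr = lr, loss = loss,
                 optimizer = "adamw", weightDecay = weightDecay,
                 seed = as.integer(seed),
                 channels = as.integer(channels), hidden = as.integer(hidden),
                 dropout = dropout, lrSchedule = lrSchedule,
                 patience = as.integer(patience)),
            class = "trainingConfig")
}

#' Random k-fold assignment
#'
#' Partitions `n` subjects into `k` folds whose sizes differ by at most
#' one, by a seeded random permutation. Each subject appears in exactly
#' one test fold.
#'
#' @param n number of subjects.
#' @param k fold count (default 5: each fold holds out 20%).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`, one per subject.
#' @export
makeFolds <- function(n, k = 5, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("n (", n, ") must be >= k (", k, ")")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

# ---- AdamW on a list of parameter arrays -------------------------------

adamwInit <- function(params) {
  # moment buffers mirror each parameter's native structure
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamwStep <- function(params, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    g <- if (is.matrix(params[[nm]]))
      matrix(as.numeric(g), nrow(params[[nm]]), ncol(params[[nm]]))
    else as.numeric(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weightDecay * params[[nm]])
  }
  list(params = params, state = state)
}

lossGrad <- function(pred, y, loss) {
  e <- pred - y
  n <- length(y)
  if (loss == "mse2_plus_l1")
    list(loss = 2 * mean(e^2) + mean(abs(e)),
         dpred = (4 * e + sign(e)) / n)
  else
    list(loss = mean(e^2), dpred = 2 * e / n)
}

#' Combined regression loss
#'
#' `2 * mean squared error + mean absolute error` of predictions, the
#' regularizing loss variant used for real cognitive data; with
#' `loss = "mse"` this reduces to plain MSE.
#'
#' @param pred,truth numeric vectors.
#' @param loss `"mse"` or `"mse2_plus_l1"`.
#' @return scalar loss.
#' @export
regressionLoss <- function(pred, truth, loss = "mse2_plus_l1") {
  lossGrad(pred, truth, loss)$loss
}

# ---- fully connected network -------------------------------------------

#' Train the fully connected benchmark network
#'
#' One linear layer followed by ReLU, mimicking linear regression with a
#' non-linear output mapping: `pred = max(0, X w + b)`. Trained with
#' AdamW on the configured loss; deterministic given `cfg$seed`.
#'
#' @param features a [FeatureMatrix-class] (or numeric matrix).
#' @param scores a [ScoreVector-class] or numeric vector.
#' @param cfg a [trainingConfig()].
#' @return A [FNNModel-class].
#' @export
trainFNN <- function(features, scores,
                     cfg = trainingConfig(epochs = 200, batchSize = 2,
                                          lr = 5e-5)) {
  X <- if (is(features, "FeatureMatrix")) features@values else
    as.matrix(features)
  y <- if (is(scores, "ScoreVector")) scores@values else as.numeric(scores)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least two training subjects")
  params <- with_seed(cfg$seed, list(
    w = stats::rnorm(p, 0, 1 / sqrt(max(p, 1))),
    b = mean(y)))
  state <- adamwInit(params)
  history <- numeric(cfg$epochs)
  lr <- cfg$lr
  best <- Inf; stall <- 0L
  orders <- with_seed(cfg$seed + 1L,
                      lapply(seq_len(cfg$epochs), function(e) sample(n)))
  for (ep in seq_len(cfg$epochs)) {
    ord <- orders[[ep]]
    epLoss <- 0
    starts <- seq(1, n, by = cfg$batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      z <- as.numeric(Xb %*% params$w) + params$b
      pred <- pmax(z, 0)
      lg <- lossGrad(pred, yb, cfg$loss)
      if (!is.finite(lg$loss))
        stop("FNN training diverged (non-finite loss at epoch ", ep, ")")
      dz <- lg$dpred * (z > 0)
      grads <- list(w = as.numeric(crossprod(Xb, dz)), b = sum(dz))
      upd <- adamwStep(params, grads, state, lr, cfg$weightDecay)
      params <- upd$params; state <- upd$state
      epLoss <- epLoss + lg$loss * length(idx)
    }
    history[ep] <- epLoss / n
    if (cfg$lrSchedule == "reduce_on_plateau") {
      if (history[ep] < best - 1e-12) { best <- history[ep]; stall <- 0L }
      else if ((stall <- stall + 1L) >= cfg$patience) {
        lr <- lr / 2; stall <- 0L
      }
    }
  }
  new("FNNModel", family = "fnn", config = unclass(cfg),
      weights = as.numeric(params$w), bias = as.numeric(params$b),
      voxelIndex = if (is(features, "FeatureMatrix")) features@voxelIndex
                   else integer(0),
      grid = if (is(features, "FeatureMatrix")) features@grid
             else volumeGrid(c(1L, 1L, 1L)),
      history = history)
}

# ---- 3D convolutional network ------------------------------------------

pooledDim <- function(d) as.integer((d + 1L) %/% 2L)

initCNNParams <- function(grid, arch, cfg, ymean) {
  d <- grid@dim
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  nvox <- prod(d)
  flatDim <- if (arch == "regularized")
    prod(pooledDim(pooledDim(d))) * c2 else nvox * c2
  he <- function(nin, nrow, ncol)
    matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / nin)), nrow, ncol)
  with_seed(cfg$seed, {
    p <- list(
      W1 = he(27, 27, c1), b1 = rep(0, c1),
      W2 = he(27 * c1, 27 * c1, c2), b2 = rep(0, c2))
    if (arch == "regularized") {
      h <- cfg$hidden
      p$Wl1 <- he(flatDim, flatDim, h)
      p$bl1 <- rep(0, h)
      p$Wl2 <- he(h, h, 1L)
      p$bl2 <- ymean
    } else {
      p$Wl1 <- he(flatDim, flatDim, 1L)
      p$bl1 <- ymean
    }
    p
  })
}

#' Train the 3D convolutional lesion-symptom model
#'
#' Two architectures: `"simple"` is two 3x3x3 convolution blocks
#' (conv + ReLU) followed by flattening and one linear output unit, the
#' configuration used with simulated scores; `"regularized"` adds spatial
#' dropout inside each block, 2x2x2 max pooling after each block and a
#' second linear layer, the configuration for noisier real data, usually
#' with the `mse2_plus_l1` loss. Optimized with AdamW; deterministic
#' given `cfg$seed`.
#'
#' @param x a [LesionCohort-class] (or voxels-by-subjects matrix plus
#'   `grid`).
#' @param scores aligned [ScoreVector-class] or numeric vector.
#' @param arch `"simple"` or `"regularized"`.
#' @param cfg a [trainingConfig()].
#' @param grid required when `x` is a plain matrix.
#' @return A [CNNModel-class].
#' @export
trainCNN <- function(x, scores, arch = c("simple", "regularized"),
                     cfg = trainingConfig(), grid = NULL) {
  arch <- match.arg(arch)
  if (is(x, "LesionCohort")) { grid <- x@grid; X <- x@voxels }
  else { X <- as.matrix(x); if (is.null(grid)) stop("grid required") }
  y <- if (is(scores, "ScoreVector")) scores@values else as.numeric(scores)
  n <- ncol(X)
  if (length(y) != n) stop("scores not aligned with maps")
  params <- initCNNParams(grid, arch, cfg, mean(y))
  state <- adamwInit(params)
  lossType <- if (cfg$loss == "mse2_plus_l1") 1L else 0L
  reg <- arch == "regularized"
  d <- grid@dim
  nvox1 <- prod(d)
  nvox2 <- if (reg) prod(pooledDim(d)) else nvox1
  history <- numeric(cfg$epochs)
  lr <- cfg$lr
  best <- Inf; stall <- 0L
  orders <- with_seed(cfg$seed + 1L,
                      lapply(seq_len(cfg$epochs), function(e) sample(n)))
  useDrop <- reg && cfg$dropout > 0
  dropSeed <- cfg$seed + 2L
  for (ep in seq_len(cfg$epochs)) {
    ord <- orders[[ep]]
    epLoss <- 0
    starts <- seq(1, n, by = cfg$batchSize)
    for (si in seq_along(starts)) {
      idx <- ord[starts[si]:min(starts[si] + cfg$batchSize - 1, n)]
      B <- length(idx)
      dm1 <- dm2 <- NULL
      if (useDrop) {
        masks <- with_seed(dropSeed + ep * 10000L + si, list(
          m1 = matrix(stats::rbinom(nvox1 * B, 1, 1 - cfg$dropout) /
                        (1 - cfg$dropout), nvox1, B),
          m2 = matrix(stats::rbinom(nvox2 * B, 1, 1 - cfg$dropout) /
                        (1 - cfg$dropout), nvox2, B)))
        dm1 <- masks$m1; dm2 <- masks$m2
      }
      res <- .cnn_train_batch(X[, idx, drop = FALSE], y[idx], d, params,
                              reg, lossType, dm1, dm2)
      if (!is.finite(res$loss))
        stop("CNN training diverged (non-finite loss at epoch ", ep, ")")
      upd <- adamwStep(params, res$grads, state, lr, cfg$weightDecay)
      params <- upd$params; state <- upd$state
      epLoss <- epLoss + res$loss * B
    }
    history[ep] <- epLoss / n
    if (cfg$lrSchedule == "reduce_on_plateau") {
      if (history[ep] < best - 1e-12) { best <- history[ep]; stall <- 0L }
      else if ((stall <- stall + 1L) >= cfg$patience) {
        lr <- lr / 2; stall <- 0L
      }
    }
  }
  new("CNNModel", family = paste0("cnn_", arch), config = unclass(cfg),
      params = params, arch = arch, grid = grid, history = history)
}

# ---- support vector regression -----------------------------------------

#' Default SVR hyperparameter grid
#'
#' C in {0.1, 1, 10, 100}; gamma in {scale heuristic, 1e-3, 1e-2, 1e-1}
#' where the scale heuristic is `1 / (p * var(X))`; epsilon in
#' {0.01, 0.1}. Enumeration order is fixed (epsilon slowest) and breaks
#' ties.
#'
#' @param X training feature matrix (for the gamma scale heuristic).
#' @return data.frame with columns `cost`, `gamma`, `epsilon`.
#' @export
svrDefaultGrid <- function(X) {
  vX <- stats::var(as.numeric(X))
  gScale <- if (vX > 0) 1 / (ncol(X) * vX) else 1
  expand.grid(cost = c(0.1, 1, 10, 100),
              gamma = c(gScale, 1e-3, 1e-2, 1e-1),
              epsilon = c(0.01, 0.1))
}

#' Train radial-basis support vector regression
#'
#' The conventional multivariate lesion-symptom model: an RBF-kernel
#' epsilon-SVR on flattened (volume-corrected, feature-selected) voxel
#' features. Hyperparameters are optimized by an inner k-fold grid search
#' choosing the combination with the highest mean Pearson correlation
#' between predicted and true scores on the inner test folds; the winning
#' combination is refit on all training rows.
#'
#' @param features a [FeatureMatrix-class] or numeric matrix.
#' @param scores aligned scores.
#' @param paramGrid data.frame of `cost`/`gamma`/`epsilon` combinations;
#'   default [svrDefaultGrid()].
#' @param innerFolds inner CV fold count (default 5).
#' @param seed seed for the inner fold assignment.
#' @return An [SVRModel-class] with the grid-search table in `@tuning`.
#' @export
trainSVR <- function(features, scores, paramGrid = NULL, innerFolds = 5,
                     seed = 1L) {
  X <- if (is(features, "FeatureMatrix")) features@values else
    as.matrix(features)
  y <- if (is(scores, "ScoreVector")) scores@values else as.numeric(scores)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 training subjects")
  if (stats::sd(y) == 0) stop("degenerate scores: zero variance")
  if (is.null(paramGrid)) paramGrid <- svrDefaultGrid(X)
  if (!nrow(paramGrid)) stop("empty parameter grid")
  fold <- makeFolds(n, innerFolds, seed)
  score <- numeric(nrow(paramGrid))
  for (g in seq_len(nrow(paramGrid))) {
    r <- numeric(innerFolds)
    for (f in seq_len(innerFolds)) {
      tr <- fold != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = paramGrid$cost[g],
                      gamma = paramGrid$gamma[g],
                      epsilon = paramGrid$epsilon[g], scale = FALSE)
      p <- as.numeric(stats::predict(m, X[!tr, , drop = FALSE]))
      r[f] <- if (stats::sd(p) == 0) 0 else stats::cor(p, y[!tr])
    }
    score[g] <- mean(r)
  }
  bestIdx <- which.max(score)  # first maximum wins ties
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = paramGrid$cost[bestIdx],
                    gamma = paramGrid$gamma[bestIdx],
                    epsilon = paramGrid$epsilon[bestIdx], scale = FALSE)
  tuning <- cbind(paramGrid, meanPearson = score)
  new("SVRModel", family = "svr",
      config = list(grid = paramGrid, innerFolds = innerFolds, seed = seed,
                    best = as.list(paramGrid[bestIdx, ])),
      fit = fit,
      voxelIndex = if (is(features, "FeatureMatrix")) features@voxelIndex
                   else integer(0),
      grid = if (is(features, "FeatureMatrix")) features@grid
             else volumeGrid(c(1L, 1L, 1L)),
      tuning = tuning)
}

# ---- prediction --------------------------------------------------------

featureValues <- function(inputs) {
  if (is(inputs, "FeatureMatrix")) inputs@values else as.matrix(inputs)
}

setMethod("predictScores", "SVRModel", function(model, inputs) {
  X <- featureValues(inputs)
  if (length(model@voxelIndex) && is(inputs, "FeatureMatrix") &&
      !identical(inputs@voxelIndex, model@voxelIndex))
    stop("feature/voxel index mismatch with the fitted model")
  as.numeric(stats::predict(model@fit, X))
})

setMethod("predictScores", "FNNModel", function(model, inputs) {
  X <- featureValues(inputs)
  if (ncol(X) != length(model@weights))
    stop("input contract mismatch: expected ", length(model@weights),
         " features")
  pmax(as.numeric(X %*% model@weights) + model@bias, 0)
})

setMethod("predictScores", "CNNModel", function(model, inputs) {
  X <- if (is(inputs, "LesionCohort")) {
    if (!sameGrid(inputs, model@grid)) stop("grid mismatch")
    inputs@voxels
  } else if (is(inputs, "LesionMap")) {
    if (!sameGrid(inputs, model@grid)) stop("grid mismatch")
    matrix(as.numeric(inputs@data), ncol = 1)
  } else as.matrix(inputs)
  if (nrow(X) != prod(model@grid@dim))
    stop("input contract mismatch: expected ", prod(model@grid@dim),
         " voxels")
  as.numeric(.cnn_forward(X, model@grid@dim, model@params,
                          model@arch == "regularized"))
})

#' @rdname predictScores
#' @param object a fitted [LSMModel-class].
#' @param newdata inputs matching the model contract.
#' @param ... ignored.
#' @export
setMethod("predict", "LSMModel", function(object, newdata, ...)
  predictScores(object, newdata))
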