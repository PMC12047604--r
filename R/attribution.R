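#' Occlusion attribution for an image-input model
#'
#' Slides a window over the stride lattice; each placement is zeroed
#' ("the lesion is removed there") and the prediction recomputed. The
#' placement's effect is `delta(W) = f(map) - f(map with W zeroed)`, and
#' each voxel's attribution is the mean of `delta(W)` over all placements
#' covering it, so overlapping windows are averaged. Positive attribution
#' marks locations whose occlusion lowers the predicted (worse) score.
#' Placements are clipped at the grid boundary, so every voxel is covered.
#'
#' @param model a [CNNModel-class] (or any function mapping a
#'   voxels-by-inputs matrix to a numeric prediction per column, which is
#'   how analytic reference models are plugged in).
#' @param map a [LesionMap-class].
#' @param window window size in voxels (default 5x5x5).
#' @param stride stride in voxels (default 3x3x3); must not exceed the
#'   window.
#' @param batchSize occluded variants evaluated per forward call.
#' @return An [AttributionMap-class] for the subject.
#' @export
occlusionAttribution <- function(model, map, window = c(5, 5, 5),
                                 stride = c(3, 3, 3), batchSize = 256L) {
  window <- rep(as.integer(window), length.out = 3)
  stride <- rep(as.integer(stride), length.out = 3)
  d <- gridDim(map)
  if (any(window > d)) stop("window larger than grid")
  if (any(stride > window)) stop("stride must not exceed window")
  predictFun <- if (is.function(model)) model else
    function(X) predictScores(model, X)
  x <- as.numeric(as.array(map))
  base <- predictFun(matrix(x, ncol = 1))[1]

  starts <- lapply(1:3, function(a) seq(0L, d[a] - 1L, by = stride[a]))
  pl <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  nP <- nrow(pl)
  winIdx <- lapply(seq_len(nP), function(i) {
    lo <- pl[i, ]
    size <- pmin(window, d - lo)
    cuboidIndices(lo, size, d)
  })

  sumDelta <- numeric(length(x))
  cover <- numeric(length(x))
  for (w in winIdx) cover[w] <- cover[w] + 1
  # occluding an all-zero window cannot change the prediction (zeroing
  # zeros is a no-op), so only windows containing lesion are evaluated
  active <- which(vapply(winIdx, function(w) any(x[w] != 0), logical(1)))
  if (length(active)) for (s in seq(1, length(active), by = batchSize)) {
    ii <- active[s:min(s + batchSize - 1, length(active))]
    Xocc <- matrix(x, length(x), length(ii))
    for (j in seq_along(ii)) Xocc[winIdx[[ii[j]]], j] <- 0
    preds <- predictFun(Xocc)
    delta <- base - preds
    for (j in seq_along(ii)) {
      w <- winIdx[[ii[j]]]
      sumDelta[w] <- sumDelta[w] + delta[j]
    }
  }
  attributionMap(sumDelta / cover, getGrid(map),
                 map@subjectId, "occlusion")
}

#' Positive part of an attribution map
#'
#' Negative values are set to zero; only positive attributions (locations
#' driving a higher predicted score) enter the analyses.
#'
#' @param attr an [AttributionMap-class].
#' @return An [AttributionMap-class].
#' @export
positivePart <- function(attr) {
  attributionMap(pmax(attr@data, 0), attr@grid, attr@subjectId, attr@method)
}

#' SVR beta-map attribution
#'
#' Back-projects the fitted SVR onto voxel space through the dual
#' coefficients: `beta_v = sum_j alpha_j x_{j,v}` over the support
#' vectors, placed at the selected voxel coordinates and zero elsewhere.
#' For a linear kernel this is exactly the primal weight vector; for the
#' RBF kernel it is the customary beta-map approximation.
#'
#' @param model a fitted [SVRModel-class].
#' @param features optional [FeatureMatrix-class]; its voxel index must
#'   match the model's (defaults to the model's own index).
#' @return A group-level [AttributionMap-class].
#' @export
svrBetaMap <- function(model, features = NULL) {
  idx <- model@voxelIndex
  grid <- model@grid
  if (!is.null(features)) {
    if (!identical(features@voxelIndex, idx))
      stop("feature/voxel index mismatch with the fitted model")
    grid <- features@grid
  }
  beta <- as.numeric(crossprod(model@fit$SV, model@fit$coefs))
  a <- array(0, grid@dim)
  a[idx] <- beta
  attributionMap(a, grid, "group", "svr_beta")
}

#' FNN weight-map attribution
#'
#' The linear layer's per-feature weight placed at its voxel coordinate,
#' zero elsewhere. A pure model property, independent of any input image.
#'
#' @param model a fitted [FNNModel-class].
#' @return A group-level [AttributionMap-class].
#' @export
fnnWeightMap <- function(model) {
  a <- array(0, model@grid@dim)
  a[model@voxelIndex] <- model@weights
  attributionMap(a, model@grid, "group", "fnn_weights")
}

#' Group-level attribution map
#'
#' Applies [positivePart()] to every individual map, then takes the
#' voxelwise mean: for occlusion this pools every patient's test-fold map
#' (each patient appears once across folds); for SVR/FNN it averages the
#' per-fold beta/weight maps.
#'
#' @param maps list of [AttributionMap-class] objects from one method on
#'   one grid.
#' @return A group [AttributionMap-class].
#' @export
groupAttribution <- function(maps) {
  if (!length(maps)) stop("empty attribution collection")
  g <- getGrid(maps[[1]])
  method <- maps[[1]]@method
  acc <- array(0, g@dim)
  for (m in maps) {
    if (!sameGrid(m, g)) stop("grid mismatch across attribution maps")
    if (m@method != method) stop("mixed attribution methods")
    acc <- acc + pmax(m@data, 0)
  }
  attributionMap(acc / length(maps), g, "group", method)
}
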