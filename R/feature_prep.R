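#' Lesion-volume correction
#'
#' Divides lesioned voxels by the square root of the total lesion volume
#' (lesioned-voxel count), so subjects with large lesion burden do not
#' dominate the multivariate fit: every lesioned voxel carries `1/sqrt(V)`
#' and the corrected map sums to `sqrt(V)`. An empty map stays all-zero.
#'
#' @param x a [LesionMap-class] or [LesionCohort-class].
#' @return For a map, a 3D numeric array; for a cohort, a
#'   voxels-by-subjects matrix of corrected values.
#' @export
volumeCorrect <- function(x) {
  if (is(x, "LesionMap")) {
    v <- sum(x@data)
    if (v == 0) return(array(0, dim(x@data)))
    return(x@data / sqrt(v))
  }
  v <- colSums(x@voxels)
  scale <- ifelse(v > 0, 1 / sqrt(v), 0)
  sweep(x@voxels, 2, scale, `*`)
}

#' Mass-univariate voxel selection
#'
#' The standard mass-univariate lesion-symptom screen used here for
#' feature selection: every voxel lesioned in at least `minLesionCount`
#' and at most `n - minLesionCount` subjects is tested with a two-sample
#' Welch t-test of the scores between lesioned and non-lesioned subjects,
#' one-sided in the direction "lesion associated with higher (worse)
#' score". Voxels with `p < alpha` (uncorrected) are selected.
#'
#' @param cohort a [LesionCohort-class].
#' @param scores a [ScoreVector-class] or numeric vector aligned with the
#'   cohort.
#' @param minLesionCount minimum lesioned (and spared) subject count for a
#'   voxel to be tested (default 10).
#' @param alpha one-sided significance level (default 0.05).
#' @return A [VoxelSelectionMask-class].
#' @export
massUnivariateSelect <- function(cohort, scores, minLesionCount = 10,
                                 alpha = 0.05) {
  s <- if (is(scores, "ScoreVector")) scores@values else as.numeric(scores)
  n <- nSubjects(cohort)
  if (length(s) != n) stop("scores not aligned with cohort")
  if (stats::sd(s) == 0) stop("all-constant scores")
  if (minLesionCount < 1) stop("minLesionCount must be >= 1")
  X <- cohort@voxels
  n1 <- rowSums(X)
  tested <- n1 >= minLesionCount & n1 <= n - minLesionCount
  tstat <- rep(NA_real_, nrow(X)); pval <- rep(NA_real_, nrow(X))
  if (any(tested)) {
    Xt <- X[tested, , drop = FALSE]
    m1 <- as.numeric(Xt %*% s) / n1[tested]
    ss1 <- as.numeric(Xt %*% (s * s))
    v1 <- (ss1 - n1[tested] * m1^2) / (n1[tested] - 1)
    n0 <- n - n1[tested]
    sum0 <- sum(s) - as.numeric(Xt %*% s)
    m0 <- sum0 / n0
    ss0 <- sum(s * s) - ss1
    v0 <- (ss0 - n0 * m0^2) / (n0 - 1)
    v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)
    se2 <- v1 / n1[tested] + v0 / n0
    tv <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1[tested]^2 * (n1[tested] - 1)) +
                     v0^2 / (n0^2 * (n0 - 1)))
    pv <- stats::pt(tv, df, lower.tail = FALSE)
    # degenerate variance handling: identical scores in both groups
    pv[!is.finite(tv)] <- 1
    tv[!is.finite(tv)] <- 0
    tstat[tested] <- tv
    pval[tested] <- pv
  }
  sel <- tested & !is.na(pval) & pval < alpha
  d <- cohort@grid@dim
  new("VoxelSelectionMask", grid = cohort@grid,
      selected = array(sel, d), tested = array(tested, d),
      stat = array(tstat, d), p = array(pval, d))
}

#' Select every lesioned voxel (no statistical screen)
#'
#' Marks all voxels lesioned in at least `minLesionCount` subjects as
#' selected. Used when flattening should keep the full lesion support,
#' e.g. for simulation-path SVR/FNN without a univariate screen.
#'
#' @inheritParams massUnivariateSelect
#' @return A [VoxelSelectionMask-class] with NA statistics.
#' @export
lesionSupportMask <- function(cohort, minLesionCount = 1) {
  n1 <- rowSums(cohort@voxels)
  sel <- n1 >= minLesionCount
  d <- cohort@grid@dim
  new("VoxelSelectionMask", grid = cohort@grid,
      selected = array(sel, d), tested = array(sel, d),
      stat = array(NA_real_, d), p = array(NA_real_, d))
}

#' Null unselected voxels in a lesion map
#'
#' Voxels outside the selected set are forced to 0; selected voxels are
#' untouched. Used to reduce the input dimensionality of the image-input
#' model on real data.
#'
#' @param x a [LesionMap-class] or [LesionCohort-class].
#' @param mask a [VoxelSelectionMask-class] on the same grid.
#' @return An object of the same class as `x`.
#' @export
applyNulling <- function(x, mask) {
  if (!sameGrid(x, mask)) stop("grid mismatch between map and mask")
  keep <- as.numeric(mask@selected)
  if (is(x, "LesionMap"))
    return(lesionMap(x@data * array(keep, dim(x@data)), x@grid, x@subjectId))
  newCohort(x@voxels * keep, x@grid, subjectIds(x), x@scores)
}

#' Flatten volume-corrected maps into a feature matrix
#'
#' One column per selected voxel, in ascending linear-index
#' (lexicographic) order; one row per subject in cohort order. Values are
#' taken from the supplied voxels-by-subjects matrix (typically the
#' output of [volumeCorrect()]).
#'
#' @param corrected voxels-by-subjects numeric matrix, or a
#'   [LesionCohort-class] (flattened as-is, without correction).
#' @param mask a [VoxelSelectionMask-class]; its selected voxels define
#'   the feature columns.
#' @return A [FeatureMatrix-class].
#' @export
flattenSelected <- function(corrected, mask) {
  if (is(corrected, "LesionCohort")) {
    if (!sameGrid(corrected, mask)) stop("grid mismatch")
    corrected <- corrected@voxels
  }
  idx <- which(as.logical(mask@selected))
  if (!length(idx)) stop("empty selection: no voxels to flatten")
  vals <- t(corrected[idx, , drop = FALSE])
  dimnames(vals) <- NULL
  new("FeatureMatrix", values = vals, voxelIndex = as.integer(idx),
      grid = mask@grid)
}

#' Place feature-matrix columns (or weights) back on the grid
#'
#' @param values numeric vector, one value per feature column.
#' @param features a [FeatureMatrix-class] (or an object with
#'   `voxelIndex` and a grid).
#' @return 3D numeric array, zero outside the feature voxels.
#' @export
unflatten <- function(values, features) {
  a <- array(0, features@grid@dim)
  a[features@voxelIndex] <- values
  a
}
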