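#' Voxelwise lesion prevalence of a cohort
#'
#' Sums all binary maps of the cohort: `counts[v]` is the number of
#' subjects with a lesion at voxel v.
#'
#' @param cohort a non-empty [LesionCohort-class].
#' @return A [PrevalenceMap-class].
#' @export
buildPrevalenceMap <- function(cohort) {
  if (nSubjects(cohort) < 1) stop("empty cohort")
  counts <- array(as.integer(rowSums(cohort@voxels)), cohort@grid@dim)
  new("PrevalenceMap", grid = cohort@grid, counts = counts,
      nSubjects = nSubjects(cohort))
}

# 3D sliding-window minimum over cuboids of `size`, returned at each
# feasible lower corner (dims - size + 1 per axis); separable per axis
slidingMin3d <- function(a, size) {
  for (axis in 1:3) {
    k <- size[axis]
    n <- dim(a)[axis] - k + 1
    take <- function(from) switch(axis,
      a[from:(from + n - 1), , , drop = FALSE],
      a[, from:(from + n - 1), , drop = FALSE],
      a[, , from:(from + n - 1), drop = FALSE])
    out <- take(1)
    if (k > 1) for (s in 1:(k - 1)) out <- pmin(out, take(1 + s))
    a <- out
  }
  a
}

#' Place ground-truth ROIs under a prevalence constraint
#'
#' Enumerates every axis-aligned cuboid placement (stride-1 voxel lattice)
#' whose voxels all have lesion prevalence at or above `minPrevalence`,
#' then draws `nRois` mutually disjoint placements uniformly at random
#' without replacement (sequential draws with rejection of overlapping
#' candidates, capped at `maxAttempts`). Weights are initialized to 1.
#'
#' @param prev a [PrevalenceMap-class].
#' @param nRois number of ROIs to place.
#' @param roiSizeVox ROI edge length(s) in voxels (scalar or length 3).
#'   Alternatively give `roiSizeMm` to specify millimetres, rounded to
#'   voxels on the prevalence map's grid.
#' @param minPrevalence minimum per-voxel subject count inside an ROI
#'   (default 10).
#' @param seed integer seed controlling the random draw.
#' @param roiSizeMm ROI edge length in mm (used when `roiSizeVox` is NULL).
#' @param maxAttempts rejection-sampling cap for disjointness.
#' @return A [ROISet-class] with unit weights.
#' @export
placeROIs <- function(prev, nRois = 3, roiSizeVox = NULL,
                      minPrevalence = 10, seed = 1L, roiSizeMm = NULL,
                      maxAttempts = 10000) {
  if (nRois < 1) stop("nRois must be >= 1")
  if (is.null(roiSizeVox)) {
    if (is.null(roiSizeMm)) stop("give roiSizeVox or roiSizeMm")
    roiSizeVox <- pmax(1L, as.integer(round(roiSizeMm / prev@grid@spacing)))
  }
  size <- as.integer(rep(roiSizeVox, length.out = 3))
  d <- prev@grid@dim
  if (any(size > d)) stop("ROI size exceeds grid")
  wmin <- slidingMin3d(prev@counts, size)
  feas <- which(wmin >= minPrevalence, arr.ind = TRUE)  # 1-based lo corners
  if (nrow(feas) < nRois)
    stop("infeasible ROI placement: only ", nrow(feas),
         " candidate placement(s) satisfy prevalence >= ", minPrevalence)
  lo <- with_seed(seed, {
    chosen <- matrix(NA_integer_, 0, 3)
    attempts <- 0L
    avail <- seq_len(nrow(feas))
    while (nrow(chosen) < nRois) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("infeasible ROI placement: could not find ", nRois,
             " disjoint ROIs in ", maxAttempts, " attempts")
      cand <- feas[sample(avail, 1L), ] - 1L  # 0-based lo
      ok <- TRUE
      if (nrow(chosen)) for (j in seq_len(nrow(chosen))) {
        if (all(pmax(cand, chosen[j, ]) < pmin(cand + size,
                                               chosen[j, ] + size))) {
          ok <- FALSE; break
        }
      }
      if (ok) chosen <- rbind(chosen, cand)
    }
    chosen
  })
  roiSet(prev@grid, lo, size)
}

#' Lesion load of an ROI
#'
#' The number of lesioned voxels inside the cuboid divided by the total
#' number of voxels of that cuboid: a fraction in `[0, 1]` per subject
#' and ROI.
#'
#' @param x a [LesionMap-class] or [LesionCohort-class].
#' @param rois a [ROISet-class] on the same grid.
#' @return For a map, a named numeric vector (one load per ROI); for a
#'   cohort, a subjects-by-ROIs matrix.
#' @export
lesionLoad <- function(x, rois) {
  if (!sameGrid(x, rois)) stop("grid mismatch between maps and ROIs")
  idx <- roiIndexList(rois)
  nvox <- vapply(idx, length, integer(1))
  if (is(x, "LesionMap")) {
    v <- as.numeric(x@data)
    return(vapply(seq_along(idx),
                  function(k) sum(v[idx[[k]]]) / nvox[k], numeric(1)) |>
             stats::setNames(rois@ids))
  }
  loads <- vapply(seq_along(idx), function(k)
    colSums(x@voxels[idx[[k]], , drop = FALSE]) / nvox[k],
    numeric(nSubjects(x)))
  loads <- matrix(loads, nrow = nSubjects(x),
                  dimnames = list(subjectIds(x), rois@ids))
  loads
}

#' Weighted raw cognitive score from ROI lesion loads
#'
#' `score_i = sum_k w_k * LL_{i,k}`: each subject's lesion loads are
#' weighted by the per-ROI contribution weights and summed. With unit
#' weights this is the basic simulation; weights such as `{1,2,1}` or
#' `{1,4,1}` make the middle ROI strategically dominant.
#'
#' @param loads subjects-by-ROIs lesion-load matrix (entries in `[0,1]`).
#' @param weights per-ROI positive weights, length = ROI count.
#' @return Numeric raw scores, one per subject.
#' @export
weightedRawScore <- function(loads, weights) {
  loads <- as.matrix(loads)
  if (length(weights) != ncol(loads))
    stop("weights length (", length(weights),
         ") does not match ROI count (", ncol(loads), ")")
  as.numeric(loads %*% as.numeric(weights))
}

#' Population min-max normalization of scores
#'
#' `(x - min) / (max - min)` using the values within the study
#' population, so the maximum maps to exactly 1 and the minimum to
#' exactly 0.
#'
#' @param raw numeric raw scores (at least two distinct values).
#' @param kind score kind recorded on the result.
#' @param noiseFraction recorded nf (0 unless noisy).
#' @return A normalized [ScoreVector-class].
#' @export
minmaxNormalize <- function(raw, kind = "basic", noiseFraction = 0) {
  if (is(raw, "ScoreVector")) {
    if (missing(kind)) kind <- raw@kind
    raw <- raw@values
  }
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("degenerate normalization: all scores are identical")
  scoreVector((raw - rng[1]) / (rng[2] - rng[1]), kind = kind,
              noiseFraction = noiseFraction, normalized = TRUE)
}

#' Perturb simulated scores with Gaussian noise
#'
#' Draws `noise_i ~ Normal(0, sd(basic))` with the standard deviation of
#' the original simulated scores, mixes
#' `noise_score_i = (1 - nf) * basic_i + nf * noise_i`, and re-applies the
#' population min-max normalization. The squared correlation between
#' basic and noisy scores approaches
#' `(1-nf)^2 / ((1-nf)^2 + nf^2)` for large cohorts.
#'
#' @param basic a normalized basic [ScoreVector-class] (or numeric).
#' @param nf noise fraction in `[0, 1]`.
#' @param seed integer seed for the noise draw.
#' @param sdType `"population"` (n denominator, default) or `"sample"`
#'   (n-1) standard deviation of the basic scores.
#' @return A normalized noisy [ScoreVector-class].
#' @export
addNoise <- function(basic, nf, seed, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (nf < 0 || nf > 1) stop("nf must lie in [0,1]")
  v <- if (is(basic, "ScoreVector")) basic@values else as.numeric(basic)
  n <- length(v)
  s <- stats::sd(v)
  if (sdType == "population") s <- s * sqrt((n - 1) / n)
  noise <- with_seed(seed, stats::rnorm(n, 0, s))
  mixed <- (1 - nf) * v + nf * noise
  minmaxNormalize(mixed, kind = "noisy", noiseFraction = nf)
}

#' Simulate cognitive scores for a cohort
#'
#' Convenience wrapper: lesion loads, Eq.-style weighted sum, min-max
#' normalization, optional noise injection.
#'
#' @param cohort a [LesionCohort-class].
#' @param rois a [ROISet-class]; its weights are used unless `weights`
#'   overrides them.
#' @param weights optional per-ROI weights.
#' @param nf noise fraction (0 = no noise).
#' @param seed seed for the noise draw.
#' @return A normalized [ScoreVector-class].
#' @export
simulateScores <- function(cohort, rois, weights = NULL, nf = 0, seed = 1L) {
  if (is.null(weights)) weights <- rois@weights
  loads <- lesionLoad(cohort, rois)
  raw <- weightedRawScore(loads, weights)
  kind <- if (all(weights == weights[1])) "basic" else "weighted"
  sc <- minmaxNormalize(raw, kind = kind)
  if (nf > 0) sc <- addNoise(sc, nf, seed) else sc
}
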