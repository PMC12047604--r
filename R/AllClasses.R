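#' @import methods
NULL

#' VolumeGrid: the shared sampling grid of a lesion-mapping study
#'
#' All volumes in a cohort live on one grid: a voxel dimension triple, a
#' voxel size triple in millimetres, and a free-text space label (for
#' example `"MNI152-like"`). Two grids are compatible only when dimensions,
#' voxel sizes and space label match exactly; no resampling is ever applied.
#'
#' @slot dim integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot space character(1), free-text space label.
#' @export
setClass("VolumeGrid",
  representation(dim = "integer", spacing = "numeric", space = "character"),
  prototype(space = "unspecified")
)

setValidity("VolumeGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("grid dim must be 3 integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("voxel spacing must be 3 positive lengths (mm)")
  if (length(object@space) != 1L)
    return("space label must be a single string")
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param dim voxels per axis (length-3 integer-like).
#' @param spacing voxel size in mm (length-3, or a scalar recycled to 3).
#' @param space free-text space label.
#' @return A [VolumeGrid-class] object.
#' @examples
#' volumeGrid(c(18, 22, 18), 10, "MNI152-like")
#' @export
volumeGrid <- function(dim, spacing = 1, space = "unspecified") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeGrid", dim = as.integer(dim), spacing = as.numeric(spacing),
      space = as.character(space))
}

#' LesionMap: one subject's binary lesion mask
#'
#' A 3D array of 0/1 values on a [VolumeGrid-class]. This is the model
#' input and the unit of simulation: 1 marks a lesioned voxel (for WMH,
#' a voxel segmented as hyperintense).
#'
#' @slot grid the [VolumeGrid-class].
#' @slot data 3D numeric array of exactly 0/1.
#' @slot subjectId character(1).
#' @export
setClass("LesionMap",
  representation(grid = "VolumeGrid", data = "array", subjectId = "character")
)

setValidity("LesionMap", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("lesion map data must be a 3D array")
  if (!identical(dim(d), as.integer(object@grid@dim)))
    return("data dimensions do not match grid")
  if (any(!is.finite(d))) return("non-finite voxel values")
  if (!all(d == 0 | d == 1)) return("lesion map values must be exactly 0 or 1")
  if (length(object@subjectId) != 1L) return("subjectId must be length 1")
  TRUE
})

#' @rdname LesionMap-class
#' @param data 3D array coercible to 0/1.
#' @param grid a [VolumeGrid-class].
#' @param subjectId subject identifier.
#' @export
lesionMap <- function(data, grid, subjectId = "subject") {
  new("LesionMap", grid = grid, data = array(as.numeric(data), dim = grid@dim),
      subjectId = as.character(subjectId))
}

#' LesionCohort: a cohort of co-registered binary lesion maps
#'
#' Maps are stored column-wise in a voxels-by-subjects matrix (values 0/1)
#' so that prevalence, flattening and lesion-load computations are single
#' matrix operations; [getMap()] rebuilds the 3D array of one subject.
#' Scores, when present, are aligned with `subjectIds`.
#'
#' @slot grid shared [VolumeGrid-class].
#' @slot voxels numeric matrix, `prod(dim)` rows, one column per subject.
#' @slot subjectIds character, unique, in cohort order.
#' @slot scores numeric, per-subject score or NA.
#' @export
setClass("LesionCohort",
  representation(grid = "VolumeGrid", voxels = "matrix",
                 subjectIds = "character", scores = "numeric")
)

setValidity("LesionCohort", function(object) {
  n <- ncol(object@voxels)
  if (nrow(object@voxels) != prod(object@grid@dim))
    return("voxel matrix rows must equal grid voxel count")
  if (length(object@subjectIds) != n)
    return("one subject id per column required")
  if (anyDuplicated(object@subjectIds))
    return("duplicate subject_id")
  if (length(object@scores) != n)
    return("scores must have one entry per subject (NA allowed)")
  v <- object@voxels
  if (any(v != 0 & v != 1)) return("cohort voxels must be 0/1")
  TRUE
})

#' ScoreVector: per-subject cognitive scores
#'
#' Simulated (basic / weighted / noisy) or real scores. Normalized vectors
#' are min-max scaled within the study population so the best (highest)
#' score is exactly 1 and the lowest exactly 0.
#'
#' @slot values numeric per-subject scores.
#' @slot kind one of `"basic"`, `"weighted"`, `"noisy"`, `"real"`.
#' @slot noiseFraction mixing weight nf in `[0,1]`; 0 unless noisy.
#' @slot normalized logical(1).
#' @export
setClass("ScoreVector",
  representation(values = "numeric", kind = "character",
                 noiseFraction = "numeric", normalized = "logical"),
  prototype(kind = "basic", noiseFraction = 0, normalized = FALSE)
)

setValidity("ScoreVector", function(object) {
  if (!object@kind %in% c("basic", "weighted", "noisy", "real"))
    return("kind must be basic/weighted/noisy/real")
  if (object@noiseFraction < 0 || object@noiseFraction > 1)
    return("noiseFraction must lie in [0,1]")
  if (object@normalized) {
    v <- object@values
    if (any(v < 0 | v > 1)) return("normalized scores must lie in [0,1]")
    if (max(v) != 1) return("normalized scores must attain 1 exactly")
  }
  TRUE
})

#' @rdname ScoreVector-class
#' @param values numeric scores.
#' @param kind score kind.
#' @param noiseFraction noise fraction nf.
#' @param normalized whether values are population min-max normalized.
#' @export
scoreVector <- function(values, kind = "basic", noiseFraction = 0,
                        normalized = FALSE) {
  new("ScoreVector", values = as.numeric(values), kind = kind,
      noiseFraction = noiseFraction, normalized = normalized)
}

#' LesionPriorField: voxelwise lesion-seeding propensity
#'
#' A smooth non-negative field on the grid giving the relative propensity
#' of lesion seeding per voxel. The default prior emulates the
#' periventricular-dominant spatial prevalence of WMH: a band around two
#' deep ellipsoidal shells, near zero elsewhere.
#'
#' @slot grid the [VolumeGrid-class].
#' @slot intensity 3D non-negative array; at least one positive voxel.
#' @export
setClass("LesionPriorField",
  representation(grid = "VolumeGrid", intensity = "array")
)

setValidity("LesionPriorField", function(object) {
  if (!identical(dim(object@intensity), as.integer(object@grid@dim)))
    return("intensity dimensions do not match grid")
  if (any(object@intensity < 0)) return("intensity must be non-negative")
  if (!any(object@intensity > 0)) return("at least one positive voxel required")
  TRUE
})

#' PrevalenceMap: voxelwise lesion counts across a cohort
#'
#' `counts[v]` is the number of subjects with a lesion at voxel v, obtained
#' by summing all binary maps of the cohort.
#'
#' @slot grid the [VolumeGrid-class].
#' @slot counts 3D array of non-negative integers.
#' @slot nSubjects cohort size.
#' @export
setClass("PrevalenceMap",
  representation(grid = "VolumeGrid", counts = "array", nSubjects = "integer")
)

setValidity("PrevalenceMap", function(object) {
  if (!identical(dim(object@counts), as.integer(object@grid@dim)))
    return("counts dimensions do not match grid")
  if (any(object@counts < 0) || any(object@counts > object@nSubjects))
    return("counts must lie in [0, nSubjects]")
  TRUE
})

#' ROISet: cuboid regions of interest with contribution weights
#'
#' Axis-aligned cuboids on the grid, stored as 0-based half-open index
#' ranges `[lo, lo + size)`. Each ROI carries a positive contribution
#' weight w_k used by the weighted score model. ROIs are pairwise disjoint
#' and fully inside the grid.
#'
#' @slot grid the [VolumeGrid-class].
#' @slot lo integer matrix k x 3, 0-based lower corners.
#' @slot size integer matrix k x 3, extents in voxels.
#' @slot ids character ROI identifiers.
#' @slot weights numeric positive per-ROI weights w_k.
#' @export
setClass("ROISet",
  representation(grid = "VolumeGrid", lo = "matrix", size = "matrix",
                 ids = "character", weights = "numeric")
)

setValidity("ROISet", function(object) {
  k <- nrow(object@lo)
  if (!all(dim(object@lo) == c(k, 3L)) || !all(dim(object@size) == c(k, 3L)))
    return("lo and size must be k x 3 matrices")
  if (length(object@ids) != k || length(object@weights) != k)
    return("ids and weights must have one entry per ROI")
  if (anyDuplicated(object@ids)) return("duplicate ROI ids")
  if (any(object@weights <= 0)) return("ROI weights must be positive")
  if (any(object@size < 1)) return("ROI size must be >= 1 voxel per axis")
  d <- object@grid@dim
  for (i in seq_len(k)) {
    if (any(object@lo[i, ] < 0) || any(object@lo[i, ] + object@size[i, ] > d))
      return(sprintf("ROI '%s' extends outside the grid", object@ids[i]))
  }
  if (k > 1L) {
    # pairwise disjointness of half-open cuboids
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      lo1 <- object@lo[i, ]; hi1 <- lo1 + object@size[i, ]
      lo2 <- object@lo[j, ]; hi2 <- lo2 + object@size[j, ]
      if (all(pmax(lo1, lo2) < pmin(hi1, hi2)))
        return(sprintf("ROIs '%s' and '%s' overlap",
                       object@ids[i], object@ids[j]))
    }
  }
  TRUE
})

#' @rdname ROISet-class
#' @param grid a [VolumeGrid-class].
#' @param lo k x 3 matrix of 0-based lower corners.
#' @param size k x 3 matrix (or length-3 vector recycled) of extents.
#' @param ids ROI identifiers; default `roi1..roik`.
#' @param weights per-ROI contribution weights, default 1.
#' @export
roiSet <- function(grid, lo, size, ids = NULL, weights = NULL) {
  lo <- matrix(as.integer(lo), ncol = 3L)
  if (is.null(dim(size)) && length(size) == 3L)
    size <- matrix(as.integer(size), nrow = nrow(lo), ncol = 3L, byrow = TRUE)
  size <- matrix(as.integer(size), ncol = 3L)
  k <- nrow(lo)
  if (is.null(ids)) ids <- paste0("roi", seq_len(k))
  if (is.null(weights)) weights <- rep(1, k)
  new("ROISet", grid = grid, lo = lo, size = size,
      ids = as.character(ids), weights = as.numeric(weights))
}

#' VoxelSelectionMask: mass-univariate feature selection result
#'
#' Per-voxel test statistics for the two-group comparison of scores between
#' lesioned and non-lesioned subjects, the tested-voxel mask (lesion count
#' within `[minLesionCount, n - minLesionCount]`), and the selected voxels
#' (tested, p below alpha, lesion associated with higher score).
#'
#' @slot grid the [VolumeGrid-class].
#' @slot selected 3D logical array.
#' @slot tested 3D logical array; `selected` is a subset of `tested`.
#' @slot stat 3D numeric array of test statistics (NA where untested).
#' @slot p 3D numeric array of one-sided p-values (NA where untested).
#' @export
setClass("VoxelSelectionMask",
  representation(grid = "VolumeGrid", selected = "array", tested = "array",
                 stat = "array", p = "array")
)

setValidity("VoxelSelectionMask", function(object) {
  d <- as.integer(object@grid@dim)
  for (s in c("selected", "tested", "stat", "p"))
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("%s dimensions do not match grid", s))
  if (any(object@selected & !object@tested))
    return("selected voxels must be a subset of tested voxels")
  TRUE
})

#' FeatureMatrix: flattened voxel features for SVR / FNN
#'
#' One row per subject (cohort order), one column per selected voxel in
#' ascending linear-index (lexicographic) order; `voxelIndex` maps columns
#' back onto the grid for attribution back-projection.
#'
#' @slot values numeric matrix, subjects x features.
#' @slot voxelIndex integer, 1-based linear voxel index per column.
#' @slot grid the [VolumeGrid-class].
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", voxelIndex = "integer", grid = "VolumeGrid")
)

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@values) != length(object@voxelIndex))
    return("one voxel index per feature column required")
  if (anyDuplicated(object@voxelIndex)) return("duplicate voxel indices")
  if (length(object@voxelIndex) &&
      (min(object@voxelIndex) < 1L ||
       max(object@voxelIndex) > prod(object@grid@dim)))
    return("voxel indices outside grid")
  if (is.unsorted(object@voxelIndex)) return("voxel indices must be ascending")
  TRUE
})

#' AttributionMap: voxelwise lesion-location importance
#'
#' Individual (`subjectId`) or group-level (`"group"`) importance of each
#' lesion location for the model's predicted score. Sign convention:
#' positive values mark locations whose lesions drive a higher (worse)
#' predicted score; for occlusion, positive where occluding the window
#' lowers the prediction.
#'
#' @slot grid the [VolumeGrid-class].
#' @slot data 3D numeric array, finite everywhere.
#' @slot subjectId subject id or `"group"`.
#' @slot method one of `"occlusion"`, `"svr_beta"`, `"fnn_weights"`.
#' @export
setClass("AttributionMap",
  representation(grid = "VolumeGrid", data = "array",
                 subjectId = "character", method = "character")
)

setValidity("AttributionMap", function(object) {
  if (!identical(dim(object@data), as.integer(object@grid@dim)))
    return("data dimensions do not match grid")
  if (any(!is.finite(object@data))) return("attribution values must be finite")
  if (!object@method %in% c("occlusion", "svr_beta", "fnn_weights"))
    return("unknown attribution method")
  TRUE
})

attributionMap <- function(data, grid, subjectId, method) {
  new("AttributionMap", grid = grid,
      data = array(as.numeric(data), dim = grid@dim),
      subjectId = as.character(subjectId), method = method)
}

#' Trained lesion-symptom models
#'
#' `LSMModel` is the virtual parent of the three model families:
#' `SVRModel` (radial-basis support vector regression on flattened
#' features), `FNNModel` (one linear layer plus ReLU on flattened
#' features), and `CNNModel` (3D convolutional network on full maps).
#' All carry a config snapshot and respond to [predictScores()].
#'
#' @slot family model family label.
#' @slot config training configuration snapshot (list).
#' @export
setClass("LSMModel", representation("VIRTUAL",
  family = "character", config = "list"))

#' @rdname LSMModel-class
#' @slot fit the underlying [e1071::svm()] fit.
#' @slot voxelIndex linear voxel indices of the feature columns.
#' @slot grid the [VolumeGrid-class] features were taken from.
#' @slot tuning grid-search results (data.frame).
#' @export
setClass("SVRModel", contains = "LSMModel",
  representation(fit = "ANY", voxelIndex = "integer", grid = "VolumeGrid",
                 tuning = "data.frame"))

#' @rdname LSMModel-class
#' @slot weights per-feature weight vector of the linear layer.
#' @slot bias scalar bias of the linear layer.
#' @slot history per-epoch training loss.
#' @export
setClass("FNNModel", contains = "LSMModel",
  representation(weights = "numeric", bias = "numeric",
                 voxelIndex = "integer", grid = "VolumeGrid",
                 history = "numeric"))

#' @rdname LSMModel-class
#' @slot params named list of weight arrays (conv kernels, linear layers).
#' @slot arch `"simple"` or `"regularized"`.
#' @export
setClass("CNNModel", contains = "LSMModel",
  representation(params = "list", arch = "character", grid = "VolumeGrid",
                 history = "numeric"))

#' EvaluationReport: predictive performance and attribution accuracy
#'
#' Per-fold out-of-sample R-squared (ordinary least squares of truth on
#' prediction), precision-recall AUC of the group attribution map against
#' the ROI ground truth, supra-threshold in/out-ROI attribution ratios
#' (plain and with millimetre dilation of the ROIs), Dice coefficient and
#' the list of false-negative ROIs.
#'
#' @slot model model family label.
#' @slot r2Folds per-fold R-squared values.
#' @slot prAUC precision-recall AUC in `[0,1]` (NA when not evaluated).
#' @slot attributionRatio in/out-ROI attribution ratio (may be `Inf`).
#' @slot dilatedRatio ratio with dilated ROIs.
#' @slot dilationFactor `dilatedRatio / attributionRatio`, as computed.
#' @slot dice Dice coefficient of the thresholded map vs the ROI union.
#' @slot falseNegativeROIs ids of ROIs with no supra-threshold voxel.
#' @slot config evaluation/config snapshot.
#' @export
setClass("EvaluationReport",
  representation(model = "character", r2Folds = "numeric", prAUC = "numeric",
                 attributionRatio = "numeric", dilatedRatio = "numeric",
                 dilationFactor = "numeric", dice = "numeric",
                 falseNegativeROIs = "character", config = "list"))
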