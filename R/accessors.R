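#' @rdname gridDim
setMethod("gridDim", "VolumeGrid", function(x) x@dim)
#' @rdname gridDim
setMethod("voxelSize", "VolumeGrid", function(x) x@spacing)
#' @rdname gridDim
setMethod("voxelVolumeMl", "VolumeGrid", function(x) prod(x@spacing) / 1000)
#' @rdname gridDim
setMethod("spaceLabel", "VolumeGrid", function(x) x@space)

#' @rdname volumeGrid
setMethod("getGrid", "VolumeGrid", function(x) x)

grid_carriers <- c("LesionMap", "LesionCohort", "LesionPriorField",
                   "PrevalenceMap", "ROISet", "VoxelSelectionMask",
                   "AttributionMap", "FeatureMatrix")
for (.cls in grid_carriers) {
  setMethod("getGrid", .cls, function(x) x@grid)
  setMethod("gridDim", .cls, function(x) x@grid@dim)
  setMethod("voxelSize", .cls, function(x) x@grid@spacing)
  setMethod("voxelVolumeMl", .cls, function(x) prod(x@grid@spacing) / 1000)
  setMethod("spaceLabel", .cls, function(x) x@grid@space)
}

#' Test whether two grids are compatible
#'
#' Compatibility requires exactly equal dimensions, voxel sizes and space
#' labels; no tolerance is applied.
#'
#' @param a,b [VolumeGrid-class] objects (or carriers).
#' @return logical(1).
#' @export
sameGrid <- function(a, b) {
  ga <- getGrid(a); gb <- getGrid(b)
  identical(ga@dim, gb@dim) && identical(ga@spacing, gb@spacing) &&
    identical(ga@space, gb@space)
}

setMethod("nSubjects", "LesionCohort", function(x) ncol(x@voxels))
setMethod("subjectIds", "LesionCohort", function(x) x@subjectIds)
setMethod("cohortScores", "LesionCohort", function(x) {
  stats::setNames(x@scores, x@subjectIds)
})

setMethod("getMap", "LesionCohort", function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@subjectIds)
    if (is.na(i)) stop("unknown subject id")
  }
  lesionMap(x@voxels[, i], x@grid, x@subjectIds[i])
})

setMethod("lesionVolumeMl", "LesionMap", function(x)
  sum(x@data) * voxelVolumeMl(x@grid))
setMethod("lesionVolumeMl", "LesionCohort", function(x)
  stats::setNames(colSums(x@voxels) * voxelVolumeMl(x@grid), x@subjectIds))

setMethod("nROIs", "ROISet", function(x) nrow(x@lo))
setMethod("roiIds", "ROISet", function(x) x@ids)
setMethod("roiWeights", "ROISet", function(x)
  stats::setNames(x@weights, x@ids))
setMethod("roiWeights<-", "ROISet", function(x, value) {
  x@weights <- as.numeric(value)
  validObject(x)
  x
})

setMethod("scoreValues", "ScoreVector", function(x) x@values)

#' Coerce volume-carrying objects to plain arrays
#'
#' @param x a [LesionMap-class], [AttributionMap-class],
#'   [PrevalenceMap-class] or [LesionPriorField-class].
#' @param ... ignored.
#' @export
setMethod("as.array", "LesionMap", function(x, ...) x@data)
#' @rdname as.array-LesionMap-method
setMethod("as.array", "AttributionMap", function(x, ...) x@data)
#' @rdname as.array-LesionMap-method
setMethod("as.array", "PrevalenceMap", function(x, ...) x@counts)
#' @rdname as.array-LesionMap-method
setMethod("as.array", "LesionPriorField", function(x, ...) x@intensity)

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid %s @ %s mm [%s]\n",
              paste(object@dim, collapse = "x"),
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              object@space))
})

setMethod("show", "LesionMap", function(object) {
  cat(sprintf("LesionMap '%s': %d lesioned voxels (%.2f ml) on %s grid\n",
              object@subjectId, sum(object@data),
              lesionVolumeMl(object),
              paste(object@grid@dim, collapse = "x")))
})

setMethod("show", "LesionCohort", function(object) {
  v <- lesionVolumeMl(object)
  cat(sprintf("LesionCohort: %d subjects on %s grid @ %s mm\n",
              nSubjects(object), paste(object@grid@dim, collapse = "x"),
              paste(format(object@grid@spacing, trim = TRUE), collapse = "x")))
  cat(sprintf("  lesion volume (ml): median %.1f, IQR %.1f-%.1f\n",
              stats::median(v), stats::quantile(v, 0.25),
              stats::quantile(v, 0.75)))
  if (!all(is.na(object@scores)))
    cat(sprintf("  scores: range [%.3f, %.3f]\n",
                min(object@scores, na.rm = TRUE),
                max(object@scores, na.rm = TRUE)))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d cuboid ROI(s) on %s grid\n", nROIs(object),
              paste(object@grid@dim, collapse = "x")))
  for (i in seq_len(nROIs(object)))
    cat(sprintf("  %s: lo=(%s) size=(%s) w=%g\n", object@ids[i],
                paste(object@lo[i, ], collapse = ","),
                paste(object@size[i, ], collapse = ","),
                object@weights[i]))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector (%s%s): n=%d, range [%.3f, %.3f]%s\n",
              object@kind,
              if (object@noiseFraction > 0)
                sprintf(", nf=%.2f", object@noiseFraction) else "",
              length(object@values), min(object@values), max(object@values),
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "AttributionMap", function(object) {
  cat(sprintf("AttributionMap [%s] '%s': value range [%.4g, %.4g]\n",
              object@method, object@subjectId,
              min(object@data), max(object@data)))
})

setMethod("show", "VoxelSelectionMask", function(object) {
  cat(sprintf("VoxelSelectionMask: %d tested, %d selected voxels\n",
              sum(object@tested), sum(object@selected)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d subjects x %d voxel features\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "LSMModel", function(object) {
  cat(sprintf("Trained %s lesion-symptom model\n", object@family))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s]\n", object@model))
  cat(sprintf("  R2 (per fold): mean %.3f, sd %.3f\n",
              mean(object@r2Folds), stats::sd(object@r2Folds)))
  cat(sprintf("  PR-AUC: %.3f\n", object@prAUC))
  cat(sprintf("  attribution ratio: %.3g (dilated %.3g, factor %.2fx)\n",
              object@attributionRatio, object@dilatedRatio,
              object@dilationFactor))
  cat(sprintf("  Dice: %.3f; false-negative ROIs: %s\n", object@dice,
              if (length(object@falseNegativeROIs))
                paste(object@falseNegativeROIs, collapse = ", ") else "none"))
})
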