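#' @rdname volumeGrid
#' @param x an object with a grid.
#' @export
setGeneric("getGrid", function(x) standardGeneric("getGrid"))

#' Grid accessors
#'
#' `gridDim` returns voxels per axis, `voxelSize` the voxel edge lengths in
#' mm, `voxelVolumeMl` the volume of one voxel in millilitres, and
#' `spaceLabel` the space annotation.
#'
#' @param x a [VolumeGrid-class] or any object carrying one.
#' @return numeric/integer vectors as described.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridDim
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname gridDim
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' @rdname gridDim
#' @export
setGeneric("spaceLabel", function(x) standardGeneric("spaceLabel"))

#' Cohort accessors
#'
#' @param x a [LesionCohort-class].
#' @param i subject index or id (for `getMap`).
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname nSubjects
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname nSubjects
#' @export
setGeneric("cohortScores", function(x) standardGeneric("cohortScores"))

#' @rdname nSubjects
#' @export
setGeneric("getMap", function(x, i) standardGeneric("getMap"))

#' Total lesion volume
#'
#' Lesioned-voxel count times voxel volume, in millilitres.
#'
#' @param x a [LesionMap-class] or [LesionCohort-class].
#' @return For a map, a scalar; for a cohort, one value per subject.
#' @export
setGeneric("lesionVolumeMl", function(x) standardGeneric("lesionVolumeMl"))

#' ROI accessors
#'
#' @param x a [ROISet-class].
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))

#' @rdname nROIs
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname nROIs
#' @export
setGeneric("roiWeights", function(x) standardGeneric("roiWeights"))

#' @rdname nROIs
#' @param value replacement weights (length = number of ROIs, positive).
#' @export
setGeneric("roiWeights<-", function(x, value) standardGeneric("roiWeights<-"))

#' Predict per-subject scores from a trained lesion-symptom model
#'
#' A pure function of (model, inputs): SVR and FNN models consume a
#' [FeatureMatrix-class] (or a plain numeric matrix with matching columns),
#' the CNN consumes a [LesionCohort-class] or a voxels-by-subjects matrix.
#'
#' @param model a fitted [LSMModel-class].
#' @param inputs inputs matching the model's contract.
#' @return numeric vector, one finite prediction per subject.
#' @export
setGeneric("predictScores", function(model, inputs)
  standardGeneric("predictScores"))

#' Raw score values
#'
#' @param x a [ScoreVector-class].
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
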