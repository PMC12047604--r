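#' Export a voxel selection mask
#'
#' Writes the selected-voxel mask as a 0/1 NIfTI volume and, optionally,
#' a CSV of per-voxel statistics (voxel index, coordinates, lesioned
#' count implied by testing, t statistic, p value) for the tested voxels.
#'
#' @param mask a [VoxelSelectionMask-class].
#' @param niftiPath output NIfTI path.
#' @param csvPath optional CSV path for per-voxel statistics.
#' @return `niftiPath`, invisibly.
#' @export
writeSelectionMask <- function(mask, niftiPath, csvPath = NULL) {
  writeScalarMap(array(as.numeric(mask@selected), mask@grid@dim),
                 mask@grid, niftiPath)
  if (!is.null(csvPath)) {
    idx <- which(mask@tested)
    coords <- indexToCoord(idx, mask@grid@dim)
    utils::write.csv(
      data.frame(voxel_index = idx, x = coords[, 1], y = coords[, 2],
                 z = coords[, 3], statistic = mask@stat[idx],
                 p_value = mask@p[idx], selected = mask@selected[idx]),
      csvPath, row.names = FALSE)
  }
  invisible(niftiPath)
}

#' Save / load a trained model with its config snapshot
#'
#' Models are serialized with R's native serialization; the training
#' configuration travels inside the object, so a reloaded model predicts
#' identically.
#'
#' @param model a fitted [LSMModel-class].
#' @param path file path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "LSMModel")) stop("not a saved lesion-symptom model")
  model
}

#' Write per-epoch training curves as CSV
#'
#' @param model a fitted [FNNModel-class] or [CNNModel-class].
#' @param path CSV path.
#' @export
writeTrainingCurve <- function(model, path) {
  if (!.hasSlot(model, "history")) stop("model has no training history")
  utils::write.csv(data.frame(epoch = seq_along(model@history),
                              loss = model@history),
                   path, row.names = FALSE)
  invisible(path)
}
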