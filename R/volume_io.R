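#' Read a binary lesion map from NIfTI
#'
#' Reads a 3D NIfTI volume and binarizes it with the rule `value > 0.5 -> 1`
#' so float-encoded masks are tolerated. The grid (dimensions, voxel sizes)
#' is populated from the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param subjectId subject identifier; defaults to the file stem.
#' @param space space label to record on the grid.
#' @return A [LesionMap-class].
#' @export
readLesionMap <- function(path, subjectId = NULL, space = "unspecified") {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D volume: ", path, " has ", length(d),
                            " dimensions")
  v <- as.numeric(img)
  if (any(!is.finite(v))) stop("non-finite voxel values in ", path)
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  grid <- volumeGrid(d, RNifti::pixdim(img), space)
  lesionMap(as.numeric(v > 0.5), grid, subjectId)
}

#' Write a scalar 3D map as NIfTI
#'
#' @param values 3D numeric array (finite), shape matching `grid`.
#' @param grid the [VolumeGrid-class] defining voxel sizes.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly. Read-back reproduces the values within
#'   float32 precision and the grid exactly.
#' @export
writeScalarMap <- function(values, grid, path) {
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid@dim)))
    stop("values shape does not match grid")
  if (any(!is.finite(values))) stop("non-finite values")
  img <- RNifti::asNifti(array(values, dim = grid@dim))
  RNifti::pixdim(img) <- grid@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeScalarMap
#' @param map a [LesionMap-class] or [AttributionMap-class] to write.
#' @export
writeVolume <- function(map, path) {
  writeScalarMap(as.array(map), getGrid(map), path)
}

#' Read a cohort manifest CSV
#'
#' The manifest has columns `subject_id`, `map_path` and optionally
#' `score`. Relative map paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with resolved paths.
#' @export
readCohortManifest <- function(path) {
  if (!file.exists(path)) stop("missing manifest: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "map_path")
  if (!all(req %in% names(m)))
    stop("manifest must have columns subject_id, map_path")
  rel <- !grepl("^(/|[A-Za-z]:)", m$map_path)
  m$map_path[rel] <- file.path(dirname(path), m$map_path[rel])
  m
}

#' Load a cohort of lesion maps from a manifest
#'
#' Loads all maps in manifest order, enforcing unique subject ids and one
#' shared grid across the cohort (exact match of dimensions and voxel
#' sizes; no resampling).
#'
#' @param manifest a manifest data.frame (columns `subject_id`, `map_path`,
#'   optional `score`) or the path of a manifest CSV.
#' @param requireScores error when any score is missing.
#' @param space space label stamped on the shared grid.
#' @return A [LesionCohort-class] in manifest order.
#' @export
loadCohort <- function(manifest, requireScores = FALSE,
                       space = "unspecified") {
  if (is.character(manifest)) manifest <- readCohortManifest(manifest)
  ids <- as.character(manifest$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scores <- if ("score" %in% names(manifest))
    as.numeric(manifest$score) else rep(NA_real_, length(ids))
  if (requireScores && any(is.na(scores)))
    stop("score missing for subject(s): ",
         paste(ids[is.na(scores)], collapse = ", "))
  maps <- lapply(seq_along(ids), function(i)
    readLesionMap(manifest$map_path[i], ids[i], space))
  grid <- getGrid(maps[[1]])
  for (i in seq_along(maps))
    if (!sameGrid(maps[[i]], grid))
      stop("grid mismatch: subject '", ids[i],
           "' is not on the cohort grid")
  vox <- vapply(maps, function(m) as.numeric(m@data),
                numeric(prod(grid@dim)))
  newCohort(vox, grid, ids, scores)
}

newCohort <- function(vox, grid, ids, scores = rep(NA_real_, ncol(vox))) {
  new("LesionCohort", grid = grid,
      voxels = matrix(as.numeric(vox), nrow = prod(grid@dim),
                      dimnames = NULL),
      subjectIds = as.character(ids), scores = as.numeric(scores))
}

#' Write a cohort to NIfTI files plus a manifest CSV
#'
#' @param cohort a [LesionCohort-class].
#' @param dir output directory (created if needed).
#' @param scores optional [ScoreVector-class] or numeric vector written to
#'   the `score` column (defaults to the cohort's own scores).
#' @return Path of the written manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir, scores = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scores)) scores <- cohort@scores
  if (is(scores, "ScoreVector")) scores <- scoreValues(scores)
  ids <- subjectIds(cohort)
  paths <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_along(ids))
    writeScalarMap(array(cohort@voxels[, i], cohort@grid@dim),
                   cohort@grid, paths[i])
  man <- data.frame(subject_id = ids, map_path = basename(paths),
                    score = scores)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  invisible(manPath)
}
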