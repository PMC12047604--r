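#' Derive a stage seed from a master seed
#'
#' Experiments derive one sub-seed per named stage from the master seed so
#' stages can be re-run in isolation. The map is a fixed affine hash modulo
#' a Mersenne prime, keeping seeds in the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stage stage index (integer) or a stage name (hashed).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(stage) * 16807 + 1
  as.integer(s %% (m - 1) + 1)
}

# local RNG scope: run expr with a temporary seed, restoring the caller's
# RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1-based linear indices of the voxels of one cuboid [lo, lo+size)
cuboidIndices <- function(lo, size, dims) {
  ix <- (lo[1] + 1L):(lo[1] + size[1])
  iy <- (lo[2] + 1L):(lo[2] + size[2])
  iz <- (lo[3] + 1L):(lo[3] + size[3])
  g <- expand.grid(x = ix, y = iy, z = iz)
  as.integer(g$x + (g$y - 1L) * dims[1] + (g$z - 1L) * dims[1] * dims[2])
}

#' Logical mask of the ROI union
#'
#' @param rois a [ROISet-class].
#' @return 3D logical array, TRUE inside any ROI.
#' @export
roiMask <- function(rois) {
  d <- rois@grid@dim
  m <- array(FALSE, d)
  for (i in seq_len(nROIs(rois)))
    m[cuboidIndices(rois@lo[i, ], rois@size[i, ], d)] <- TRUE
  m
}

# per-ROI list of linear voxel indices
roiIndexList <- function(rois) {
  d <- rois@grid@dim
  out <- lapply(seq_len(nROIs(rois)), function(i)
    cuboidIndices(rois@lo[i, ], rois@size[i, ], d))
  names(out) <- rois@ids
  out
}

# voxel coordinates (1-based, k x 3) of linear indices
indexToCoord <- function(idx, dims) {
  idx0 <- idx - 1L
  x <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  z <- idx0 %/% (dims[1] * dims[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

#' Dilate the ROI union by a Euclidean distance in millimetres
#'
#' A voxel is in the dilated set when its centre lies within `mm` of the
#' centre of any ROI voxel, honouring anisotropic voxel sizes.
#'
#' @param rois a [ROISet-class].
#' @param mm dilation radius in millimetres.
#' @return 3D logical array.
#' @export
dilatedRoiMask <- function(rois, mm) {
  base <- roiMask(rois)
  if (mm <= 0) return(base)
  d <- rois@grid@dim
  sp <- rois@grid@spacing
  # voxel-offset ball covering the radius
  r <- floor(mm / sp)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2 <=
    mm^2
  offs <- offs[keep, , drop = FALSE]
  src <- which(base, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (i in seq_len(nrow(offs))) {
    sh <- cbind(src[, 1] + offs$dx[i], src[, 2] + offs$dy[i],
                src[, 3] + offs$dz[i])
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  out
}

#' Serialize an ROISet to JSON
#'
#' @param rois a [ROISet-class].
#' @param path output path.
#' @export
writeROISet <- function(rois, path) {
  obj <- list(
    grid = list(dim = rois@grid@dim, spacing = rois@grid@spacing,
                space = rois@grid@space),
    rois = lapply(seq_len(nROIs(rois)), function(i)
      list(id = rois@ids[i], lo = rois@lo[i, ], size = rois@size[i, ],
           weight = rois@weights[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeROISet
#' @export
readROISet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- volumeGrid(obj$grid$dim, obj$grid$spacing, obj$grid$space)
  if (is.data.frame(obj$rois)) {
    lo <- do.call(rbind, obj$rois$lo)
    size <- do.call(rbind, obj$rois$size)
    roiSet(grid, lo, size, obj$rois$id, obj$rois$weight)
  } else {
    lo <- do.call(rbind, lapply(obj$rois, `[[`, "lo"))
    size <- do.call(rbind, lapply(obj$rois, `[[`, "size"))
    roiSet(grid, lo, size,
           vapply(obj$rois, `[[`, character(1), "id"),
           vapply(obj$rois, `[[`, numeric(1), "weight"))
  }
}
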