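#' @include AllClasses.R
NULL

#' Preprocessing configuration
#'
#' Data normalization applied identically at train and test time: in-plane
#' resampling to a standard pixel spacing, central crop or zero-pad to a
#' fixed network grid, and per-slice intensity standardization. Slice
#' thickness along z is never changed.
#'
#' @param targetSpacing in-plane target spacing (ty, tx) in mm; default
#'   \code{c(1.25, 1.25)}, the standard resolution the pipeline normalizes to
#' @param cropSize network grid (H, W); both must be positive and even,
#'   default \code{c(256, 256)}
#' @param resample logical; disabling skips the resampling step (used by the
#'   normalization ablation)
#' @return a \code{PreprocessConfig} list
#' @export
preprocessConfig <- function(targetSpacing = c(1.25, 1.25),
                             cropSize = c(256L, 256L),
                             resample = TRUE) {
  targetSpacing <- as.numeric(targetSpacing)
  cropSize <- as.integer(cropSize)
  if (length(targetSpacing) != 2L || any(!is.finite(targetSpacing)) ||
      any(targetSpacing <= 0))
    stop("targetSpacing must be two positive values (ty, tx) in mm")
  if (length(cropSize) != 2L || any(cropSize <= 0L) || any(cropSize %% 2L != 0L))
    stop("cropSize must be two positive even integers (H, W)")
  structure(list(targetSpacing = targetSpacing, cropSize = cropSize,
                 resample = isTRUE(resample)),
            class = "PreprocessConfig")
}

#' @export
print.PreprocessConfig <- function(x, ...) {
  cat(sprintf("PreprocessConfig: target spacing (%.3g, %.3g) mm, crop %dx%d, resample %s\n",
              x$targetSpacing[1], x$targetSpacing[2], x$cropSize[1], x$cropSize[2],
              if (x$resample) "on" else "off"))
  invisible(x)
}

resampledShapeFor <- function(shapeYX, spacingYX, targetYX) {
  out <- as.integer(roundHalfUp(shapeYX * spacingYX / targetYX))
  pmax(out, 1L)
}

#' Resample a volume or label map within the short-axis plane
#'
#' Images are interpolated bilinearly, label maps nearest-neighbor. The slice
#' count and slice spacing are unchanged. The output in-plane shape is
#' \code{round(shape * spacing / target)} with half-away-from-zero rounding.
#'
#' @param x a \linkS4class{VolumeImage} or \linkS4class{LabelMap}
#' @param targetSpacing in-plane target spacing (ty, tx) in mm
#' @return list with \code{result} (same class as \code{x}) and
#'   \code{geometry}, the resampling fragment of a \linkS4class{GeometryRecord}
#' @export
resampleInPlane <- function(x, targetSpacing = c(1.25, 1.25)) {
  targetSpacing <- as.numeric(targetSpacing)
  if (any(!is.finite(targetSpacing)) || any(targetSpacing <= 0))
    stop("targetSpacing must be positive")
  isLab <- is(x, "LabelMap")
  if (!isLab && !is(x, "VolumeImage")) stop("x must be a VolumeImage or LabelMap")
  arr <- if (isLab) x@labels else x@voxels
  sp <- x@spacing
  d <- dim(arr)
  outYX <- resampledShapeFor(d[2:3], sp[2:3], targetSpacing)
  out <- array(if (isLab) 0L else 0, dim = c(d[1], outYX))
  for (z in seq_len(d[1])) {
    sl <- arr[z, , , drop = TRUE]
    dim(sl) <- d[2:3]
    rs <- if (isLab) cpp_resize_nearest(sl + 0.0, outYX[1], outYX[2])
          else cpp_resize_bilinear(sl, outYX[1], outYX[2])
    out[z, , ] <- if (isLab) as.integer(rs) else rs
  }
  newSpacing <- c(sp[1], targetSpacing)
  geom <- list(originalShape = as.integer(d), originalSpacing = sp,
               resampledShape = outYX, targetSpacing = targetSpacing)
  result <- if (isLab) LabelMap(out, newSpacing) else VolumeImage(out, newSpacing)
  list(result = result, geometry = geom)
}

cropPadParams <- function(sizeYX, cropYX) {
  off <- integer(2L); pad <- integer(2L)
  for (a in 1:2) {
    if (sizeYX[a] >= cropYX[a]) off[a] <- (sizeYX[a] - cropYX[a]) %/% 2L
    else pad[a] <- (cropYX[a] - sizeYX[a]) %/% 2L
  }
  list(cropOffset = off, padBefore = pad)
}

cropPadSlice <- function(sl, cropYX, off, pad, fill = 0) {
  d <- dim(sl)
  out <- array(fill, dim = cropYX)
  ny <- min(d[1], cropYX[1]); nx <- min(d[2], cropYX[2])
  out[pad[1] + seq_len(ny), pad[2] + seq_len(nx)] <-
    sl[off[1] + seq_len(ny), off[2] + seq_len(nx)]
  out
}

#' Central crop or symmetric zero-pad to a fixed in-plane size
#'
#' Axes larger than \code{cropSize} lose a centered window's surroundings;
#' smaller axes are symmetrically zero-padded. Offsets and pad amounts are
#' recorded so the operation inverts exactly.
#'
#' @param x 2D slice, 3D stack (Z, Y, X), \linkS4class{VolumeImage} or
#'   \linkS4class{LabelMap}
#' @param cropSize target in-plane size (H, W)
#' @return list with \code{result} and \code{geometry} (cropOffset, padBefore,
#'   targetSize)
#' @export
centerCropOrPad <- function(x, cropSize = c(256L, 256L)) {
  cropSize <- as.integer(cropSize)
  isLab <- is(x, "LabelMap")
  isVol <- is(x, "VolumeImage")
  arr <- if (isLab) x@labels else if (isVol) x@voxels else x
  d <- dim(arr)
  if (is.null(d)) stop("x must be a matrix or rank-3 array")
  was2d <- length(d) == 2L
  if (was2d) { dim(arr) <- c(1L, d); d <- dim(arr) }
  prm <- cropPadParams(d[2:3], cropSize)
  out <- array(if (isLab) 0L else 0, dim = c(d[1], cropSize))
  for (z in seq_len(d[1])) {
    sl <- arr[z, , , drop = TRUE]; dim(sl) <- d[2:3]
    cs <- cropPadSlice(sl, cropSize, prm$cropOffset, prm$padBefore)
    out[z, , ] <- if (isLab) as.integer(cs) else cs
  }
  geom <- c(prm, list(targetSize = cropSize))
  result <- if (isLab) LabelMap(out, x@spacing)
    else if (isVol) VolumeImage(out, x@spacing)
    else if (was2d) { o <- out[1, , ]; dim(o) <- cropSize; o }
    else out
  list(result = result, geometry = geom)
}

#' Standardize a 2D slice to zero mean and unit standard deviation
#'
#' Applied per cropped slice. A constant slice (zero standard deviation, e.g.
#' fully padded) maps to all zeros.
#'
#' @param slice2d numeric matrix
#' @return matrix with mean 0 and population sd 1, or all zeros if constant
#' @export
normalizeIntensity <- function(slice2d) {
  m <- mean(slice2d)
  s <- sqrt(mean((slice2d - m)^2))
  if (!is.finite(s) || s == 0) return(array(0, dim = dim(slice2d)))
  (slice2d - m) / s
}

makeGeometryRecord <- function(resampleGeom, cropGeom, resampleEnabled) {
  new("GeometryRecord",
      originalShape = as.integer(resampleGeom$originalShape),
      originalSpacing = as.numeric(resampleGeom$originalSpacing),
      resampledShape = as.integer(resampleGeom$resampledShape),
      targetSpacing = as.numeric(resampleGeom$targetSpacing),
      resampleEnabled = isTRUE(resampleEnabled),
      cropOffset = as.integer(cropGeom$cropOffset),
      padBefore = as.integer(cropGeom$padBefore),
      targetSize = as.integer(cropGeom$targetSize))
}

#' Preprocess one frame for the network
#'
#' Resample (if enabled) then center-crop/pad, then standardize each slice.
#'
#' @param volume a \linkS4class{VolumeImage}
#' @param config a \code{\link{preprocessConfig}}
#' @return list with \code{x}, an array (H, W, 1, Z) of normalized slices,
#'   and \code{geometry}, the complete \linkS4class{GeometryRecord}
#' @export
preprocessFrame <- function(volume, config = preprocessConfig()) {
  stopifnot(is(volume, "VolumeImage"))
  d <- dim(volume@voxels)
  if (config$resample) {
    rs <- resampleInPlane(volume, config$targetSpacing)
  } else {
    rs <- list(result = volume,
               geometry = list(originalShape = as.integer(d),
                               originalSpacing = volume@spacing,
                               resampledShape = as.integer(d[2:3]),
                               targetSpacing = volume@spacing[2:3]))
  }
  cp <- centerCropOrPad(rs$result, config$cropSize)
  geom <- makeGeometryRecord(rs$geometry, cp$geometry, config$resample)
  vox <- cp$result@voxels
  x <- array(0, dim = c(config$cropSize, 1L, d[1]))
  for (z in seq_len(d[1])) {
    sl <- vox[z, , ]; dim(sl) <- config$cropSize
    x[, , 1L, z] <- normalizeIntensity(sl)
  }
  list(x = x, geometry = geom)
}

# matching deterministic path for label maps (nearest-neighbor, same crop)
preprocessLabelFrame <- function(labelmap, config = preprocessConfig()) {
  stopifnot(is(labelmap, "LabelMap"))
  lab <- if (config$resample) resampleInPlane(labelmap, config$targetSpacing)$result
         else labelmap
  centerCropOrPad(lab, config$cropSize)$result
}

#' Restore per-class network scores to the original scanner grid
#'
#' Undoes the crop/pad (cropped-away regions receive zero score for every
#' class, which the lowest-index argmax tie-break resolves to background),
#' bilinearly rescales every class plane back to the original in-plane grid,
#' and only then assigns each pixel to the class with the highest score.
#'
#' @param scores array (H, W, 4) for one slice or (H, W, 4, Z) for a stack,
#'   on the network grid \code{targetSize} of \code{geometry}
#' @param geometry a complete \linkS4class{GeometryRecord}
#' @return a \linkS4class{LabelMap} on the original grid with the original
#'   spacing
#' @export
restorePrediction <- function(scores, geometry) {
  if (!is(geometry, "GeometryRecord")) stop("geometry must be a GeometryRecord")
  d <- dim(scores)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("scores must be (H, W, C) or (H, W, C, Z)")
  if (length(d) == 3L) dim(scores) <- c(d, 1L)
  d <- dim(scores)
  H <- geometry@targetSize[1]; W <- geometry@targetSize[2]
  if (d[1] != H || d[2] != W)
    stop(sprintf("scores grid (%dx%d) does not match geometry targetSize (%dx%d)",
                 d[1], d[2], H, W))
  nC <- d[3]; nZ <- d[4]
  oz <- geometry@originalShape[1]; oy <- geometry@originalShape[2]
  ox <- geometry@originalShape[3]
  if (nZ != oz)
    stop(sprintf("number of slices (%d) does not match original shape Z (%d)", nZ, oz))
  ry <- geometry@resampledShape[1]; rx <- geometry@resampledShape[2]
  off <- geometry@cropOffset; pad <- geometry@padBefore
  out <- array(0L, dim = c(oz, oy, ox))
  planes <- array(0, dim = c(oy, ox, nC))
  for (z in seq_len(nZ)) {
    for (cc in seq_len(nC)) {
      sl <- scores[, , cc, z]; dim(sl) <- c(H, W)
      # invert pad/crop: place the network window back on the resampled grid
      canvas <- matrix(0, nrow = ry, ncol = rx)
      ny <- min(ry, H); nx <- min(rx, W)
      canvas[off[1] + seq_len(ny), off[2] + seq_len(nx)] <-
        sl[pad[1] + seq_len(ny), pad[2] + seq_len(nx)]
      planes[, , cc] <- if (ry == oy && rx == ox) canvas
                        else cpp_resize_bilinear(canvas, oy, ox)
    }
    sm <- matrix(planes, nrow = oy * ox, ncol = nC)
    out[z, , ] <- max.col(sm, ties.method = "first") - 1L
  }
  LabelMap(out, geometry@originalSpacing)
}
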