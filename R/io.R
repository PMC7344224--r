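#' @include AllClasses.R
NULL

# RNifti returns arrays indexed (x, y, z) with pixdim (sx, sy, sz); the
# internal convention is (z, y, x), adapted here at the I/O boundary only.
niftiToInternal <- function(img) {
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got rank ", length(dim(arr)))
  pd <- RNifti::pixdim(img)
  list(voxels = aperm(arr, c(3L, 2L, 1L)), spacing = rev(pd[1:3]))
}

#' Read a 3D NIfTI volume as a VolumeImage
#'
#' @param path path to a .nii or .nii.gz file holding one 3D frame
#' @return a \linkS4class{VolumeImage} with spacing taken from the header
#'   pixdim; by convention the slice (z) axis is the lowest-resolution axis,
#'   as stored in the file's third dimension for short-axis stacks.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- niftiToInternal(RNifti::readNifti(path))
  VolumeImage(v$voxels, v$spacing)
}

#' Read a 3D NIfTI label map
#'
#' @param path path to a .nii or .nii.gz file of integer class codes
#' @return a \linkS4class{LabelMap}; values outside \{0,1,2,3\} raise a
#'   validation error naming the offending values.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- niftiToInternal(RNifti::readNifti(path))
  lab <- v$voxels
  if (any(abs(lab - round(lab)) > 1e-6))
    stop("label file contains non-integer values: ", path)
  LabelMap(round(lab), v$spacing)
}

internalToNifti <- function(voxels, spacing, datatype) {
  arr <- aperm(voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing)
  attr(img, ".datatype") <- datatype
  img
}

#' Write a VolumeImage to NIfTI
#'
#' Stored as float64 so that write/read round-trips are exact.
#'
#' @param volume a \linkS4class{VolumeImage}
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeImage"))
  img <- internalToNifti(volume@voxels, volume@spacing, "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a LabelMap to NIfTI
#'
#' Stored with an integer datatype; spacing is preserved in the header so
#' that volumes computed downstream agree.
#'
#' @param labelmap a \linkS4class{LabelMap}
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeLabelMap <- function(labelmap, path) {
  stopifnot(is(labelmap, "LabelMap"))
  img <- internalToNifti(labelmap@labels, labelmap@spacing, "int16")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a subject study (ED and ES frames, optional labels)
#'
#' @param imagePaths named list/vector with elements \code{ed} and \code{es}
#' @param labelPaths optional named list/vector; either element may be NA or
#'   missing for unlabeled frames
#' @param subjectId identifier; defaults to the ED file name
#' @param labelFlags per-frame, per-structure availability (see
#'   \linkS4class{SubjectStudy}); defaults to full availability for frames
#'   with a label file
#' @return a \linkS4class{SubjectStudy}. Mismatched image/label grids raise a
#'   structural error naming both shapes.
#' @export
readStudy <- function(imagePaths, labelPaths = NULL, subjectId = NULL,
                      labelFlags = NULL) {
  imagePaths <- as.list(imagePaths)
  stopifnot(all(c("ed", "es") %in% names(imagePaths)))
  ed <- readVolume(imagePaths$ed)
  es <- readVolume(imagePaths$es)
  getLab <- function(frame, img) {
    p <- labelPaths[[frame]]
    if (is.null(p) || is.na(p)) return(NULL)
    lab <- readLabelMap(p)
    if (!identical(dim(lab@labels), dim(img@voxels)))
      stop(sprintf("%s label shape (%s) does not match image shape (%s)",
                   toupper(frame), paste(dim(lab@labels), collapse = "x"),
                   paste(dim(img@voxels), collapse = "x")))
    lab
  }
  labelPaths <- as.list(labelPaths)
  edLab <- getLab("ed", ed)
  esLab <- getLab("es", es)
  if (is.null(subjectId)) subjectId <- sub("\\.nii(\\.gz)?$", "", basename(imagePaths$ed))
  if (is.null(labelFlags)) labelFlags <- defaultFlags(edLab, esLab)
  SubjectStudy(subjectId, ed, es, edLab, esLab, labelFlags)
}
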