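#' @include cmrseg-package.R
NULL

#' VolumeImage: a 3D stack of scalar intensities with physical spacing
#'
#' The unit of image I/O and geometry. Voxels are indexed (slice z, row y,
#' col x) and spacing is given voxel-center-to-center in mm as
#' \code{(sz, sy, sx)}.
#'
#' @slot voxels rank-3 numeric array, dim (Z, Y, X)
#' @slot spacing numeric length-3, mm per voxel along (z, y, x), all > 0
#' @exportClass VolumeImage
setClass("VolumeImage",
  representation(voxels = "array", spacing = "numeric"))

setValidity("VolumeImage", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "voxels must be a rank-3 array with all dimensions >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 finite positive values (sz, sy, sx) in mm")
  if (any(!is.finite(object@voxels)))
    msg <- c(msg, "voxel intensities must be finite (no NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeImage
#'
#' @param voxels rank-3 numeric array indexed (z, y, x)
#' @param spacing numeric length-3 spacing (sz, sy, sx) in mm
#' @return a \linkS4class{VolumeImage}
#' @export
VolumeImage <- function(voxels, spacing) {
  new("VolumeImage", voxels = voxels, spacing = as.numeric(spacing))
}

#' LabelMap: an integer class map on the same grid as a VolumeImage
#'
#' Class codes: 0 background, 1 LV cavity, 2 myocardium, 3 RV cavity.
#'
#' @slot labels rank-3 integer array, dim (Z, Y, X), values in {0, 1, 2, 3}
#' @slot spacing numeric length-3 spacing (sz, sy, sx) in mm
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "array", spacing = "numeric"))

setValidity("LabelMap", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "labels must be a rank-3 array with all dimensions >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 finite positive values (sz, sy, sx) in mm")
  bad <- setdiff(unique(as.vector(object@labels)), CLASS_CODES)
  if (length(bad))
    msg <- c(msg, sprintf("label values outside {0,1,2,3}: %s",
                          paste(sort(bad), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#'
#' @param labels rank-3 array of integer class codes in {0, 1, 2, 3}
#' @param spacing numeric length-3 spacing (sz, sy, sx) in mm
#' @return a \linkS4class{LabelMap}
#' @export
LabelMap <- function(labels, spacing) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, spacing = as.numeric(spacing))
}

setClassUnion("LabelMapOrNULL", c("LabelMap", "NULL"))

#' SubjectStudy: paired end-diastolic and end-systolic frames
#'
#' The unit of inference and clinical evaluation. Labels are optional and may
#' be partial: \code{labelFlags} records, per frame and structure, whether a
#' manual annotation exists (partially labeled cohorts annotate e.g. only the
#' LV at ED and ES plus the myocardium at ED).
#'
#' @slot subjectId character identifier
#' @slot edImage,esImage \linkS4class{VolumeImage} frames
#' @slot edLabel,esLabel \linkS4class{LabelMap} or NULL
#' @slot labelFlags list with logical vectors \code{ed} and \code{es}, each
#'   named (LV, MYO, RV)
#' @exportClass SubjectStudy
setClass("SubjectStudy",
  representation(subjectId = "character",
                 edImage = "VolumeImage", esImage = "VolumeImage",
                 edLabel = "LabelMapOrNULL", esLabel = "LabelMapOrNULL",
                 labelFlags = "list"))

setValidity("SubjectStudy", function(object) {
  msg <- character()
  chk <- function(img, lab, frame) {
    if (is.null(lab)) return(character())
    if (!identical(dim(img@voxels), dim(lab@labels)))
      return(sprintf("%s label grid (%s) does not match image grid (%s)",
                     frame, paste(dim(lab@labels), collapse = "x"),
                     paste(dim(img@voxels), collapse = "x")))
    if (!isTRUE(all.equal(img@spacing, lab@spacing)))
      return(sprintf("%s label spacing differs from image spacing", frame))
    character()
  }
  msg <- c(msg, chk(object@edImage, object@edLabel, "ED"),
           chk(object@esImage, object@esLabel, "ES"))
  fl <- object@labelFlags
  if (!all(c("ed", "es") %in% names(fl)))
    msg <- c(msg, "labelFlags must have elements 'ed' and 'es'")
  if (length(msg)) msg else TRUE
})

defaultFlags <- function(edLabel, esLabel) {
  list(ed = stats::setNames(rep(!is.null(edLabel), 3L), names(STRUCTURES)),
       es = stats::setNames(rep(!is.null(esLabel), 3L), names(STRUCTURES)))
}

#' Construct a SubjectStudy
#'
#' @param subjectId character identifier
#' @param edImage,esImage \linkS4class{VolumeImage} frames
#' @param edLabel,esLabel optional \linkS4class{LabelMap}s
#' @param labelFlags per-frame, per-structure availability of manual labels;
#'   defaults to all structures available whenever the frame has a label map
#' @return a \linkS4class{SubjectStudy}
#' @export
SubjectStudy <- function(subjectId, edImage, esImage,
                         edLabel = NULL, esLabel = NULL,
                         labelFlags = defaultFlags(edLabel, esLabel)) {
  new("SubjectStudy", subjectId = subjectId, edImage = edImage,
      esImage = esImage, edLabel = edLabel, esLabel = esLabel,
      labelFlags = labelFlags)
}

#' GeometryRecord: the invertible record of preprocessing geometry
#'
#' Records everything needed to map network outputs on the fixed-size network
#' grid back onto the original scanner grid: original shape and spacing, the
#' resampled in-plane shape, and the crop/pad offsets. Cropping and padding
#' amounts are kept separately per axis so that the inverse is exact by
#' construction.
#'
#' @slot originalShape integer (Z, Y, X)
#' @slot originalSpacing numeric (sz, sy, sx) mm
#' @slot resampledShape integer in-plane shape (Y', X') after resampling
#' @slot targetSpacing numeric in-plane target spacing (ty, tx) mm
#' @slot resampleEnabled logical
#' @slot cropOffset integer (dy, dx): rows/cols removed before the window
#' @slot padBefore integer (py, px): zero rows/cols added before the content
#' @slot targetSize integer (H, W) network grid
#' @exportClass GeometryRecord
setClass("GeometryRecord",
  representation(originalShape = "integer", originalSpacing = "numeric",
                 resampledShape = "integer", targetSpacing = "numeric",
                 resampleEnabled = "logical", cropOffset = "integer",
                 padBefore = "integer", targetSize = "integer"))

setValidity("GeometryRecord", function(object) {
  msg <- character()
  if (length(object@originalShape) != 3L) msg <- c(msg, "originalShape must be (Z, Y, X)")
  if (length(object@targetSize) != 2L || any(object@targetSize < 1L))
    msg <- c(msg, "targetSize must be two positive integers")
  if (any(object@cropOffset < 0L) || any(object@padBefore < 0L))
    msg <- c(msg, "cropOffset and padBefore must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---- generics & accessors ---------------------------------------------------

#' @rdname VolumeImage-class
#' @param object,x a VolumeImage / LabelMap / SubjectStudy
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname VolumeImage-class
#' @export
setMethod("voxels", "VolumeImage", function(x) x@voxels)

#' @rdname LabelMap-class
#' @param x a LabelMap
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname LabelMap-class
#' @export
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname VolumeImage-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname VolumeImage-class
#' @export
setMethod("spacing", "VolumeImage", function(x) x@spacing)
#' @rdname LabelMap-class
#' @export
setMethod("spacing", "LabelMap", function(x) x@spacing)

#' @rdname SubjectStudy-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname SubjectStudy-class
#' @export
setMethod("subjectId", "SubjectStudy", function(x) x@subjectId)
#' @rdname SubjectStudy-class
#' @export
setGeneric("edImage", function(x) standardGeneric("edImage"))
#' @rdname SubjectStudy-class
#' @export
setMethod("edImage", "SubjectStudy", function(x) x@edImage)
#' @rdname SubjectStudy-class
#' @export
setGeneric("esImage", function(x) standardGeneric("esImage"))
#' @rdname SubjectStudy-class
#' @export
setMethod("esImage", "SubjectStudy", function(x) x@esImage)
#' @rdname SubjectStudy-class
#' @export
setGeneric("edLabel", function(x) standardGeneric("edLabel"))
#' @rdname SubjectStudy-class
#' @export
setMethod("edLabel", "SubjectStudy", function(x) x@edLabel)
#' @rdname SubjectStudy-class
#' @export
setGeneric("esLabel", function(x) standardGeneric("esLabel"))
#' @rdname SubjectStudy-class
#' @export
setMethod("esLabel", "SubjectStudy", function(x) x@esLabel)
#' @rdname SubjectStudy-class
#' @export
setGeneric("labelFlags", function(x) standardGeneric("labelFlags"))
#' @rdname SubjectStudy-class
#' @export
setMethod("labelFlags", "SubjectStudy", function(x) x@labelFlags)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeImage: %d slices x %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = CLASS_CODES))
  cat(sprintf("LabelMap: %d slices x %d x %d, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  voxels per class BG/LV/MYO/RV: %s\n",
              paste(as.integer(tab), collapse = "/")))
})

setMethod("show", "SubjectStudy", function(object) {
  cat(sprintf("SubjectStudy '%s'\n", object@subjectId))
  cat("  ED: "); show(object@edImage)
  cat("  ES: "); show(object@esImage)
  hasLab <- function(l) if (is.null(l)) "absent" else "present"
  cat(sprintf("  labels: ED %s, ES %s\n", hasLab(object@edLabel), hasLab(object@esLabel)))
  fl <- object@labelFlags
  cat(sprintf("  available structures: ED {%s}, ES {%s}\n",
              paste(names(which(fl$ed)), collapse = ","),
              paste(names(which(fl$es)), collapse = ",")))
})

setMethod("show", "GeometryRecord", function(object) {
  cat(sprintf("GeometryRecord: original %s @ (%s) mm -> resampled %s -> %s (crop %s, pad %s)\n",
              paste(object@originalShape, collapse = "x"),
              paste(signif(object@originalSpacing, 3), collapse = ", "),
              paste(object@resampledShape, collapse = "x"),
              paste(object@targetSize, collapse = "x"),
              paste(object@cropOffset, collapse = ","),
              paste(object@padBefore, collapse = ",")))
})
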