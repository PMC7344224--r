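#' @include train.R
NULL

# preprocess one frame, run the network in evaluation mode, restore geometry
segmentFrame <- function(net, volume, preprocess) {
  pf <- preprocessFrame(volume, preprocess)
  logits <- unetForward(net, pf$x, train = FALSE)
  restorePrediction(logits, pf$geometry)
}

#' Segment a subject study
#'
#' The test-time path: each frame is resampled and centrally cropped exactly
#' as at training time, every slice is standardized and passed through the
#' network in evaluation mode (batch-norm running statistics, no dropout —
#' deterministic, and identical whether slices are batched or processed one
#' at a time), the per-class scores are restored to the original grid by
#' bilinear rescaling, and each voxel is assigned the highest-scoring class.
#'
#' @param net a trained \code{\link{buildUnet}} network
#' @param study a \linkS4class{SubjectStudy}
#' @param preprocess the \code{\link{preprocessConfig}} used at training time;
#'   its crop size must be divisible by 16
#' @return list with \code{ed} and \code{es} \linkS4class{LabelMap}s sharing
#'   shape and spacing with the input frames
#' @export
segmentStudy <- function(net, study, preprocess = preprocessConfig()) {
  stopifnot(inherits(net, "UNet"), is(study, "SubjectStudy"))
  if (any(preprocess$cropSize %% 16L != 0L))
    stop(sprintf("crop size %dx%d is incompatible with the network: must be divisible by 16",
                 preprocess$cropSize[1], preprocess$cropSize[2]))
  list(ed = segmentFrame(net, study@edImage, preprocess),
       es = segmentFrame(net, study@esImage, preprocess))
}
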