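#' @include preprocess.R
NULL

#' Training-time augmentation configuration
#'
#' Four geometric augmentations composed in a fixed order — horizontal and
#' vertical flips (each with probability 0.5), rotation, isotropic scaling,
#' random cropping — plus optional gamma contrast. Each transform can be
#' toggled independently, which is how the augmentation ablation removes one
#' operation at a time. Gamma contrast is disabled by default: it yielded
#' only minor improvements and is excluded from the standard pipeline.
#'
#' @param flip enable random horizontal and vertical flips (p = 0.5 each)
#' @param rotation enable random rotation; angle drawn uniformly from
#'   \code{rotationRange} (degrees), default \code{c(-30, 30)}
#' @param scale enable random isotropic scaling; factor drawn uniformly from
#'   \code{scaleRange}, default \code{c(0.7, 1.4)}
#' @param cropShift enable random (rather than centered) placement of the
#'   fixed-size crop window, implicitly performing random shifting
#' @param gamma enable random gamma contrast on \code{gammaRange}
#' @param rotationRange,scaleRange,gammaRange numeric length-2 ranges (lo < hi)
#' @param seed optional integer seed for standalone use; the training loop
#'   manages its own stream
#' @return an \code{AugmentConfig} list
#' @export
augmentConfig <- function(flip = TRUE, rotation = TRUE, scale = TRUE,
                          cropShift = TRUE, gamma = FALSE,
                          rotationRange = c(-30, 30),
                          scaleRange = c(0.7, 1.4),
                          gammaRange = c(0.7, 1.5),
                          seed = NULL) {
  chkRange <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop(nm, " must be an ordered range (lo < hi)")
  }
  chkRange(rotationRange, "rotationRange")
  chkRange(scaleRange, "scaleRange")
  chkRange(gammaRange, "gammaRange")
  structure(list(flip = isTRUE(flip), rotation = isTRUE(rotation),
                 scale = isTRUE(scale), cropShift = isTRUE(cropShift),
                 gamma = isTRUE(gamma), flipProb = 0.5,
                 rotationRange = as.numeric(rotationRange),
                 scaleRange = as.numeric(scaleRange),
                 gammaRange = as.numeric(gammaRange), seed = seed),
            class = "AugmentConfig")
}

#' @export
print.AugmentConfig <- function(x, ...) {
  on <- function(b) if (b) "on" else "off"
  cat(sprintf(
    "AugmentConfig: flip %s (p=%.2g), rotation %s [%g, %g] deg, scale %s [%g, %g], cropShift %s, gamma %s\n",
    on(x$flip), x$flipProb, on(x$rotation), x$rotationRange[1], x$rotationRange[2],
    on(x$scale), x$scaleRange[1], x$scaleRange[2], on(x$cropShift), on(x$gamma)))
  invisible(x)
}

#' Sample one augmentation event
#'
#' Each enabled transform's parameter is drawn uniformly from its range using
#' the current R random stream; disabled transforms yield identity
#' parameters. The crop offset is drawn over all positions where the crop
#' window fits inside the (scaled) canvas; with \code{cropShift} disabled, or
#' when the canvas is not larger than the window, the window is centered.
#'
#' @param config an \code{\link{augmentConfig}}
#' @param inputShape in-plane shape (Y, X) the draw will be applied to
#' @param cropSize crop window (H, W)
#' @return an \code{AugmentationDraw} list: \code{flipH}, \code{flipV},
#'   \code{angle} (deg), \code{scale}, \code{cropOffset} (dy, dx; amount
#'   skipped before the window on the possibly padded canvas) and
#'   \code{gamma} (NA when disabled)
#' @export
drawAugmentation <- function(config, inputShape = c(256L, 256L),
                             cropSize = c(256L, 256L)) {
  stopifnot(inherits(config, "AugmentConfig"))
  flipH <- config$flip && (runif(1) < config$flipProb)
  flipV <- config$flip && (runif(1) < config$flipProb)
  angle <- if (config$rotation)
    runif(1, config$rotationRange[1], config$rotationRange[2]) else 0
  sc <- if (config$scale) runif(1, config$scaleRange[1], config$scaleRange[2]) else 1
  gam <- if (config$gamma) runif(1, config$gammaRange[1], config$gammaRange[2]) else NA_real_
  canvas <- pmax(as.integer(roundHalfUp(sc * inputShape)), 1L)
  off <- integer(2L)
  for (a in 1:2) {
    slack <- canvas[a] - cropSize[a]
    off[a] <- if (slack > 0L) {
      if (config$cropShift) as.integer(floor(runif(1) * (slack + 1L))) else slack %/% 2L
    } else 0L
  }
  list(flipH = flipH, flipV = flipV, angle = angle, scale = sc,
       cropOffset = off, gamma = gam,
       canvasShape = canvas, inputShape = as.integer(inputShape))
}

identityDraw <- function(inputShape = c(256L, 256L), cropSize = c(256L, 256L)) {
  canvas <- as.integer(inputShape)
  off <- pmax((canvas - as.integer(cropSize)) %/% 2L, 0L)
  list(flipH = FALSE, flipV = FALSE, angle = 0, scale = 1,
       cropOffset = off, gamma = NA_real_,
       canvasShape = canvas, inputShape = canvas)
}

warpRotScale <- function(sl, angleDeg, scale, canvasYX, bilinear) {
  d <- dim(sl)
  th <- angleDeg * pi / 180
  a <- cos(th) / scale; b <- sin(th) / scale
  cin <- (d - 1) / 2
  cout <- (canvasYX - 1) / 2
  # inverse map: src = R(-theta)/s * (out - cout) + cin
  coef <- c(a, b, cin[1] - a * cout[1] - b * cout[2],
            -b, a, cin[2] + b * cout[1] - a * cout[2])
  cpp_warp_affine(sl, canvasYX[1], canvasYX[2], coef, bilinear, 0)
}

cropAt <- function(sl, off, cropYX, fill = 0) {
  d <- dim(sl)
  out <- array(fill, dim = cropYX)
  # pad symmetrically where the canvas is smaller than the window
  pad <- pmax((cropYX - d) %/% 2L, 0L)
  ny <- min(d[1], cropYX[1]); nx <- min(d[2], cropYX[2])
  out[pad[1] + seq_len(ny), pad[2] + seq_len(nx)] <-
    sl[off[1] + seq_len(ny), off[2] + seq_len(nx)]
  out
}

#' Apply one augmentation draw to an image/label slice pair
#'
#' Transform order: flips, then rotation and scaling about the image center
#' (one combined warp; bilinear for the image, nearest-neighbor for the
#' label, zero fill outside), then gamma contrast on the image if drawn, then
#' the crop to \code{cropSize}. An identity draw on an input already at
#' \code{cropSize} returns the pair bit-exactly.
#'
#' @param imageSlice,labelSlice matrices on a shared grid (label may be NULL)
#' @param draw an \code{\link{drawAugmentation}} result
#' @param cropSize output size (H, W)
#' @return list with \code{image} and \code{label}, both exactly
#'   \code{cropSize}; label values stay in \{0,1,2,3\}
#' @export
applyAugmentation <- function(imageSlice, labelSlice, draw,
                              cropSize = c(256L, 256L)) {
  cropSize <- as.integer(cropSize)
  if (!is.null(labelSlice) && !identical(dim(imageSlice), dim(labelSlice)))
    stop("image and label slices must share a grid")
  img <- imageSlice; lab <- labelSlice
  if (draw$flipH) { img <- img[, rev(seq_len(ncol(img)))]; if (!is.null(lab)) lab <- lab[, rev(seq_len(ncol(lab)))] }
  if (draw$flipV) { img <- img[rev(seq_len(nrow(img))), ]; if (!is.null(lab)) lab <- lab[rev(seq_len(nrow(lab))), ] }
  if (draw$angle != 0 || draw$scale != 1) {
    canvas <- draw$canvasShape
    img <- warpRotScale(img, draw$angle, draw$scale, canvas, TRUE)
    if (!is.null(lab))
      lab <- array(as.integer(warpRotScale(lab + 0.0, draw$angle, draw$scale,
                                           canvas, FALSE)), dim = canvas)
  }
  if (!is.na(draw$gamma)) {
    rng <- range(img)
    if (rng[2] > rng[1])
      img <- rng[1] + (rng[2] - rng[1]) *
        gammaContrast((img - rng[1]) / (rng[2] - rng[1]), draw$gamma)
  }
  img <- cropAt(img, draw$cropOffset, cropSize)
  if (!is.null(lab))
    lab <- array(as.integer(cropAt(lab, draw$cropOffset, cropSize, 0L)), dim = cropSize)
  list(image = img, label = lab)
}

#' Gamma contrast transform
#'
#' Monotone intensity map \eqn{x \mapsto x^\gamma} on intensities rescaled to
#' [0, 1]; preserves the rank order of pixel intensities for any
#' \eqn{\gamma > 0}.
#'
#' @param imageSlice numeric matrix with values in [0, 1]
#' @param gamma positive exponent
#' @return transformed matrix
#' @export
gammaContrast <- function(imageSlice, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  imageSlice^gamma
}
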