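#' @include nnet-ops.R augment.R
NULL

#' Training configuration
#'
#' Defaults follow the full-scale protocol: random batches of 20 2D
#' short-axis slices, SGD with initial learning rate 0.001 halved every 50
#' epochs, pixelwise cross-entropy over the 4 classes.
#'
#' @param batchSize slices per iteration (default 20)
#' @param lr initial learning rate (default 0.001)
#' @param lrDecay multiplicative decay factor (default 0.5)
#' @param lrStep epochs between decays (default 50)
#' @param epochs number of epochs
#' @param momentum SGD momentum in [0, 1); 0 (plain SGD) by default.
#'   Reduced-scale runs with few iterations benefit from heavy-ball momentum
#' @param patience stop early when the validation mean IoU has not improved
#'   by more than \code{minDelta} for this many epochs; \code{Inf} (default)
#'   trains for the full epoch budget
#' @param minDelta minimum validation improvement that resets the patience
#'   counter
#' @param seed integer seed controlling shuffling, augmentation draws and
#'   dropout
#' @return a \code{TrainConfig} list
#' @export
trainConfig <- function(batchSize = 20L, lr = 0.001, lrDecay = 0.5,
                        lrStep = 50L, epochs = 10L, momentum = 0,
                        patience = Inf, minDelta = 0.005, seed = 1L) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(batchSize = as.integer(batchSize), lr = lr,
                 lrDecay = lrDecay, lrStep = as.integer(lrStep),
                 epochs = as.integer(epochs), momentum = momentum,
                 patience = patience, minDelta = minDelta,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given (1-based) epoch under the step schedule
#' @param epoch epoch number, starting at 1
#' @param config a \code{\link{trainConfig}}
#' @return the learning rate
#' @export
learningRateAt <- function(epoch, config) {
  config$lr * config$lrDecay^(epoch %/% config$lrStep)
}

#' Mean intersection-over-union between label batches
#'
#' Per-class IoU (|A\eqn{\cap}B| / |A\eqn{\cup}B|) is accumulated over the
#' whole batch for each of the 4 classes, then averaged over the classes
#' whose union is non-empty; classes absent from both prediction and
#' reference do not enter the mean.
#'
#' @param pred,ref integer arrays (any matching shape) or
#'   \linkS4class{LabelMap}s with values in \{0,1,2,3\}
#' @return mean IoU in [0, 1]
#' @export
meanIoU <- function(pred, ref) {
  if (is(pred, "LabelMap")) pred <- pred@labels
  if (is(ref, "LabelMap")) ref <- ref@labels
  if (!identical(dim(pred), dim(ref)))
    stop(sprintf("shape mismatch: prediction %s vs reference %s",
                 paste(dim(pred), collapse = "x"), paste(dim(ref), collapse = "x")))
  ious <- vapply(CLASS_CODES, function(k) {
    a <- pred == k; b <- ref == k
    u <- sum(a | b)
    if (u == 0) NA_real_ else sum(a & b) / u
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

# flatten labeled frames of a study list into per-slice (image, label) pairs
# at the network-ready spacing (resampled once; crop/augment happen per draw)
sliceDataset <- function(studies, preprocessConfig) {
  out <- list()
  for (st in studies) {
    for (frame in c("ed", "es")) {
      img <- if (frame == "ed") st@edImage else st@esImage
      lab <- if (frame == "ed") st@edLabel else st@esLabel
      if (is.null(lab)) next
      if (preprocessConfig$resample) {
        img <- resampleInPlane(img, preprocessConfig$targetSpacing)$result
        lab <- resampleInPlane(lab, preprocessConfig$targetSpacing)$result
      }
      v <- img@voxels; l <- lab@labels; d <- dim(v)
      for (z in seq_len(d[1])) {
        im2 <- v[z, , ]; dim(im2) <- d[2:3]
        lb2 <- l[z, , ]; dim(lb2) <- d[2:3]
        out[[length(out) + 1L]] <- list(image = im2, label = lb2)
      }
    }
  }
  out
}

augmentedBatch <- function(slices, idx, augConfig, cropSize) {
  B <- length(idx)
  x <- array(0, dim = c(cropSize, 1L, B))
  y <- array(0L, dim = c(cropSize, B))
  anyAug <- !is.null(augConfig) &&
    (augConfig$flip || augConfig$rotation || augConfig$scale ||
     augConfig$cropShift || augConfig$gamma)
  for (b in seq_len(B)) {
    sl <- slices[[idx[b]]]
    draw <- if (anyAug) drawAugmentation(augConfig, dim(sl$image), cropSize)
            else identityDraw(dim(sl$image), cropSize)
    aug <- applyAugmentation(sl$image, sl$label, draw, cropSize)
    x[, , 1L, b] <- normalizeIntensity(aug$image)
    y[, , b] <- aug$label
  }
  list(x = x, y = y)
}

# per-class intersection/union accumulator -> batch mean IoU
iouAccumulate <- function(acc, pred, ref) {
  for (k in CLASS_CODES) {
    a <- pred == k; b <- ref == k
    acc$inter[k + 1L] <- acc$inter[k + 1L] + sum(a & b)
    acc$union[k + 1L] <- acc$union[k + 1L] + sum(a | b)
  }
  acc
}

iouFinalize <- function(acc) {
  keep <- acc$union > 0
  mean(acc$inter[keep] / acc$union[keep])
}

argmaxLabels <- function(logits) {
  d <- dim(logits)
  out <- array(0L, dim = d[c(1, 2, 4)])
  for (n in seq_len(d[4])) {
    sm <- matrix(logits[, , , n], d[1] * d[2], d[3])
    out[, , n] <- max.col(sm, ties.method = "first") - 1L
  }
  out
}

#' Train a U-Net with mean-IoU model selection
#'
#' Each epoch iterates over all 2D slices of all labeled training frames in
#' shuffled order, in batches of \code{batchSize} augmented slices, and
#' minimizes pixelwise cross-entropy by SGD under the step learning-rate
#' schedule. After every epoch, mean IoU is computed on the validation
#' slices, augmented with the same strategy as training but from a fixed
#' seed so the selection signal is comparable across epochs; the snapshot
#' with the highest validation mean IoU is returned (ties go to the earliest
#' epoch, acting as earlier stopping).
#'
#' @param net a \code{\link{buildUnet}} network
#' @param trainStudies,valStudies non-empty lists of \linkS4class{SubjectStudy}
#'   with labels
#' @param config a \code{\link{trainConfig}}
#' @param preprocess a \code{\link{preprocessConfig}}
#' @param augment an \code{\link{augmentConfig}} or NULL for none
#' @param verbose print one line per epoch (epoch, lr, loss, val mIoU)
#' @return list with \code{net} (best snapshot), \code{history} data frame
#'   (epoch, lr, loss, val_miou) and \code{bestEpoch}
#' @export
trainModel <- function(net, trainStudies, valStudies, config = trainConfig(),
                       preprocess = preprocessConfig(),
                       augment = augmentConfig(), verbose = FALSE) {
  if (length(trainStudies) == 0L) stop("empty training set")
  if (length(valStudies) == 0L) stop("empty validation set")
  trainSlices <- sliceDataset(trainStudies, preprocess)
  valSlices <- sliceDataset(valStudies, preprocess)
  if (length(trainSlices) == 0L) stop("training studies contain no labeled frames")
  if (length(valSlices) == 0L) stop("validation studies contain no labeled frames")
  cropSize <- preprocess$cropSize
  set.seed(config$seed)
  nTr <- length(trainSlices)
  bestIoU <- -Inf; bestEpoch <- NA_integer_; bestParams <- NULL
  vel <- NULL
  lastImprove <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     val_miou = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- learningRateAt(epoch, config)
    ord <- sample.int(nTr)
    nIter <- ceiling(nTr / config$batchSize)
    epochLoss <- 0
    for (it in seq_len(nIter)) {
      idx <- ord[((it - 1L) * config$batchSize + 1L):min(it * config$batchSize, nTr)]
      bt <- augmentedBatch(trainSlices, idx, augment, cropSize)
      fw <- unetForward(net, bt$x, train = TRUE)
      net <- fw$net
      ce <- softmaxCrossEntropy(fw$logits, bt$y)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d, iteration %d", epoch, it))
      grads <- unetBackward(net, fw$cache, ce$dlogits)
      upd <- sgdStep(net$params, grads, lr, config$momentum, vel)
      net$params <- upd$params
      vel <- upd$vel
      epochLoss <- epochLoss + ce$loss * length(idx)
    }
    epochLoss <- epochLoss / nTr
    # validation under a fixed augmentation seed, isolated from the training
    # stream so it does not perturb the shuffle/dropout sequence
    rngState <- get(".Random.seed", envir = globalenv())
    set.seed(config$seed + 997L)
    acc <- list(inter = numeric(4), union = numeric(4))
    nVal <- length(valSlices)
    vIter <- ceiling(nVal / config$batchSize)
    for (it in seq_len(vIter)) {
      idx <- (((it - 1L) * config$batchSize + 1L):min(it * config$batchSize, nVal))
      bt <- augmentedBatch(valSlices, idx, augment, cropSize)
      logits <- unetForward(net, bt$x, train = FALSE)
      acc <- iouAccumulate(acc, argmaxLabels(logits), bt$y)
    }
    assign(".Random.seed", rngState, envir = globalenv())
    valIoU <- iouFinalize(acc)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr, loss = epochLoss,
                                   val_miou = valIoU))
    if (verbose)
      message(sprintf("epoch %3d  lr %.5g  loss %.4f  val_mIoU %.4f",
                      epoch, lr, epochLoss, valIoU))
    if (valIoU > bestIoU + config$minDelta) lastImprove <- epoch
    if (valIoU > bestIoU) {
      bestIoU <- valIoU; bestEpoch <- epoch; bestParams <- net$params
    }
    if (epoch - max(lastImprove, 1L) >= config$patience) break
  }
  best <- net
  best$params <- bestParams
  list(net = best, history = hist, bestEpoch = bestEpoch)
}
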