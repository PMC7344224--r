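#' @include unet.R
NULL

# internal layer helpers for the U-Net forward/backward passes; all heavy
# kernels (im2col convolutions, fused BN+ReLU, pooling, upsampling, dropout,
# cross-entropy) live in src/kernels.cpp

BN_MOMENTUM <- 0.1

# one conv3x3 -> BN -> ReLU block; training caches the im2col matrices so
# the backward pass reuses them
blockForward <- function(x, w, bn, train) {
  if (train) {
    fc <- cpp_conv3x3_forward_cache(x, w)
    f <- cpp_bn_relu_train(fc$y, bn$gamma, bn$beta)
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * f$mean
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * f$var
    list(y = f$y, col = fc$col, conv = fc$y, mean = f$mean,
         invstd = f$invstd, bn = bn)
  } else {
    cv <- cpp_conv3x3_forward(x, w)
    list(y = cpp_bn_relu_eval(cv, bn$gamma, bn$beta, bn$rmean, bn$rvar), bn = bn)
  }
}

blockBackward <- function(cache, w, bn, dy, computeDx = TRUE) {
  bb <- cpp_bn_relu_backward(cache$conv, cache$y, dy, bn$gamma,
                             cache$mean, cache$invstd)
  cb <- cpp_conv3x3_backward_cached(cache$col, w, bb$dx, computeDx)
  list(dx = cb$dx, dw = cb$dw, dgamma = bb$dgamma, dbeta = bb$dbeta)
}

#' Forward pass of the U-Net
#'
#' @param net a \code{\link{buildUnet}} network
#' @param x input array (H, W, inChannels, N); H and W must be divisible by
#'   16 (four 2x2 poolings)
#' @param train logical; TRUE enables batch statistics, dropout (drawn from
#'   the current R random stream) and caching for backprop. FALSE uses the
#'   running batch-norm statistics and no dropout, so repeated calls are
#'   bit-identical and slice batching does not change results.
#' @return for \code{train = FALSE}, the logits array (H, W, 4, N); for
#'   \code{train = TRUE}, a list with \code{logits}, \code{cache} and the
#'   updated \code{net} (running statistics)
#' @export
unetForward <- function(net, x, train = FALSE) {
  stopifnot(inherits(net, "UNet"))
  d <- dim(x)
  if (length(d) != 4L) stop("x must be an array (H, W, C, N)")
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop(sprintf("input size %dx%d must be divisible by 16", d[1], d[2]))
  p <- net$params
  nl <- net$config$levels
  drop <- net$config$dropout
  cache <- list()
  skips <- list()
  h <- x
  for (l in seq_len(nl)) {
    nm <- sprintf("enc%d", l)
    b1 <- blockForward(h, p[[nm]]$w1, p[[nm]]$bn1, train)
    b2 <- blockForward(b1$y, p[[nm]]$w2, p[[nm]]$bn2, train)
    if (train) {
      p[[nm]]$bn1 <- b1$bn; p[[nm]]$bn2 <- b2$bn
      cache[[nm]] <- list(b1 = b1, b2 = b2)
    }
    skips[[l]] <- b2$y
    if (l < nl) {
      mp <- cpp_maxpool2_forward(b2$y)
      h <- mp$y
      if (train) cache[[nm]]$poolIdx <- mp$idx
    } else h <- b2$y
  }
  for (s in seq_len(nl - 1L)) {
    nm <- sprintf("dec%d", s)
    up <- cpp_upsample2_forward(h)
    cat <- cpp_concat_channels(up, skips[[nl - s]])
    if (train && drop > 0) {
      dp <- cpp_dropout_forward(cat, drop)
      dropped <- dp$y
      mask <- dp$mask
    } else {
      mask <- NULL
      dropped <- cat
    }
    b1 <- blockForward(dropped, p[[nm]]$w1, p[[nm]]$bn1, train)
    b2 <- blockForward(b1$y, p[[nm]]$w2, p[[nm]]$bn2, train)
    if (train) {
      p[[nm]]$bn1 <- b1$bn; p[[nm]]$bn2 <- b2$bn
      cache[[nm]] <- list(b1 = b1, b2 = b2, mask = mask,
                          upChannels = dim(up)[3])
    }
    h <- b2$y
  }
  logits <- cpp_conv1x1_forward(h, p$head$w, p$head$b)
  if (!train) return(logits)
  cache$headIn <- h
  net$params <- p
  list(logits = logits, cache = cache, net = net)
}

# gradient of every parameter given dLoss/dLogits; mirrors unetForward
unetBackward <- function(net, cache, dlogits) {
  p <- net$params
  nl <- net$config$levels
  grads <- list()
  hb <- cpp_conv1x1_backward(cache$headIn, p$head$w, dlogits)
  grads$head <- list(w = hb$dw, b = hb$db)
  dh <- hb$dx
  dskips <- vector("list", nl)
  for (s in rev(seq_len(nl - 1L))) {
    nm <- sprintf("dec%d", s)
    cc <- cache[[nm]]
    g2 <- blockBackward(cc$b2, p[[nm]]$w2, p[[nm]]$bn2, dh)
    g1 <- blockBackward(cc$b1, p[[nm]]$w1, p[[nm]]$bn1, g2$dx)
    grads[[nm]] <- list(w1 = g1$dw, gamma1 = g1$dgamma, beta1 = g1$dbeta,
                        w2 = g2$dw, gamma2 = g2$dgamma, beta2 = g2$dbeta)
    dcat <- if (is.null(cc$mask)) g1$dx else cpp_elemwise_mul(g1$dx, cc$mask)
    sp <- cpp_split_channels(dcat, cc$upChannels)
    dskips[[nl - s]] <- sp$b
    dh <- cpp_upsample2_backward(sp$a)
  }
  for (l in rev(seq_len(nl))) {
    nm <- sprintf("enc%d", l)
    cc <- cache[[nm]]
    dr2 <- if (l == nl) dh
           else cpp_maxpool2_backward(dh, cc$poolIdx) + dskips[[l]]
    g2 <- blockBackward(cc$b2, p[[nm]]$w2, p[[nm]]$bn2, dr2)
    g1 <- blockBackward(cc$b1, p[[nm]]$w1, p[[nm]]$bn1, g2$dx, computeDx = (l > 1L))
    grads[[nm]] <- list(w1 = g1$dw, gamma1 = g1$dgamma, beta1 = g1$dbeta,
                        w2 = g2$dw, gamma2 = g2$dgamma, beta2 = g2$dbeta)
    dh <- g1$dx
  }
  grads
}

# mean pixelwise cross-entropy over 4-class logits and its gradient
softmaxCrossEntropy <- function(logits, labels) {
  storage.mode(labels) <- "integer"
  cpp_softmax_xent(logits, labels)
}

# SGD update, optionally with heavy-ball momentum: v <- mu*v + g; p <- p - lr*v
sgdStep <- function(params, grads, lr, momentum = 0, vel = NULL) {
  plain <- momentum == 0
  if (!plain && is.null(vel)) vel <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (!plain) {
      v <- vel[[nm]]
      if (is.null(v)) v <- rapply(g, function(z) z * 0, how = "replace")
      v <- mapply(function(a, b) momentum * a + b, v, g, SIMPLIFY = FALSE)
      vel[[nm]] <- v
      g <- v
    }
    if (nm == "head") {
      params$head$w <- params$head$w - lr * g$w
      params$head$b <- params$head$b - lr * g$b
    } else {
      params[[nm]]$w1 <- params[[nm]]$w1 - lr * g$w1
      params[[nm]]$w2 <- params[[nm]]$w2 - lr * g$w2
      params[[nm]]$bn1$gamma <- params[[nm]]$bn1$gamma - lr * g$gamma1
      params[[nm]]$bn1$beta <- params[[nm]]$bn1$beta - lr * g$beta1
      params[[nm]]$bn2$gamma <- params[[nm]]$bn2$gamma - lr * g$gamma2
      params[[nm]]$bn2$beta <- params[[nm]]$bn2$beta - lr * g$beta2
    }
  }
  list(params = params, vel = vel)
}
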