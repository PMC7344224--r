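#' @include cmrseg-package.R
NULL

#' U-Net configuration
#'
#' The modified 2D U-Net: five encoder levels of two 3x3 conv + batch-norm +
#' ReLU blocks with 2x2 max-pooling between levels, a decoder of four stages
#' (parameter-free bilinear 2x upsampling, skip concatenation, dropout, two
#' conv-BN-ReLU blocks), and a 1x1 convolution head to 4 class logits. With
#' base filter count f the encoder channels are (f, 2f, 4f, 8f, 8f) and the
#' decoder output channels (4f, 2f, f, f); f = 64 and f = 16 give the
#' full-width and quarter-width networks.
#'
#' @param baseFilters integer f >= 1; 64 for the full-width network, 16 for
#'   the quarter-width one
#' @param dropout dropout rate in [0, 1) applied after each of the four skip
#'   concatenations; default 0.2
#' @param inChannels input channels (1 for CMR slices)
#' @param outClasses output classes; fixed at 4 (BG, LV, MYO, RV)
#' @return a \code{UNetConfig} list with derived channel schedules
#' @export
unetConfig <- function(baseFilters = 64L, dropout = 0.2, inChannels = 1L,
                       outClasses = 4L) {
  f <- as.integer(baseFilters)
  if (is.na(f) || f < 1L) stop("baseFilters must be a positive integer")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)")
  structure(list(baseFilters = f, dropout = dropout,
                 inChannels = as.integer(inChannels),
                 outClasses = as.integer(outClasses),
                 encoderChannels = c(f, 2L * f, 4L * f, 8L * f, 8L * f),
                 decoderChannels = c(4L * f, 2L * f, f, f),
                 levels = 5L),
            class = "UNetConfig")
}

#' @export
print.UNetConfig <- function(x, ...) {
  cat(sprintf("UNetConfig: base filters %d, encoder (%s), decoder (%s), dropout %.2g\n",
              x$baseFilters, paste(x$encoderChannels, collapse = ", "),
              paste(x$decoderChannels, collapse = ", "), x$dropout))
  invisible(x)
}

#' Ordered layer description of the U-Net
#'
#' One row per layer in forward order. Convolution rows carry kernel size and
#' the derived weight-parameter count (kernel elements only: k_h x k_w x
#' c_in x c_out, excluding biases and batch-norm parameters).
#'
#' @param config a \code{\link{unetConfig}}
#' @return \code{NetworkDescription} data frame with columns \code{layer},
#'   \code{kind}, \code{c_in}, \code{c_out}, \code{k_h}, \code{k_w},
#'   \code{weights}
#' @export
unetDescription <- function(config = unetConfig()) {
  stopifnot(inherits(config, "UNetConfig"))
  enc <- config$encoderChannels
  dec <- config$decoderChannels
  rows <- list()
  add <- function(layer, kind, cin = NA_integer_, cout = NA_integer_,
                  kh = NA_integer_, kw = NA_integer_) {
    w <- if (startsWith(kind, "conv")) as.numeric(kh) * kw * cin * cout else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, kind = kind, c_in = cin, c_out = cout,
      k_h = kh, k_w = kw, weights = w, stringsAsFactors = FALSE)
  }
  cin <- config$inChannels
  for (l in seq_along(enc)) {
    add(sprintf("enc%d_conv1", l), "conv3x3", cin, enc[l], 3L, 3L)
    add(sprintf("enc%d_conv2", l), "conv3x3", enc[l], enc[l], 3L, 3L)
    cin <- enc[l]
    if (l < length(enc)) add(sprintf("pool%d", l), "maxpool2x2", cin, cin)
  }
  for (s in seq_along(dec)) {
    skip <- enc[length(enc) - s]
    add(sprintf("up%d", s), "upsample2x", cin, cin)
    add(sprintf("skip%d", s), "concat+dropout", cin + skip, cin + skip)
    add(sprintf("dec%d_conv1", s), "conv3x3", cin + skip, dec[s], 3L, 3L)
    add(sprintf("dec%d_conv2", s), "conv3x3", dec[s], dec[s], 3L, 3L)
    cin <- dec[s]
  }
  add("head", "conv1x1", cin, config$outClasses, 1L, 1L)
  desc <- do.call(rbind, rows)
  class(desc) <- c("NetworkDescription", "data.frame")
  desc
}

#' Count convolution weight parameters
#'
#' Sums k_h x k_w x c_in x c_out over every convolutional layer, excluding
#' biases and batch-norm parameters.
#'
#' @param x a \code{NetworkDescription} (from \code{\link{unetDescription}}),
#'   a \code{\link{unetConfig}}, or a built network
#' @return integer-valued numeric total
#' @export
countConvWeights <- function(x) {
  if (inherits(x, "UNetConfig")) x <- unetDescription(x)
  if (inherits(x, "UNet")) x <- x$description
  stopifnot(inherits(x, "NetworkDescription") || is.data.frame(x))
  sum(x$weights)
}

#' @export
print.NetworkDescription <- function(x, ...) {
  df <- as.data.frame(x)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("total conv weights: %s (%.3g million)\n",
              format(sum(df$weights), big.mark = ","), sum(df$weights) / 1e6))
  invisible(x)
}

heInit <- function(nIn, dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / nIn)), dim = dims)
}

newBN <- function(ch) {
  list(gamma = rep(1, ch), beta = rep(0, ch),
       rmean = rep(0, ch), rvar = rep(1, ch))
}

#' Build a trainable U-Net
#'
#' Initializes all convolution kernels with He-scaled Gaussian draws from the
#' current R random stream (seed before calling for reproducibility) and
#' batch-norm with unit scale / zero shift. Hidden convolutions carry no bias
#' (batch norm absorbs it); the 1x1 head has a bias but no batch norm and no
#' activation.
#'
#' @param config a \code{\link{unetConfig}}
#' @return a \code{UNet} object (weights, batch-norm state, description)
#' @export
buildUnet <- function(config = unetConfig()) {
  stopifnot(inherits(config, "UNetConfig"))
  enc <- config$encoderChannels
  dec <- config$decoderChannels
  params <- list()
  cin <- config$inChannels
  for (l in seq_along(enc)) {
    params[[sprintf("enc%d", l)]] <- list(
      w1 = matrix(heInit(9 * cin, c(9 * cin, enc[l])), 9 * cin, enc[l]),
      bn1 = newBN(enc[l]),
      w2 = matrix(heInit(9 * enc[l], c(9 * enc[l], enc[l])), 9 * enc[l], enc[l]),
      bn2 = newBN(enc[l]))
    cin <- enc[l]
  }
  for (s in seq_along(dec)) {
    catc <- cin + enc[length(enc) - s]
    params[[sprintf("dec%d", s)]] <- list(
      w1 = matrix(heInit(9 * catc, c(9 * catc, dec[s])), 9 * catc, dec[s]),
      bn1 = newBN(dec[s]),
      w2 = matrix(heInit(9 * dec[s], c(9 * dec[s], dec[s])), 9 * dec[s], dec[s]),
      bn2 = newBN(dec[s]))
    cin <- dec[s]
  }
  # head bias starts at class log-priors (background-dominant), the standard
  # initialization for imbalanced dense prediction: early epochs then predict
  # mostly background instead of oscillating between foreground classes
  prior <- c(0.85, rep(0.15 / (config$outClasses - 1), config$outClasses - 1))
  params$head <- list(w = matrix(heInit(cin, c(cin, config$outClasses)),
                                 cin, config$outClasses),
                      b = log(prior))
  structure(list(config = config, params = params,
                 description = unetDescription(config)),
            class = "UNet")
}

#' @export
print.UNet <- function(x, ...) {
  cat(sprintf("UNet (base filters %d): %s conv weights, input %dch -> %d classes\n",
              x$config$baseFilters,
              format(countConvWeights(x$description), big.mark = ","),
              x$config$inChannels, x$config$outClasses))
  invisible(x)
}
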