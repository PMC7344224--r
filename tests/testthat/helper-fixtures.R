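# small fixtures shared across test files; everything is generated in code

# compact phantom that fits a 48x48 crop at 1.25 mm (FOV 60 mm);
# named arguments override the compact defaults
tinyPhantomConfig <- function(...) {
  args <- list(nSlices = 4L, shape = c(48L, 48L), spacing = c(8, 1.25, 1.25),
               rBase = 12, thickness = 4, rvThickness = 5, rvAngle = 140,
               contraction = 0.65, noiseSd = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantomConfig, args)
}

tinyStudy <- function(seed = 1L, ...) generateStudy(tinyPhantomConfig(...), seed = seed)

# a binary disk mask centered in an n x n grid
diskMask <- function(n, radius, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  dy <- matrix(seq_len(n) - cy, n, n)
  dx <- matrix(seq_len(n) - cx, n, n, byrow = TRUE)
  (sqrt(dy^2 + dx^2) <= radius) + 0L
}

# memoized small trained network for inference smoke tests
.tinyNetEnv <- new.env()
getTinyTrainedNet <- function() {
  if (!is.null(.tinyNetEnv$fit)) return(.tinyNetEnv$fit)
  set.seed(314)
  cfgs <- replicate(10, tinyPhantomConfig(rBase = runif(1, 10, 13),
                                          thickness = runif(1, 4, 5.5)),
                    simplify = FALSE)
  studies <- lapply(seq_along(cfgs), function(i)
    generateStudy(cfgs[[i]], seed = 400 + i)$study)
  net <- buildUnet(unetConfig(baseFilters = 4L))
  pp <- preprocessConfig(cropSize = c(48L, 48L))
  fit <- trainModel(net, studies[1:8], studies[9:10],
                    trainConfig(batchSize = 10L, epochs = 18L, lr = 0.05,
                                momentum = 0.9, seed = 27L),
                    pp, augmentConfig())
  .tinyNetEnv$fit <- list(net = fit$net, preprocess = pp,
                          test = tinyStudy(seed = 777))
  .tinyNetEnv$fit
}
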