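test_that("mean IoU averages per-class IoU over classes present", {
  ref <- array(c(0L, 0L, 1L, 1L), c(2, 2, 1))
  pred <- array(c(0L, 1L, 1L, 1L), c(2, 2, 1))
  # BG: 1/2, LV: 2/3 -> mean 7/12
  expect_equal(meanIoU(pred, ref), 7 / 12)

  same <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
  expect_equal(meanIoU(same, same), 1)
  allBg <- array(0L, c(2, 2, 2))
  expect_equal(meanIoU(allBg, allBg), 1)  # only background contributes
  expect_error(meanIoU(array(0L, c(2, 2)), array(0L, c(3, 2))), "mismatch")
})

test_that("mean IoU matches a brute-force enumeration oracle", {
  set.seed(8)
  for (i in 1:200) {
    a <- array(sample(0:3, 27, TRUE, prob = runif(4)), c(3, 3, 3))
    b <- array(sample(0:3, 27, TRUE, prob = runif(4)), c(3, 3, 3))
    ious <- c()
    for (k in 0:3) {
      inter <- 0; uni <- 0
      for (j in 1:27) {  # explicit element loop, no vectorized set ops
        inter <- inter + (a[j] == k && b[j] == k)
        uni <- uni + (a[j] == k || b[j] == k)
      }
      if (uni > 0) ious <- c(ious, inter / uni)
    }
    expect_equal(meanIoU(a, b), mean(ious))
  }
})

test_that("the learning-rate schedule halves every 50 epochs", {
  cfg <- trainConfig(epochs = 100L)
  expect_equal(learningRateAt(49, cfg), 0.001)
  expect_equal(learningRateAt(50, cfg), 0.0005)
  expect_equal(learningRateAt(100, cfg), 0.00025)
})

test_that("training configuration rejects invalid settings", {
  expect_error(trainConfig(batchSize = 0), "batchSize")
  expect_error(trainConfig(lr = 0), "lr")
  expect_error(trainConfig(epochs = 0), "epochs")
  g <- tinyStudy(seed = 30)
  net <- buildUnet(unetConfig(4L))
  expect_error(trainModel(net, list(), list(g$study)), "empty training set")
  expect_error(trainModel(net, list(g$study), list()), "empty validation set")
})

test_that("the network overfits a single slice without augmentation", {
  cfg <- tinyPhantomConfig(nSlices = 1L)
  g <- generateStudy(cfg, seed = 55)
  set.seed(12)
  net <- buildUnet(unetConfig(baseFilters = 6L))
  pp <- preprocessConfig(cropSize = c(48L, 48L))
  tc <- trainConfig(batchSize = 2L, lr = 0.05, momentum = 0.9, epochs = 120L,
                    lrStep = 60L, seed = 3L)
  fit <- trainModel(net, list(g$study), list(g$study), tc, pp, augment = NULL)
  # 120 epochs x 2 frame-slices on the same ED/ES pair: a pure capacity check
  slices <- cmrseg:::sliceDataset(list(g$study), pp)
  bt <- cmrseg:::augmentedBatch(slices, seq_along(slices), NULL, c(48L, 48L))
  pred <- cmrseg:::argmaxLabels(unetForward(fit$net, bt$x))
  expect_gt(meanIoU(pred, bt$y), 0.95)
})

test_that("a fixed seed reproduces the loss curve exactly", {
  g1 <- tinyStudy(seed = 61); g2 <- tinyStudy(seed = 62)
  pp <- preprocessConfig(cropSize = c(48L, 48L))
  tc <- trainConfig(batchSize = 4L, lr = 0.05, epochs = 2L, seed = 17L)
  run <- function() {
    set.seed(88)
    net <- buildUnet(unetConfig(baseFilters = 2L))
    trainModel(net, list(g1$study), list(g2$study), tc, pp, augmentConfig())$history
  }
  expect_identical(run(), run())
})

test_that("the returned snapshot is the best-validation-IoU epoch", {
  g1 <- tinyStudy(seed = 63); g2 <- tinyStudy(seed = 64)
  pp <- preprocessConfig(cropSize = c(48L, 48L))
  set.seed(5)
  net <- buildUnet(unetConfig(baseFilters = 2L))
  fit <- trainModel(net, list(g1$study), list(g2$study),
                    trainConfig(batchSize = 4L, lr = 0.05, epochs = 4L, seed = 9L),
                    pp, augmentConfig())
  expect_equal(fit$history$val_miou[fit$bestEpoch], max(fit$history$val_miou))
  # ties (and the maximum) resolve to the earliest qualifying epoch
  expect_equal(fit$bestEpoch, which.max(fit$history$val_miou))
  # selection property: snapshot is at least as good as the final epoch
  expect_gte(fit$history$val_miou[fit$bestEpoch],
             fit$history$val_miou[nrow(fit$history)])
})
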