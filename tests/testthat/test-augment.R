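test_that("disabled transforms draw identity parameters", {
  cfg <- augmentConfig(flip = FALSE, rotation = FALSE, scale = FALSE,
                       cropShift = FALSE)
  set.seed(1)
  d <- drawAugmentation(cfg, c(256L, 256L), c(256L, 256L))
  expect_false(d$flipH); expect_false(d$flipV)
  expect_equal(d$angle, 0); expect_equal(d$scale, 1)
  expect_equal(d$cropOffset, c(0L, 0L))
  expect_true(is.na(d$gamma))
})

test_that("draw parameters are uniform over the configured ranges", {
  cfg <- augmentConfig()
  set.seed(42)
  draws <- replicate(10000, drawAugmentation(cfg, c(200L, 200L), c(96L, 96L)),
                     simplify = FALSE)
  ang <- vapply(draws, `[[`, numeric(1), "angle")
  sc <- vapply(draws, `[[`, numeric(1), "scale")
  fh <- vapply(draws, `[[`, logical(1), "flipH")
  expect_gte(min(ang), -30); expect_lte(max(ang), 30)
  # uniform on [-30, 30]: mean 0 with s.e. = 60/sqrt(12)/sqrt(n)
  expect_lt(abs(mean(ang)), 3 * 60 / sqrt(12) / sqrt(10000))
  expect_gte(min(sc), 0.7); expect_lte(max(sc), 1.4)
  expect_lt(abs(mean(fh) - 0.5), 3 * 0.5 / sqrt(10000))

  set.seed(7); a <- drawAugmentation(cfg, c(200L, 200L), c(96L, 96L))
  set.seed(7); b <- drawAugmentation(cfg, c(200L, 200L), c(96L, 96L))
  expect_identical(a, b)

  expect_error(augmentConfig(rotationRange = c(30, -30)), "ordered")
})

test_that("identity draws and flip involution are exact", {
  set.seed(5)
  img <- matrix(rnorm(256 * 256), 256, 256)
  lab <- matrix(sample(0:3, 256 * 256, TRUE), 256, 256)
  idd <- cmrseg:::identityDraw(c(256L, 256L), c(256L, 256L))
  out <- applyAugmentation(img, lab, idd, c(256L, 256L))
  expect_identical(out$image, img)
  expect_identical(c(out$label), c(lab))

  fl <- idd; fl$flipH <- TRUE
  once <- applyAugmentation(img, lab, fl, c(256L, 256L))
  twice <- applyAugmentation(once$image, once$label, fl, c(256L, 256L))
  expect_identical(twice$image, img)
  expect_identical(c(twice$label), c(lab))
})

test_that("rotation by +30 then -30 nearly restores a disk mask", {
  lab <- diskMask(96, 30)
  img <- lab * 100 + 50
  d1 <- cmrseg:::identityDraw(c(96L, 96L), c(96L, 96L)); d1$angle <- 30
  d2 <- d1; d2$angle <- -30
  f <- applyAugmentation(img, lab, d1, c(96L, 96L))
  b <- applyAugmentation(f$image, f$label, d2, c(96L, 96L))
  expect_gte(mean(b$label == lab), 0.95)
})

test_that("augmentation output has fixed shape and a closed label alphabet", {
  cfg <- augmentConfig(gamma = TRUE)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(60:140, 1)
    img <- matrix(runif(n * n, 0, 200), n, n)
    lab <- diskMask(n, n / 4) * sample(1:3, 1)
    d <- drawAugmentation(cfg, c(n, n), c(96L, 96L))
    out <- applyAugmentation(img, lab, d, c(96L, 96L))
    expect_equal(dim(out$image), c(96L, 96L))
    expect_equal(dim(out$label), c(96L, 96L))
    expect_true(all(out$label %in% 0:3))
  }
})

test_that("scaling changes foreground pixel count by s^2 before clipping", {
  lab <- diskMask(128, 20)
  img <- lab + 0
  for (s in c(0.7, 1.0, 1.3)) {
    d <- cmrseg:::identityDraw(c(128L, 128L), c(128L, 128L))
    d$scale <- s
    d$canvasShape <- as.integer(cmrseg:::roundHalfUp(s * c(128, 128)))
    d$cropOffset <- pmax((d$canvasShape - 128L) %/% 2L, 0L)
    out <- applyAugmentation(img, lab, d, c(128L, 128L))
    ratio <- sum(out$label == 1) / sum(lab == 1)
    expect_lt(abs(ratio - s^2) / s^2, 0.05)
  }
})

test_that("gamma contrast is the analytic monotone map", {
  expect_equal(gammaContrast(matrix(0.5, 1, 1), 2), matrix(0.25, 1, 1))
  x <- matrix(runif(64), 8, 8)
  expect_equal(gammaContrast(x, 1), x)
  for (g in c(0.4, 1.7)) {
    y <- gammaContrast(x, g)
    expect_identical(order(c(x)), order(c(y)))  # rank order preserved
  }
  expect_error(gammaContrast(x, 0), "positive")
  expect_error(gammaContrast(x, -2), "positive")
})

test_that("a fixed seed reproduces an augmented epoch bit-exactly", {
  g <- tinyStudy(seed = 21)
  slices <- cmrseg:::sliceDataset(list(g$study), preprocessConfig(cropSize = c(48, 48)))
  cfg <- augmentConfig()
  set.seed(99)
  b1 <- cmrseg:::augmentedBatch(slices, seq_along(slices), cfg, c(48L, 48L))
  set.seed(99)
  b2 <- cmrseg:::augmentedBatch(slices, seq_along(slices), cfg, c(48L, 48L))
  expect_identical(b1, b2)
})
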