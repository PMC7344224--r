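# direct (slow) bilinear resampler used as an independent oracle; same
# pixel-center convention as standard image resize, written from the formula
oracleBilinear <- function(x, ho, wo) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    for (j in seq_len(wo)) {
      fh <- (i - 0.5) * H / ho - 0.5
      fw <- (j - 0.5) * W / wo - 0.5
      h0 <- min(max(floor(fh), 0), H - 1); uh <- min(max(fh - h0, 0), 1)
      w0 <- min(max(floor(fw), 0), W - 1); uw <- min(max(fw - w0, 0), 1)
      if (h0 >= H - 1) { h0 <- max(H - 2, 0); uh <- if (H > 1) 1 else 0 }
      if (w0 >= W - 1) { w0 <- max(W - 2, 0); uw <- if (W > 1) 1 else 0 }
      h1 <- min(h0 + 1, H - 1); w1 <- min(w0 + 1, W - 1)
      out[i, j] <- (1 - uh) * (1 - uw) * x[h0 + 1, w0 + 1] +
        uh * (1 - uw) * x[h1 + 1, w0 + 1] +
        (1 - uh) * uw * x[h0 + 1, w1 + 1] + uh * uw * x[h1 + 1, w1 + 1]
    }
  }
  out
}

test_that("in-plane resampling follows the shape rule and interpolation kernels", {
  # already at target spacing: identity
  v <- VolumeImage(array(rnorm(2 * 32 * 32), c(2, 32, 32)), c(8, 1.25, 1.25))
  rs <- resampleInPlane(v, c(1.25, 1.25))
  expect_equal(voxels(rs$result), voxels(v))

  # constant 64x64 at 2.5 mm -> constant 128x128
  v2 <- VolumeImage(array(3.7, c(1, 64, 64)), c(8, 2.5, 2.5))
  rs2 <- resampleInPlane(v2, c(1.25, 1.25))
  expect_equal(dim(voxels(rs2$result)), c(1L, 128L, 128L))
  expect_true(all(abs(voxels(rs2$result) - 3.7) < 1e-12))

  # typical scanner grid: 100x100 at 1.8 mm -> 144x144, matching an independent oracle
  set.seed(2)
  sl <- matrix(rnorm(100 * 100), 100, 100)
  v3 <- VolumeImage(array(sl, c(1, 100, 100)), c(8, 1.8, 1.8))
  rs3 <- resampleInPlane(v3, c(1.25, 1.25))
  expect_equal(dim(voxels(rs3$result))[2:3], c(144L, 144L))
  got <- voxels(rs3$result)[1, , ]
  expect_equal(unname(got), oracleBilinear(sl, 144, 144), tolerance = 1e-10)

  # slice spacing is untouched; labels use nearest neighbor (alphabet intact)
  expect_equal(spacing(rs3$result)[1], 8)
  lab <- LabelMap(array(sample(0:3, 100 * 100, TRUE), c(1, 100, 100)), c(8, 1.8, 1.8))
  rl <- resampleInPlane(lab, c(1.25, 1.25))
  expect_true(all(labelArray(rl$result) %in% 0:3))
  expect_error(resampleInPlane(v, c(-1, 1)), "positive")
})

test_that("center crop/pad uses symmetric windows and records exact inverses", {
  x <- matrix(rnorm(300 * 300), 300, 300)
  cp <- centerCropOrPad(x, c(256, 256))
  expect_equal(cp$geometry$cropOffset, c(22L, 22L))
  expect_equal(cp$result, x[23:278, 23:278])

  y <- matrix(rnorm(200 * 200), 200, 200)
  cp2 <- centerCropOrPad(y, c(256, 256))
  expect_equal(cp2$geometry$padBefore, c(28L, 28L))
  expect_equal(cp2$result[29:228, 29:228], y)
  expect_true(all(cp2$result[1:28, ] == 0))

  z <- matrix(rnorm(256 * 256), 256, 256)
  cp3 <- centerCropOrPad(z, c(256, 256))
  expect_equal(cp3$result, z)
  expect_equal(cp3$geometry$cropOffset, c(0L, 0L))

  # pad-then-crop restores the original exactly (bit-exact for labels)
  lab <- LabelMap(array(sample(0:3, 4 * 60 * 80, TRUE), c(4, 60, 80)), c(8, 1, 1))
  padded <- centerCropOrPad(lab, c(96, 96))
  g <- padded$geometry
  rec <- labelArray(padded$result)[, g$padBefore[1] + 1:60, g$padBefore[2] + 1:80]
  expect_identical(rec, labelArray(lab))
})

test_that("intensity standardization is per-slice with a zero-sd guard", {
  sl <- matrix(c(1, 3), 16, 16)
  nz <- normalizeIntensity(sl)
  expect_true(all(nz %in% c(-1, 1)))

  expect_true(all(normalizeIntensity(matrix(5, 8, 8)) == 0))

  set.seed(3)
  r <- normalizeIntensity(matrix(rnorm(50 * 50, 100, 37), 50, 50))
  expect_lt(abs(mean(r)), 1e-6)
  expect_lt(abs(sqrt(mean((r - mean(r))^2)) - 1), 1e-6)
})

test_that("prediction restoration inverts the preprocessing geometry", {
  # identity geometry: plain argmax with lowest-index tie-break
  g <- tinyStudy(seed = 9)
  pf <- preprocessFrame(edImage(g$study), preprocessConfig(cropSize = c(48, 48)))
  scores <- array(0, c(48, 48, 4, 4))
  restored <- restorePrediction(scores, pf$geometry)
  expect_s4_class(restored, "LabelMap")
  expect_equal(dim(labelArray(restored)), dim(voxels(edImage(g$study))))
  expect_true(all(labelArray(restored) == 0L))  # ties resolve to background
  expect_equal(spacing(restored), spacing(edImage(g$study)))

  # one-hot ground truth restored at resample factor 1 returns the mask exactly
  lab <- edLabel(g$study)  # already at 1.25 mm in-plane
  cropped <- cmrseg:::preprocessLabelFrame(lab, preprocessConfig(cropSize = c(48, 48)))
  oneHot <- array(0, c(48, 48, 4, 4))
  for (z in 1:4) for (k in 0:3)
    oneHot[, , k + 1, z] <- (labelArray(cropped)[z, , ] == k) + 0
  back <- restorePrediction(oneHot, pf$geometry)
  expect_identical(labelArray(back), labelArray(lab))

  expect_error(restorePrediction(array(0, c(24, 24, 4, 4)), pf$geometry),
               "does not match")
})

test_that("one-hot masks survive a 2x resample round-trip on interior pixels", {
  cfg <- phantomConfig(nSlices = 1L, shape = c(64L, 64L), spacing = c(8, 2.5, 2.5),
                       rBase = 24, thickness = 8, rvThickness = 10, noiseSd = 0)
  lab <- labelArray(generateStudy(cfg, seed = 1)$study@edLabel)[1, , ]
  lm <- LabelMap(array(lab, c(1, 64, 64)), c(8, 2.5, 2.5))
  down <- resampleInPlane(resampleInPlane(lm, c(1.25, 1.25))$result, c(2.5, 2.5))$result
  agree <- mean(labelArray(down)[1, , ] == lab)
  expect_gte(agree, 0.95)
})

test_that("foreground physical area is conserved by resampling within 5%", {
  cfg <- phantomConfig(nSlices = 1L, shape = c(180L, 180L), spacing = c(8, 1.0, 1.0),
                       rBase = 24, thickness = 10, rvThickness = 12, noiseSd = 0)
  lab <- generateStudy(cfg, seed = 1)$study@edLabel
  for (target in c(1.25, 1.8, 2.3)) {
    rs <- resampleInPlane(lab, c(target, target))$result
    for (k in 1:3) {  # all structures are >= 10 mm across in this geometry
      a0 <- sum(labelArray(lab) == k) * 1.0^2
      a1 <- sum(labelArray(rs) == k) * target^2
      expect_lt(abs(a1 - a0) / a0, 0.05)
    }
  }
})

test_that("double-resampling recovers the original shape", {
  v <- VolumeImage(array(rnorm(2 * 100 * 90), c(2, 100, 90)), c(8, 1.8, 2.1))
  there <- resampleInPlane(v, c(1.25, 1.25))$result
  back <- resampleInPlane(there, c(1.8, 2.1))
  # shape recovery uses the recorded original spacing ratio
  expect_equal(dim(voxels(back$result))[2:3], c(100L, 90L))
})
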