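test_that("3D Dice matches its closed form on constructed masks", {
  a <- array(0L, c(2, 2, 2)); b <- array(0L, c(2, 2, 2))
  a[1, , ] <- 1L               # |A| = 4
  b[, 1, ] <- 1L               # |B| = 4, |A intersect B| = 2
  expect_equal(dice3d(a, b, 1), 0.5)
  expect_equal(dice3d(a, a, 1), 1)
  expect_equal(dice3d(a, b, 3), 1)     # both empty: perfect by convention
  b2 <- array(0L, c(2, 2, 2)); b2[2, , ] <- 1L
  expect_equal(dice3d(a, b2, 1), 0)    # disjoint non-empty
  expect_error(dice3d(a, array(0L, c(2, 2, 3)), 1), "mismatch")
})

test_that("3D Dice equals a voxel-set oracle on random masks", {
  set.seed(19)
  for (i in 1:300) {
    a <- array(sample(0:3, 512, TRUE, prob = runif(4)), c(8, 8, 8))
    b <- array(sample(0:3, 512, TRUE, prob = runif(4)), c(8, 8, 8))
    k <- sample(1:3, 1)
    # oracle: explicit voxel index sets
    setA <- which(a == k); setB <- which(b == k)
    expected <- if (length(setA) + length(setB) == 0) 1
                else 2 * length(intersect(setA, setB)) / (length(setA) + length(setB))
    expect_equal(dice3d(a, b, k), expected)
  }
})

test_that("clinical parameters follow the voxel-volume and density formulas", {
  sp <- c(10, 1, 1)  # 10 mm^3 per voxel
  lab <- array(0L, c(10, 10, 10))
  lab[seq_len(1000)] <- 1L  # exactly 1000 LV voxels
  ed <- LabelMap(lab, sp)
  emptyEs <- LabelMap(array(0L, c(10, 10, 10)), sp)
  cp <- clinicalParams(ed, emptyEs)
  expect_equal(cp$LV_EDV, 10)      # 1000 voxels x 10 mm^3 = 10 mL
  expect_equal(cp$LV_ESV, 0)
  expect_equal(cp$RV_EDV, 0)

  # volumes scale exactly linearly with voxel volume
  cp2 <- clinicalParams(LabelMap(lab, c(20, 1, 1)), emptyEs)
  expect_equal(cp2$LV_EDV, 2 * cp$LV_EDV)

  # myocardial mass is ED myocardial volume x 1.05 g/mL
  myo <- array(0L, c(5, 5, 5)); myo[1:50] <- 2L
  cpm <- clinicalParams(LabelMap(myo, c(2, 2, 2)))
  expect_equal(cpm$LVM, 50 * 8 / 1000 * 1.05)

  # unavailable structures are NA, never zero
  flags <- list(ed = c(LV = TRUE, MYO = TRUE, RV = FALSE),
                es = c(LV = TRUE, MYO = FALSE, RV = FALSE))
  cpp <- clinicalParams(ed, emptyEs, flags = flags)
  expect_true(is.na(cpp$RV_EDV))
  expect_true(is.na(cpp$RV_ESV))
})

test_that("Bland-Altman reproduces hand-computed agreement statistics", {
  a <- c(10, 20, 30, 40); b <- c(8, 22, 28, 42)  # differences +2,-2,+2,-2
  r <- blandAltman(a, b)
  expect_equal(r$md, 0)
  expect_equal(r$sd, sd(c(2, -2, 2, -2)))        # sample sd, ~2.309
  expect_equal(r$loa, c(-1.96, 1.96) * sd(c(2, -2, 2, -2)))
  expect_equal(r$n_removed, 0L)

  same <- c(5, 9, 13, 20)
  r2 <- blandAltman(same, same)
  expect_equal(r2$md, 0); expect_equal(r2$sd, 0); expect_equal(r2$loa, c(0, 0))

  set.seed(23)
  # inlier means are uniform on [90, 110]: the range (20) is inside the
  # 1.5 IQR fences (IQR ~10), so only the injected far pair can be removed
  m <- runif(100, 90, 110)
  d <- rnorm(100)
  auto <- c(m + d / 2, 1000)   # one pair with a far-outlying mean
  man <- c(m - d / 2, 1000 + rnorm(1))
  r3 <- blandAltman(auto, man)
  expect_equal(r3$n_removed, 1L)
  expect_equal(r3$n_used + r3$n_removed, 101L)
  expect_error(blandAltman(1:2, 2:3), "at least 3")
})

test_that("the outlier rule never widens the limits on contaminated data", {
  set.seed(29)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    auto <- rnorm(n, 100, 10); man <- auto + rnorm(n, 0, 4)
    auto <- c(auto, 100 + 50 * runif(2, 2, 4))  # inject extreme means
    man <- c(man, 500 * runif(2, 1, 2))
    with_rule <- blandAltman(auto, man)
    without <- blandAltman(auto, man, removeOutliers = FALSE)
    expect_lte(with_rule$sd, without$sd)
  }
  # with the rule disabled the result is the textbook analysis
  a <- rnorm(30); m <- rnorm(30)
  r <- blandAltman(a, m, removeOutliers = FALSE)
  expect_equal(r$md, mean(a - m))
  expect_equal(r$sd, sd(a - m))
  expect_equal(r$n_used, 30L)
})

test_that("Spearman correlation matches the closed-form rank formula", {
  expect_equal(spearmanR(1:10, (1:10)^3), 1)
  expect_equal(spearmanR(1:10, rev(1:10)), -1)
  # d^2 sum = 2 -> rho = 1 - 6*2/(5*24) = 0.9? no: pairs {1,2,3,4,5} vs {1,3,2,5,4}
  expect_equal(spearmanR(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_warning(r <- spearmanR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))

  set.seed(31)
  for (i in 1:100) {  # tie-free permutations: 1 - 6*sum(d^2)/(n(n^2-1))
    n <- sample(4:12, 1)
    x <- sample(n); y <- sample(n)
    expected <- 1 - 6 * sum((x - y)^2) / (n * (n^2 - 1))
    expect_equal(spearmanR(x, y), expected)
  }
})

test_that("dataset evaluation is exact on self-comparison and respects partial labels", {
  studies <- lapply(1:4, function(i)
    tinyStudy(seed = 100 + i, rBase = 10 + i * 0.7, contraction = 0.55 + 0.05 * i)$study)
  preds <- lapply(studies, function(st) list(ed = edLabel(st), es = esLabel(st)))
  names(preds) <- vapply(studies, subjectId, character(1))
  ev <- evaluateDataset(preds, studies)
  expect_true(all(ev$dice$dice == 1))
  expect_true(all(ev$diceSummary$mean == 1))
  expect_true(all(ev$agreement$md == 0))
  expect_true(all(ev$agreement$spearman_r == 1))

  # partially labeled references: no RV rows, no ES MYO rows, never zeros
  partial <- lapply(1:4, function(i)
    tinyStudy(seed = 200 + i, rBase = 10 + i * 0.7, partialLabels = TRUE)$study)
  predsP <- lapply(partial, function(st) list(ed = edLabel(st), es = esLabel(st)))
  names(predsP) <- vapply(partial, subjectId, character(1))
  evP <- evaluateDataset(predsP, partial)
  expect_false("RV" %in% evP$dice$structure)
  expect_false(any(evP$dice$frame == "ES" & evP$dice$structure == "MYO"))
  expect_false("RV_EDV" %in% evP$agreement$parameter)

  expect_error(evaluateDataset(list(), studies), "no overlapping")
})

test_that("mean Dice degrades monotonically with injected segmentation noise", {
  st <- tinyStudy(seed = 301)$study
  ref <- edLabel(st)
  flip <- function(lab, frac, seed) {
    set.seed(seed)
    arr <- labelArray(lab)
    idx <- sample(length(arr), round(frac * length(arr)))
    arr[idx] <- (arr[idx] + 1L) %% 4L
    LabelMap(arr, spacing(lab))
  }
  dices <- vapply(c(0, 0.05, 0.15, 0.3), function(fr) {
    noisy <- flip(ref, fr, seed = 9)
    mean(vapply(1:3, function(k) dice3d(noisy, ref, k), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dices) < 0))
})
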