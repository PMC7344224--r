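test_that("voxel-counted volumes match the closed forms within discretization", {
  cfg <- phantomConfig(nSlices = 10L, shape = c(144L, 144L),
                       spacing = c(8, 1.25, 1.25), noiseSd = 0)
  g <- generateStudy(cfg, seed = 1)
  cp <- clinicalParams(edLabel(g$study), esLabel(g$study))
  tr <- g$truth
  for (p in c("LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "LVM")) {
    expect_lt(abs(cp[[p]] - tr[[p]]) / tr[[p]], 0.05)
  }
  # the mass-density relation is exact on the analytic side
  expect_equal(tr$LVM, tr$MYO_ED * 1.05)
  # ES myocardial area conservation: LVM is frame-independent by construction
  expect_equal(tr$MYO_ED, tr$MYO_ES, tolerance = 1e-12)
})

test_that("discretization error shrinks under grid refinement", {
  errAt <- function(s, shape) {
    cfg <- phantomConfig(nSlices = 10L, shape = c(shape, shape),
                         spacing = c(8, s, s), noiseSd = 0)
    g <- generateStudy(cfg, seed = 1)
    cp <- clinicalParams(edLabel(g$study), esLabel(g$study))
    abs(cp$LV_EDV - g$truth$LV_EDV) / g$truth$LV_EDV
  }
  coarse <- errAt(2.5, 72)
  fine <- errAt(0.625, 288)
  expect_lt(fine, coarse)
  expect_lt(fine, 0.01)
})

test_that("contraction c = 1 collapses ED and ES to the same frame", {
  cfg <- tinyPhantomConfig(contraction = 1)
  g <- generateStudy(cfg, seed = 2)
  expect_identical(labelArray(edLabel(g$study)), labelArray(esLabel(g$study)))
  expect_equal(g$truth$LV_EDV, g$truth$LV_ESV)
})

test_that("noise and geometry are separated: seeds change images, not labels", {
  cfg <- tinyPhantomConfig()
  g1 <- generateStudy(cfg, seed = 10)
  g2 <- generateStudy(cfg, seed = 20)
  expect_identical(labelArray(edLabel(g1$study)), labelArray(edLabel(g2$study)))
  expect_false(identical(voxels(edImage(g1$study)), voxels(edImage(g2$study))))
})

test_that("noise-free intensities are exactly consistent with the labels", {
  cfg <- tinyPhantomConfig(noiseSd = 0)
  g <- generateStudy(cfg, seed = 3)
  img <- voxels(edImage(g$study))
  lab <- labelArray(edLabel(g$study))
  means <- cfg$intensities  # (bg, myo, blood)
  classMeans <- c(means[1], means[3], means[2], means[3])
  expect_equal(img, array(classMeans[lab + 1L], dim(lab)))
})

test_that("every ES cavity volume is below its ED counterpart when c < 1", {
  dom <- generateDomain("A", 6, seed = 77)
  for (tr in dom$truths) {
    expect_lt(tr$LV_ESV, tr$LV_EDV)
    expect_lt(tr$RV_ESV, tr$RV_EDV)
  }
})

test_that("domain draws stay inside their declared cross-site ranges", {
  set.seed(123)
  cfgs <- replicate(1000, cmrseg:::sampleDomainConfig("B"), simplify = FALSE)
  sIn <- vapply(cfgs, function(cf) cf$spacing[2], numeric(1))
  sZ <- vapply(cfgs, function(cf) cf$spacing[1], numeric(1))
  pose <- vapply(cfgs, function(cf) cf$poseAngle, numeric(1))
  rb <- vapply(cfgs, function(cf) cf$rBase, numeric(1))
  expect_true(all(sIn >= 1.0 & sIn <= 2.3))
  expect_true(all(sZ >= 5 & sZ <= 10))
  expect_true(all(abs(pose) <= 45))
  expect_true(all(rb >= 15 & rb <= 30))
  # domain A is a fixed-protocol single-scanner cohort
  set.seed(124)
  cfgA <- replicate(50, cmrseg:::sampleDomainConfig("A"), simplify = FALSE)
  expect_true(all(vapply(cfgA, function(cf) cf$spacing[2], numeric(1)) == 1.8))
  expect_true(all(vapply(cfgA, function(cf) cf$poseAngle, numeric(1)) == 0))
})

test_that("datasets are reproducible and the truth table round-trips to disk", {
  d1 <- generateDomain("A", 3, seed = 5)
  d2 <- generateDomain("A", 3, seed = 5)
  expect_identical(lapply(d1$studies, function(s) voxels(edImage(s))),
                   lapply(d2$studies, function(s) voxels(edImage(s))))
  tmp <- withr::local_tempdir()
  savePhantomDataset(d1, tmp)
  expect_true(file.exists(file.path(tmp, "truth.csv")))
  tab <- read.csv(file.path(tmp, "truth.csv"))
  expect_equal(nrow(tab), 3 * 5)
  back <- readStudy(list(ed = file.path(tmp, "a0001_ed.nii.gz"),
                         es = file.path(tmp, "a0001_es.nii.gz")),
                    list(ed = file.path(tmp, "a0001_ed_label.nii.gz")))
  expect_identical(labelArray(edLabel(back)),
                   labelArray(edLabel(d1$studies[[1]])))
})

test_that("hypertrophy-like and degenerate configurations behave as specified", {
  # thickened wall (2.5x) is a valid configuration when the cavity allows it
  cfg <- phantomConfig(rBase = 22, thickness = 2.5 * 7, rvThickness = 8,
                       shape = c(120L, 120L), spacing = c(8, 1.8, 1.8))
  g <- generateStudy(cfg, seed = 1)
  expect_s4_class(g$study, "SubjectStudy")
  expect_gt(g$truth$LVM, 0)
  # impossible geometries are rejected
  expect_error(phantomConfig(rBase = 5, thickness = 7), "rBase > thickness")
  expect_error(phantomConfig(rBase = 40, thickness = 10, rvThickness = 30,
                             shape = c(50L, 50L), spacing = c(8, 1, 1)),
               "field of view")
  expect_error(phantomConfig(contraction = 1.2), "contraction")
})

test_that("partial-label mode mirrors a partially annotated cohort", {
  g <- tinyStudy(seed = 41, partialLabels = TRUE)
  fl <- labelFlags(g$study)
  expect_equal(unname(fl$ed), c(TRUE, TRUE, FALSE))
  expect_equal(unname(fl$es), c(TRUE, FALSE, FALSE))
  expect_false(any(labelArray(edLabel(g$study)) == 3L))
  expect_true(all(labelArray(esLabel(g$study)) %in% c(0L, 1L)))
})
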