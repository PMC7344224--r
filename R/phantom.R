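#' @include evaluate.R
NULL

#' Synthetic short-axis phantom configuration
#'
#' Analytic multi-slice short-axis anatomy: per slice the LV cavity is a disk
#' whose radius tapers linearly from base to apex, the myocardium an annulus
#' of fixed thickness, and the RV cavity an annular crescent abutting the
#' epicardium over a limited angular extent. The ES frame contracts cavity
#' radii by a factor c while conserving myocardial cross-sectional area per
#' slice (wall thickening inward, an incompressibility approximation), so LV
#' mass is identical at ED and ES by construction. Intensities are class
#' means plus Gaussian noise; the label maps are the exact generating masks
#' and all volumes have closed forms, giving an exact oracle for the
#' clinical-parameter code.
#'
#' @param nSlices slices apex-to-base (default 10)
#' @param shape in-plane grid (Y, X), default 100 x 100
#' @param spacing (sz, sy, sx) mm, default (8, 1.8, 1.8)
#' @param rBase LV endocardial radius at the most basal slice, mm
#' @param apexFrac apical endocardial radius as a fraction of \code{rBase}
#' @param thickness myocardial wall thickness, mm (must be < \code{rBase})
#' @param rvThickness radial thickness of the RV crescent, mm
#' @param rvAngle angular extent of the RV crescent, degrees
#' @param contraction ED-to-ES cavity radius factor c in (0, 1]
#' @param centerOffset heart-center offset (dy, dx), mm
#' @param poseAngle in-plane pose rotation of the RV direction, degrees
#' @param intensities class mean intensities (bg, myo, blood)
#' @param noiseSd Gaussian noise standard deviation
#' @param gammaShift contrast exponent applied to the class-mean profile
#'   (1 = none); emulates cross-site contrast shifts
#' @param partialLabels if TRUE, emulate a partially annotated cohort: only
#'   LV and MYO at ED and LV at ES are labeled (flags set accordingly)
#' @return a \code{PhantomConfig} list
#' @export
phantomConfig <- function(nSlices = 10L, shape = c(100L, 100L),
                          spacing = c(8, 1.8, 1.8),
                          rBase = 24, apexFrac = 0.4, thickness = 7,
                          rvThickness = 10, rvAngle = 150,
                          contraction = 0.65, centerOffset = c(0, 0),
                          poseAngle = 0,
                          intensities = c(bg = 60, myo = 120, blood = 200),
                          noiseSd = 12, gammaShift = 1,
                          partialLabels = FALSE) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!(rBase > thickness && thickness > 0))
    stop("need rBase > thickness > 0")
  if (contraction <= 0 || contraction > 1) stop("contraction must be in (0, 1]")
  if (rvAngle <= 0 || rvAngle >= 360) stop("rvAngle must be in (0, 360) degrees")
  if (length(unique(intensities)) != 3L) stop("class intensity means must be distinct")
  extent <- rBase + thickness + rvThickness + sqrt(sum(centerOffset^2))
  fovHalf <- min(shape * spacing[2:3]) / 2
  if (extent >= fovHalf)
    stop(sprintf("heart geometry (extent %.1f mm) does not fit the field of view (half-size %.1f mm)",
                 extent, fovHalf))
  structure(list(nSlices = as.integer(nSlices), shape = as.integer(shape),
                 spacing = as.numeric(spacing), rBase = rBase,
                 apexFrac = apexFrac, thickness = thickness,
                 rvThickness = rvThickness, rvAngle = rvAngle,
                 contraction = contraction, centerOffset = as.numeric(centerOffset),
                 poseAngle = poseAngle, intensities = as.numeric(intensities),
                 noiseSd = noiseSd, gammaShift = gammaShift,
                 partialLabels = isTRUE(partialLabels)),
            class = "PhantomConfig")
}

# per-slice endocardial radii, basal slice last (z runs apex -> base)
phantomRadii <- function(config) {
  n <- config$nSlices
  if (n == 1L) return(config$rBase)
  frac <- (seq_len(n) - 1) / (n - 1)
  config$rBase * (config$apexFrac + (1 - config$apexFrac) * frac)
}

# closed-form per-frame volumes (mL) from the generating geometry
phantomAnalyticVolumes <- function(config, frame = c("ed", "es")) {
  frame <- match.arg(frame)
  r <- phantomRadii(config)
  t <- config$thickness
  w <- config$rvThickness
  th <- config$rvAngle * pi / 180
  if (frame == "es") {
    cc <- config$contraction
    rIn <- cc * r
    rOut <- sqrt(cc^2 * r^2 + 2 * r * t + t^2)  # conserves annulus area
    w <- cc * w
  } else {
    rIn <- r
    rOut <- r + t
  }
  sz <- config$spacing[1]
  list(LV = sum(pi * rIn^2) * sz / 1000,
       MYO = sum(pi * (rOut^2 - rIn^2)) * sz / 1000,
       RV = sum(th / 2 * ((rOut + w)^2 - rOut^2)) * sz / 1000)
}

phantomFrameMasks <- function(config, frame) {
  r <- phantomRadii(config)
  t <- config$thickness
  w <- config$rvThickness
  halfAng <- config$rvAngle * pi / 360
  if (frame == "es") {
    cc <- config$contraction
    rIn <- cc * r
    rOut <- sqrt(cc^2 * r^2 + 2 * r * t + t^2)
    w <- cc * w
  } else {
    rIn <- r
    rOut <- r + t
  }
  Y <- config$shape[1]; X <- config$shape[2]
  sy <- config$spacing[2]; sx <- config$spacing[3]
  cy <- (Y + 1) / 2 + config$centerOffset[1] / sy
  cx <- (X + 1) / 2 + config$centerOffset[2] / sx
  dy <- (seq_len(Y) - cy) * sy
  dx <- (seq_len(X) - cx) * sx
  DY <- matrix(dy, Y, X)
  DX <- matrix(dx, Y, X, byrow = TRUE)
  dist <- sqrt(DY^2 + DX^2)
  phi0 <- pi + config$poseAngle * pi / 180  # RV sits across the septum
  ad <- atan2(DY, DX) - phi0
  ad <- abs(((ad + pi) %% (2 * pi)) - pi)
  lab <- array(0L, dim = c(config$nSlices, Y, X))
  for (z in seq_len(config$nSlices)) {
    sl <- matrix(0L, Y, X)
    sl[dist <= rIn[z]] <- 1L
    sl[dist > rIn[z] & dist <= rOut[z]] <- 2L
    sl[dist > rOut[z] & dist <= rOut[z] + w & ad <= halfAng] <- 3L
    lab[z, , ] <- sl
  }
  lab
}

phantomIntensity <- function(labels, config) {
  means <- config$intensities  # (bg, myo, blood)
  classMeans <- c(means[1], means[3], means[2], means[3])  # BG, LV, MYO, RV
  if (config$gammaShift != 1) {
    lo <- min(classMeans); hi <- max(classMeans)
    classMeans <- lo + (hi - lo) * (((classMeans - lo) / (hi - lo))^config$gammaShift)
  }
  img <- array(classMeans[labels + 1L], dim = dim(labels))
  img + array(rnorm(length(img), sd = config$noiseSd), dim = dim(labels))
}

#' Generate one phantom study with ground truth
#'
#' Geometry (and hence the label maps and analytic volumes) depends only on
#' the configuration; the seed drives the intensity noise, so two seeds give
#' different images with identical labels.
#'
#' @param config a \code{\link{phantomConfig}}
#' @param seed integer noise seed
#' @param subjectId identifier (default derived from the seed)
#' @return list with \code{study} (a \linkS4class{SubjectStudy} with exact
#'   labels) and \code{truth} (a \code{PhantomTruth} list: analytic ED/ES
#'   volumes of LV, MYO and RV in mL, LVM in g, and the generating config)
#' @export
generateStudy <- function(config = phantomConfig(), seed = 1L,
                          subjectId = sprintf("phantom%05d", seed)) {
  stopifnot(inherits(config, "PhantomConfig"))
  set.seed(seed)
  edLab <- phantomFrameMasks(config, "ed")
  esLab <- phantomFrameMasks(config, "es")
  edImg <- phantomIntensity(edLab, config)
  esImg <- phantomIntensity(esLab, config)
  sp <- config$spacing
  edV <- phantomAnalyticVolumes(config, "ed")
  esV <- phantomAnalyticVolumes(config, "es")
  truth <- structure(list(
    LV_EDV = edV$LV, LV_ESV = esV$LV, RV_EDV = edV$RV, RV_ESV = esV$RV,
    MYO_ED = edV$MYO, MYO_ES = esV$MYO, LVM = edV$MYO * 1.05,
    config = config), class = "PhantomTruth")
  if (config$partialLabels) {
    edKeep <- edLab; edKeep[edKeep == 3L] <- 0L      # RV unannotated at ED
    esKeep <- esLab; esKeep[esKeep %in% c(2L, 3L)] <- 0L  # only LV at ES
    flags <- list(ed = c(LV = TRUE, MYO = TRUE, RV = FALSE),
                  es = c(LV = TRUE, MYO = FALSE, RV = FALSE))
    study <- SubjectStudy(subjectId, VolumeImage(edImg, sp), VolumeImage(esImg, sp),
                          LabelMap(edKeep, sp), LabelMap(esKeep, sp), flags)
  } else {
    study <- SubjectStudy(subjectId, VolumeImage(edImg, sp), VolumeImage(esImg, sp),
                          LabelMap(edLab, sp), LabelMap(esLab, sp))
  }
  list(study = study, truth = truth)
}

#' @export
print.PhantomTruth <- function(x, ...) {
  cat(sprintf("PhantomTruth: LV EDV %.1f / ESV %.1f mL, RV EDV %.1f / ESV %.1f mL, LVM %.1f g\n",
              x$LV_EDV, x$LV_ESV, x$RV_EDV, x$RV_ESV, x$LVM))
  invisible(x)
}

runifIn <- function(r) runif(1, r[1], r[2])

# domain A emulates a single-scanner cohort (fixed spacing, pose and
# contrast, anatomical variation only); domain B draws spacing, pose,
# contrast, noise and heart size from wide cross-site ranges
sampleDomainConfig <- function(domain) {
  if (domain == "A") {
    phantomConfig(
      nSlices = 10L, shape = c(100L, 100L), spacing = c(8, 1.8, 1.8),
      rBase = runifIn(c(20, 27)), apexFrac = runifIn(c(0.35, 0.45)),
      thickness = runifIn(c(6, 9)), rvThickness = runifIn(c(8, 12)),
      rvAngle = runifIn(c(130, 170)), contraction = runifIn(c(0.55, 0.75)),
      centerOffset = c(runifIn(c(-4, 4)), runifIn(c(-4, 4))),
      poseAngle = 0, intensities = c(bg = 60, myo = 120, blood = 200),
      noiseSd = 12, gammaShift = 1)
  } else if (domain == "B") {
    s <- runifIn(c(1.0, 2.3))
    fov <- 180
    phantomConfig(
      nSlices = sample(8:12, 1L), shape = rep(as.integer(round(fov / s)), 2L),
      spacing = c(runifIn(c(5, 10)), s, s),
      rBase = runifIn(c(15, 30)), apexFrac = runifIn(c(0.3, 0.5)),
      thickness = runifIn(c(5, 10)), rvThickness = runifIn(c(8, 12)),
      rvAngle = runifIn(c(120, 180)), contraction = runifIn(c(0.5, 0.8)),
      centerOffset = c(runifIn(c(-5, 5)), runifIn(c(-5, 5))),
      poseAngle = runifIn(c(-45, 45)),
      intensities = c(bg = runifIn(c(40, 80)), myo = runifIn(c(90, 150)),
                      blood = runifIn(c(160, 240))),
      noiseSd = runifIn(c(8, 20)), gammaShift = runifIn(c(0.7, 1.4)))
  } else stop("unknown domain: ", domain)
}

#' Generate a phantom dataset from a named domain
#'
#' Domain "A" emulates a homogeneous training cohort (fixed 1.8 mm in-plane
#' spacing and 8 mm slices, fixed pose and contrast, moderate noise, only
#' anatomical variation). Domain "B" emulates shifted test sites: in-plane
#' spacing drawn from 1.0-2.3 mm, slice thickness 5-10 mm, pose within
#' +/-45 degrees, altered contrast and noise, and a wider range of heart
#' sizes — the cross-site shifts the augmentation ablation probes.
#'
#' @param domain "A" or "B"
#' @param n number of subjects
#' @param seed master seed; parameter draws and per-subject noise seeds are
#'   derived from it
#' @param partialLabels generate partially annotated studies (see
#'   \code{\link{phantomConfig}})
#' @return list with \code{studies}, \code{truths} and \code{configs}
#' @export
generateDomain <- function(domain = c("A", "B"), n = 10L, seed = 1L,
                           partialLabels = FALSE) {
  domain <- match.arg(domain)
  set.seed(seed)
  configs <- lapply(seq_len(n), function(i) {
    cfg <- sampleDomainConfig(domain)
    cfg$partialLabels <- isTRUE(partialLabels)
    cfg
  })
  noiseSeeds <- (abs(seed) %% 100000L) * 10000L + seq_len(n)
  studies <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generateStudy(configs[[i]], seed = noiseSeeds[i],
                       subjectId = sprintf("%s%04d", tolower(domain), i))
    studies[[i]] <- g$study
    truths[[i]] <- g$truth
  }
  list(studies = studies, truths = truths, configs = configs)
}

#' Write a phantom dataset as NIfTI files plus a truth table
#'
#' One image/label NIfTI pair per frame per subject, and
#' \code{truth.csv} with the analytic clinical parameters.
#'
#' @param dataset a \code{\link{generateDomain}} result
#' @param outDir output directory (created if needed)
#' @return the directory, invisibly
#' @export
savePhantomDataset <- function(dataset, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_along(dataset$studies)) {
    st <- dataset$studies[[i]]
    id <- subjectId(st)
    writeVolume(edImage(st), file.path(outDir, paste0(id, "_ed.nii.gz")))
    writeVolume(esImage(st), file.path(outDir, paste0(id, "_es.nii.gz")))
    if (!is.null(edLabel(st)))
      writeLabelMap(edLabel(st), file.path(outDir, paste0(id, "_ed_label.nii.gz")))
    if (!is.null(esLabel(st)))
      writeLabelMap(esLabel(st), file.path(outDir, paste0(id, "_es_label.nii.gz")))
    tr <- dataset$truths[[i]]
    for (pn in c("LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "LVM"))
      rows[[length(rows) + 1L]] <- data.frame(subject = id, parameter = pn,
                                              value = tr[[pn]])
  }
  write.csv(do.call(rbind, rows), file.path(outDir, "truth.csv"),
            row.names = FALSE)
  invisible(outDir)
}
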