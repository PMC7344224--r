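#' @include inference.R
NULL

#' 3D Dice overlap for one structure
#'
#' Dice = 2|A intersect B| / (|A| + |B|) over the whole 3D frame for the
#' binarized structure; 1 is a perfect match, 0 no overlap. When the
#' structure is absent from both masks the score is defined as 1.
#'
#' @param auto,ref \linkS4class{LabelMap}s or integer arrays on matching grids
#' @param structure class code (1 LV, 2 MYO, 3 RV) or name "LV"/"MYO"/"RV"
#' @return Dice score in [0, 1]
#' @export
dice3d <- function(auto, ref, structure) {
  if (is(auto, "LabelMap")) auto <- auto@labels
  if (is(ref, "LabelMap")) ref <- ref@labels
  if (!identical(dim(auto), dim(ref)))
    stop(sprintf("grid mismatch: %s vs %s", paste(dim(auto), collapse = "x"),
                 paste(dim(ref), collapse = "x")))
  if (is.character(structure)) structure <- STRUCTURES[[structure]]
  a <- auto == structure
  b <- ref == structure
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Clinical parameters from ED/ES label maps
#'
#' Volumes are voxel counts times the physical voxel volume; LV mass is the
#' ED myocardial volume times a tissue density of 1.05 g/mL. Structures
#' without a reference annotation (per \code{flags}) are reported as NA, not
#' zero.
#'
#' @param edLabel,esLabel \linkS4class{LabelMap}s (either may be NULL)
#' @param flags availability list as in \linkS4class{SubjectStudy}; defaults
#'   to full availability for non-NULL frames
#' @return a \code{ClinicalParams} list: \code{LV_EDV}, \code{LV_ESV},
#'   \code{RV_EDV}, \code{RV_ESV} (mL) and \code{LVM} (g)
#' @export
clinicalParams <- function(edLabel, esLabel = NULL,
                           flags = defaultFlags(edLabel, esLabel)) {
  vol <- function(lab, structure, available) {
    if (is.null(lab) || !isTRUE(available)) return(NA_real_)
    vx <- prod(lab@spacing) / 1000  # mm^3 -> mL
    sum(lab@labels == structure) * vx
  }
  myoED <- vol(edLabel, STRUCTURES[["MYO"]], flags$ed[["MYO"]])
  structure(list(
    LV_EDV = vol(edLabel, STRUCTURES[["LV"]], flags$ed[["LV"]]),
    LV_ESV = vol(esLabel, STRUCTURES[["LV"]], flags$es[["LV"]]),
    RV_EDV = vol(edLabel, STRUCTURES[["RV"]], flags$ed[["RV"]]),
    RV_ESV = vol(esLabel, STRUCTURES[["RV"]], flags$es[["RV"]]),
    LVM = myoED * 1.05),
    class = "ClinicalParams")
}

#' @export
print.ClinicalParams <- function(x, ...) {
  cat(sprintf("ClinicalParams: LV EDV %.1f mL, LV ESV %.1f mL, RV EDV %.1f mL, RV ESV %.1f mL, LVM %.1f g\n",
              x$LV_EDV, x$LV_ESV, x$RV_EDV, x$RV_ESV, x$LVM))
  invisible(x)
}

#' Bland-Altman agreement with interquartile-range outlier removal
#'
#' For paired automatic/manual values, computes per-pair means
#' \eqn{m_i = (a_i + b_i)/2} and differences \eqn{d_i = a_i - b_i}, removes
#' pairs whose mean falls outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] of the mean
#' distribution (so the standard deviation of the differences is not biased
#' by extreme values), and reports the mean difference, its sample standard
#' deviation and the limits of agreement MD +/- 1.96 SD on the survivors.
#' Quartiles use the Hazen definition (\code{quantile} type 5).
#'
#' @param autoValues,manualValues paired numeric vectors, n >= 3
#' @param removeOutliers apply the 1.5 IQR rule (default TRUE)
#' @return an \code{AgreementResult} list: \code{md}, \code{sd}, \code{loa}
#'   (length 2), \code{n_used}, \code{n_removed}
#' @export
blandAltman <- function(autoValues, manualValues, removeOutliers = TRUE) {
  if (length(autoValues) != length(manualValues))
    stop("paired value lists must have equal length")
  ok <- is.finite(autoValues) & is.finite(manualValues)
  autoValues <- autoValues[ok]; manualValues <- manualValues[ok]
  n <- length(autoValues)
  if (n < 3L) stop("Bland-Altman analysis requires at least 3 pairs")
  m <- (autoValues + manualValues) / 2
  d <- autoValues - manualValues
  keep <- rep(TRUE, n)
  if (removeOutliers) {
    q <- stats::quantile(m, c(0.25, 0.75), type = 5, names = FALSE)
    iqr <- q[2] - q[1]
    keep <- m >= q[1] - 1.5 * iqr & m <= q[2] + 1.5 * iqr
  }
  dd <- d[keep]
  md <- mean(dd)
  s <- if (length(dd) > 1L) stats::sd(dd) else 0
  if (!is.finite(s)) s <- 0
  structure(list(md = md, sd = s, loa = c(md - 1.96 * s, md + 1.96 * s),
                 n_used = sum(keep), n_removed = sum(!keep)),
            class = "AgreementResult")
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat(sprintf("AgreementResult: MD %.3g, SD %.3g, LOA [%.3g, %.3g], n_used %d, n_removed %d\n",
              x$md, x$sd, x$loa[1], x$loa[2], x$n_used, x$n_removed))
  invisible(x)
}

#' Spearman rank correlation of paired values
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Returns NA
#' with a warning when either list is constant (undefined).
#'
#' @param autoValues,manualValues paired numeric vectors, n >= 3
#' @return rho in [-1, 1], or NA
#' @export
spearmanR <- function(autoValues, manualValues) {
  if (length(autoValues) != length(manualValues))
    stop("paired value lists must have equal length")
  ok <- is.finite(autoValues) & is.finite(manualValues)
  autoValues <- autoValues[ok]; manualValues <- manualValues[ok]
  if (length(autoValues) < 3L) stop("Spearman correlation requires at least 3 pairs")
  if (stats::sd(autoValues) == 0 || stats::sd(manualValues) == 0) {
    warning("constant value list: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(autoValues, manualValues, method = "spearman")
}

#' Evaluate predicted segmentations against references
#'
#' Per-structure 3D Dice is computed per frame (ED and ES each as a 3D
#' overlap) and pooled over frames and subjects for the mean (sd) summary.
#' The five clinical parameters (LV/RV EDV and ESV, LV mass) are compared
#' automatic-vs-manual by Bland-Altman (with the 1.5 IQR rule) and Spearman
#' correlation. Per-structure label availability is respected: a subject
#' missing a structure's annotation contributes no row for it, never a zero.
#'
#' @param predictions named list (by subject id) of \code{list(ed=, es=)}
#'   predicted \linkS4class{LabelMap}s, as returned by
#'   \code{\link{segmentStudy}}
#' @param references list of \linkS4class{SubjectStudy} with manual labels
#' @return list with \code{dice} (subject, frame, structure, dice),
#'   \code{diceSummary} (structure, mean, sd, n), \code{clinical} (per
#'   subject auto and manual parameter values), \code{agreement} (per
#'   parameter: MD, SD, LOA, n_used, n_removed, spearman_r)
#' @export
evaluateDataset <- function(predictions, references) {
  refIds <- vapply(references, subjectId, character(1))
  names(references) <- refIds
  ids <- intersect(names(predictions), refIds)
  if (length(ids) == 0L) stop("no overlapping subjects between predictions and references")
  diceRows <- list(); clinRows <- list()
  for (id in ids) {
    ref <- references[[id]]
    pred <- predictions[[id]]
    fl <- ref@labelFlags
    for (frame in c("ed", "es")) {
      refLab <- if (frame == "ed") ref@edLabel else ref@esLabel
      if (is.null(refLab)) next
      for (sn in names(STRUCTURES)) {
        if (!isTRUE(fl[[frame]][[sn]])) next
        diceRows[[length(diceRows) + 1L]] <- data.frame(
          subject = id, frame = toupper(frame), structure = sn,
          dice = dice3d(pred[[frame]], refLab, STRUCTURES[[sn]]),
          stringsAsFactors = FALSE)
      }
    }
    cpAuto <- clinicalParams(pred$ed, pred$es, flags = fl)
    cpMan <- clinicalParams(ref@edLabel, ref@esLabel, flags = fl)
    for (pn in c("LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "LVM")) {
      clinRows[[length(clinRows) + 1L]] <- data.frame(
        subject = id, parameter = pn, auto = cpAuto[[pn]], manual = cpMan[[pn]],
        stringsAsFactors = FALSE)
    }
  }
  dice <- do.call(rbind, diceRows)
  diceSummary <- do.call(rbind, lapply(split(dice, dice$structure), function(df) {
    data.frame(structure = df$structure[1], mean = mean(df$dice),
               sd = stats::sd(df$dice), n = nrow(df), stringsAsFactors = FALSE)
  }))
  rownames(diceSummary) <- NULL
  clinical <- do.call(rbind, clinRows)
  agreeRows <- list()
  for (pn in unique(clinical$parameter)) {
    df <- clinical[clinical$parameter == pn & is.finite(clinical$auto) &
                     is.finite(clinical$manual), ]
    if (nrow(df) < 3L) next
    ba <- blandAltman(df$auto, df$manual)
    r <- suppressWarnings(spearmanR(df$auto, df$manual))
    agreeRows[[length(agreeRows) + 1L]] <- data.frame(
      parameter = pn, md = ba$md, sd = ba$sd, loa_low = ba$loa[1],
      loa_high = ba$loa[2], n_used = ba$n_used, n_removed = ba$n_removed,
      spearman_r = r, stringsAsFactors = FALSE)
  }
  list(dice = dice, diceSummary = diceSummary, clinical = clinical,
       agreement = do.call(rbind, agreeRows))
}
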