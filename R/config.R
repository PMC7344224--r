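#' @include phantom.R
NULL

#' Derive a per-module seed from one master seed
#'
#' One global seed fans out to named streams (data generation, shuffling,
#' augmentation, weight initialization) through a fixed hash, so partial
#' reruns of a pipeline stay reproducible. The result is always a valid
#' 32-bit seed.
#'
#' @param master integer master seed
#' @param stream stream name, e.g. "phantom", "train", "init"
#' @return derived integer seed
#' @export
seedFor <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 100000
  as.integer((abs(as.double(master)) * 1009 + h * 97) %% 2147483647)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level blocks and keys:
#' \itemize{
#'   \item \code{preprocess}: \code{target_spacing}, \code{crop_size},
#'     \code{resample}
#'   \item \code{augment}: \code{flip}, \code{rotation}, \code{scale},
#'     \code{crop_shift}, \code{gamma}, \code{seed}
#'   \item \code{model}: \code{base_filters}, \code{dropout}
#'   \item \code{train}: \code{batch_size}, \code{lr}, \code{lr_decay},
#'     \code{lr_step}, \code{epochs}, \code{momentum}, \code{seed}
#' }
#' Missing blocks or keys fall back to the package defaults.
#'
#' @param path YAML file path
#' @return list with \code{preprocess}, \code{augment}, \code{model},
#'   \code{train} configuration objects and \code{raw}, the parsed YAML
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(block, key, default) {
    v <- raw[[block]][[key]]
    if (is.null(v)) default else v
  }
  pp <- preprocessConfig(
    targetSpacing = unlist(pick("preprocess", "target_spacing", c(1.25, 1.25))),
    cropSize = unlist(pick("preprocess", "crop_size", c(256L, 256L))),
    resample = pick("preprocess", "resample", TRUE))
  ag <- augmentConfig(
    flip = pick("augment", "flip", TRUE),
    rotation = pick("augment", "rotation", TRUE),
    scale = pick("augment", "scale", TRUE),
    cropShift = pick("augment", "crop_shift", TRUE),
    gamma = pick("augment", "gamma", FALSE),
    seed = pick("augment", "seed", NULL))
  md <- unetConfig(
    baseFilters = pick("model", "base_filters", 64L),
    dropout = pick("model", "dropout", 0.2))
  tr <- trainConfig(
    batchSize = pick("train", "batch_size", 20L),
    lr = pick("train", "lr", 0.001),
    lrDecay = pick("train", "lr_decay", 0.5),
    lrStep = pick("train", "lr_step", 50L),
    epochs = pick("train", "epochs", 10L),
    momentum = pick("train", "momentum", 0),
    seed = pick("train", "seed", 1L))
  list(preprocess = pp, augment = ag, model = md, train = tr, raw = raw)
}

ablationRowConfigs <- function(row, preprocess, augment) {
  switch(row,
    full = list(preprocess = preprocess, augment = augment),
    no_resample = {
      p <- preprocess; p$resample <- FALSE
      list(preprocess = p, augment = augment)
    },
    no_rotation = { a <- augment; a$rotation <- FALSE; list(preprocess = preprocess, augment = a) },
    no_flip = { a <- augment; a$flip <- FALSE; list(preprocess = preprocess, augment = a) },
    no_scale = { a <- augment; a$scale <- FALSE; list(preprocess = preprocess, augment = a) },
    stop("unknown ablation row: ", row))
}

#' Single-toggle augmentation/normalization ablation
#'
#' Trains one model per configuration row on domain-A phantoms — the full
#' pipeline plus rows with exactly one operation removed (resampling,
#' rotation, flips, scaling) — then evaluates every model on held-out
#' domain-A subjects and on domain-B (shifted) subjects. Emits a grid of
#' mean (sd) Dice per structure per configuration and the mean foreground
#' Dice per row and domain. A row that fails to train is marked failed and
#' the grid is still emitted.
#'
#' @param rows character vector of configuration rows, subset of
#'   \code{c("full", "no_resample", "no_rotation", "no_flip", "no_scale")}
#' @param nTrain,nVal,nTestA,nTestB dataset sizes
#' @param epochs training epoch budget per row (validation-plateau early
#'   stopping applies, see \code{\link{trainConfig}})
#' @param patience early-stopping patience per row
#' @param baseFilters,cropSize reduced-scale network and grid
#' @param lr,batchSize,momentum optimizer settings for the reduced-scale runs
#' @param seed master seed (fans out per stream via \code{\link{seedFor}})
#' @param verbose print per-epoch training lines
#' @return list with \code{grid} (row, domain, structure, mean, sd),
#'   \code{foreground} (row, domain, dice: mean over LV/MYO/RV entries),
#'   \code{failed} (character vector of failed rows)
#' @export
runAblation <- function(rows = c("full", "no_resample", "no_rotation",
                                 "no_flip", "no_scale"),
                        nTrain = 12L, nVal = 2L, nTestA = 6L, nTestB = 6L,
                        epochs = 22L, baseFilters = 8L, cropSize = c(96L, 96L),
                        lr = 0.05, batchSize = 10L, momentum = 0.9,
                        patience = 6L, seed = 1L, verbose = FALSE) {
  preprocess <- preprocessConfig(cropSize = cropSize)
  augment <- augmentConfig()
  domA <- generateDomain("A", nTrain + nVal + nTestA, seed = seedFor(seed, "phantomA"))
  domB <- generateDomain("B", nTestB, seed = seedFor(seed, "phantomB"))
  trainSet <- domA$studies[seq_len(nTrain)]
  valSet <- domA$studies[nTrain + seq_len(nVal)]
  testA <- domA$studies[nTrain + nVal + seq_len(nTestA)]
  testB <- domB$studies
  gridRows <- list(); fgRows <- list(); failed <- character()
  for (row in rows) {
    cf <- ablationRowConfigs(row, preprocess, augment)
    res <- tryCatch({
      # every row shares the same initialization and training stream so that
      # the removed operation, not seed noise, drives row differences
      set.seed(seedFor(seed, "init"))
      net <- buildUnet(unetConfig(baseFilters = baseFilters))
      tc <- trainConfig(batchSize = batchSize, lr = lr, epochs = epochs,
                        momentum = momentum, patience = patience,
                        seed = seedFor(seed, "train"))
      fit <- trainModel(net, trainSet, valSet, tc, cf$preprocess, cf$augment,
                        verbose = verbose)
      evalOn <- function(testSet) {
        preds <- lapply(testSet, function(st)
          segmentStudy(fit$net, st, cf$preprocess))
        names(preds) <- vapply(testSet, subjectId, character(1))
        evaluateDataset(preds, testSet)
      }
      list(A = evalOn(testA), B = evalOn(testB))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, row)
      warning(sprintf("ablation row '%s' failed: %s", row, conditionMessage(res)))
      next
    }
    for (dm in c("A", "B")) {
      ds <- res[[dm]]$diceSummary
      gridRows[[length(gridRows) + 1L]] <- data.frame(
        row = row, domain = dm, structure = ds$structure,
        mean = ds$mean, sd = ds$sd, stringsAsFactors = FALSE)
      fgRows[[length(fgRows) + 1L]] <- data.frame(
        row = row, domain = dm, dice = mean(res[[dm]]$dice$dice),
        stringsAsFactors = FALSE)
    }
  }
  list(grid = do.call(rbind, gridRows), foreground = do.call(rbind, fgRows),
       failed = failed)
}
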