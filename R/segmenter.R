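#' Sample segmentation patches from synthetic slides
#'
#' Draws random patch/mask pairs from a cohort for segmenter training. Each
#' sample carries the image crop, the aligned tumor-mask crop and the
#' patch-level has-tumor label used by the auxiliary head.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param n_samples number of patches to draw.
#' @param patch_px patch side (desk-scale default 128).
#' @param seed RNG seed.
#' @return list of samples \code{list(image, mask, has_tumor, slide_id)}.
#' @export
sampleSegPatches <- function(cohort, n_samples = 150L, patch_px = 128L,
                             seed = 1L) {
  .withSeed(seed, {
    out <- vector("list", n_samples)
    ns <- length(cohort$slides)
    for (i in seq_len(n_samples)) {
      b <- cohort$slides[[((i - 1L) %% ns) + 1L]]
      d <- dim(slideRaster(b$slide))
      x <- sample.int(d[1] - patch_px + 1L, 1L) - 1L
      y <- sample.int(d[2] - patch_px + 1L, 1L) - 1L
      m <- .cropMask(tumorMask(b$truth), x, y, patch_px)
      out[[i]] <- list(image = .cropPatch(slideRaster(b$slide), x, y, patch_px),
                       mask = m, has_tumor = any(m == 1L),
                       slide_id = slideId(b$slide))
    }
    out
  })
}

#' Build a tumor segmenter handle
#'
#' Configures the pixel-level tumor/non-tumor segmenter: a random forest
#' over per-pixel features (raw RGB plus Gaussian-smoothed RGB at two
#' scales, giving each pixel local context), with an auxiliary patch-level
#' has-tumor head trained alongside. Only the pixel head is used at
#' inference; the auxiliary head is a training-time diagnostic mirroring
#' the region-classification side task.
#'
#' @param input_px training patch side in pixels.
#' @param crop_factor random training crops are \code{input_px/crop_factor}
#'   on a side (2 keeps the train-time cropping contract at desk scale).
#' @param n_trees trees in the pixel forest.
#' @param sigmas Gaussian scales for the context features.
#' @param seed forest seed.
#' @return list of class \code{tumorSegmenter}.
#' @export
buildTumorSegmenter <- function(input_px = 128L, crop_factor = 2L,
                                n_trees = 60L, sigmas = c(2, 4), seed = 1L) {
  if (input_px %% crop_factor != 0L)
    .stopf("input_px must be divisible by crop_factor")
  structure(list(input_px = as.integer(input_px),
                 crop_factor = as.integer(crop_factor),
                 n_trees = as.integer(n_trees), sigmas = sigmas,
                 seed = as.integer(seed), fit = NULL, aux = NULL),
            class = "tumorSegmenter")
}

#' Train the tumor segmenter
#'
#' Splits samples 7:2:1 (train/val/test), augments training patches with
#' label-preserving flips, 90-degree rotations and HSV jitter, crops them
#' by \code{crop_factor}, and fits the per-pixel forest on a stratified
#' pixel sample. A separate patch-level has-tumor head is fitted as the
#' auxiliary task. Errors if the training pixels are single-class.
#'
#' @param model a \code{\link{buildTumorSegmenter}} handle.
#' @param samples list from \code{\link{sampleSegPatches}} (or equivalent).
#' @param split integer triple, default \code{c(7, 2, 1)}.
#' @param augment subset of \code{c("flip", "rotation", "hsv")}.
#' @param n_pixels total training pixels sampled across patches.
#' @param seed RNG seed for splitting/augmentation/pixel sampling.
#' @return the trained handle; \code{$split_index} records the sample
#'   split, \code{$history} the out-of-bag error.
#' @export
trainTumorSegmenter <- function(model, samples, split = c(7, 2, 1),
                                augment = c("flip", "rotation", "hsv"),
                                n_pixels = 30000L, seed = 1L) {
  stopifnot(inherits(model, "tumorSegmenter"))
  n <- length(samples)
  if (!n) .stopf("no segmentation samples")
  pr <- split / sum(split)
  .withSeed(seed, {
    nTrain <- round(n * pr[1]); nVal <- round(n * pr[2])
    nTrain <- min(nTrain, n); nVal <- min(nVal, n - nTrain)
    lab <- c(rep("train", nTrain), rep("val", nVal),
             rep("test", n - nTrain - nVal))
    splitIdx <- lab[sample.int(n)]
    trIdx <- which(splitIdx == "train")
    if (!length(trIdx)) .stopf("empty training split")
    crop <- model$input_px %/% model$crop_factor
    perPatch <- max(20L, ceiling(n_pixels / length(trIdx)))
    Xs <- list(); ys <- list(); auxX <- list(); auxY <- logical(0)
    for (i in trIdx) {
      s <- samples[[i]]
      a <- .augmentOnce(s$image, s$mask,
                        flip = "flip" %in% augment,
                        rotation = "rotation" %in% augment,
                        hsv = "hsv" %in% augment)
      img <- a$patch; msk <- if (is.null(a$mask)) s$mask else a$mask
      if (crop < dim(img)[1]) {
        cx <- sample.int(dim(img)[1] - crop + 1L, 1L) - 1L
        cy <- sample.int(dim(img)[2] - crop + 1L, 1L) - 1L
        img <- .cropPatch(img, cx, cy, crop)
        msk <- .cropMask(msk, cx, cy, crop)
      }
      F <- .pixelFeatures(img, model$sigmas)
      yv <- as.integer(msk)
      pos <- which(yv == 1L); neg <- which(yv == 0L)
      k <- perPatch %/% 2L
      take <- c(if (length(pos)) pos[sample.int(length(pos),
                                                min(k, length(pos)))],
                if (length(neg)) neg[sample.int(length(neg),
                                                min(k, length(neg)))])
      Xs[[length(Xs) + 1L]] <- F[take, , drop = FALSE]
      ys[[length(ys) + 1L]] <- yv[take]
      auxX[[length(auxX) + 1L]] <- .patchFeatures(img)
      auxY <- c(auxY, any(msk == 1L))
    }
    X <- do.call(rbind, Xs); y <- unlist(ys)
    if (length(unique(y)) < 2L)
      .stopf("training pixels are single-class; add tumor and non-tumor samples")
    df <- data.frame(X, y = factor(y, levels = c(0L, 1L)))
    model$fit <- ranger::ranger(y ~ ., data = df,
                                 num.trees = model$n_trees,
                                 probability = TRUE, seed = model$seed,
                                 num.threads = 1L)
    if (length(unique(auxY)) == 2L) {
      adf <- data.frame(do.call(rbind, auxX),
                        y = factor(auxY, levels = c(FALSE, TRUE)))
      model$aux <- ranger::ranger(y ~ ., data = adf, num.trees = 50L,
                                   probability = TRUE, seed = model$seed,
                                   num.threads = 1L)
    }
    model$split_index <- splitIdx
    model$history <- data.frame(n_train = length(trIdx),
                                 n_pixels = nrow(X),
                                 oob_error = model$fit$prediction.error)
  })
  model
}

#' Segment a patch into tumor vs non-tumor pixels
#'
#' Per-pixel inference with the trained pixel head (the auxiliary head is
#' not used, mirroring the pipeline's use of the segmentation output only).
#' Deterministic and idempotent. The patch must match the training
#' resolution unless \code{any_size}.
#'
#' @param model trained \code{\link{buildTumorSegmenter}} handle.
#' @param patch (p x p x 3) array.
#' @param any_size allow patches of other sizes (the pixel features are
#'   size-agnostic).
#' @return integer 0/1 matrix of the patch dimensions.
#' @export
segmentPatch <- function(model, patch, any_size = FALSE) {
  stopifnot(inherits(model, "tumorSegmenter"))
  if (is.null(model$fit)) .stopf("segmenter is not trained")
  d <- dim(patch)
  if (!any_size && !all(d[1:2] == model$input_px))
    .stopf("patch resolution %dx%d does not match segmenter input %d",
           d[1], d[2], model$input_px)
  F <- data.frame(.pixelFeatures(patch, model$sigmas))
  pr <- stats::predict(model$fit, F, num.threads = 1L)$predictions
  m <- matrix(as.integer(pr[, "1"] >= 0.5), d[1], d[2])
  m
}

#' Dice coefficient of two binary masks
#'
#' \code{2 |P & T| / (|P| + |T|)}; defined as 1 when both masks are empty
#' (a perfect negative stays perfect).
#'
#' @param pred,truth equal-shaped 0/1 masks.
#' @return numeric in [0, 1].
#' @export
diceCoefficient <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) .stopf("mask shapes differ")
  p <- sum(pred == 1L); t <- sum(truth == 1L)
  if (p + t == 0L) return(1)
  2 * sum(pred == 1L & truth == 1L) / (p + t)
}

#' Segmentation metrics: dice coefficient and pixel accuracy
#'
#' @param pred,truth equal-shaped 0/1 masks.
#' @return named numeric vector \code{dice}, \code{pixel_accuracy}.
#' @export
segmentationMetrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) .stopf("mask shapes differ")
  c(dice = diceCoefficient(pred, truth),
    pixel_accuracy = mean(pred == truth))
}

#' Evaluate a trained segmenter on its held-out split
#'
#' The headline \code{dice} pools intersection and mask areas over all
#' pixels of the split (the conventional single test-set dice); the
#' unweighted per-patch mean is reported alongside as
#' \code{dice_per_patch}. The two differ on patches whose true tumor area
#' is a few pixels, where per-patch dice is degenerate (a handful of
#' boundary pixels flips it between 1 and 0).
#'
#' @param model trained segmenter (with \code{$split_index}).
#' @param samples the sample list used in training.
#' @param split which split to evaluate (default \code{"test"}).
#' @return named numeric vector \code{dice} (pooled),
#'   \code{dice_per_patch}, \code{pixel_accuracy}, \code{n}.
#' @export
evaluateSegmenter <- function(model, samples, split = "test") {
  idx <- which(model$split_index == split)
  if (!length(idx)) .stopf("no samples in split '%s'", split)
  inter <- 0; psum <- 0; tsum <- 0
  per <- numeric(0); acc <- numeric(0)
  for (i in idx) {
    pm <- segmentPatch(model, samples[[i]]$image, any_size = TRUE)
    tm <- samples[[i]]$mask
    inter <- inter + sum(pm == 1L & tm == 1L)
    psum <- psum + sum(pm == 1L); tsum <- tsum + sum(tm == 1L)
    per <- c(per, diceCoefficient(pm, tm))
    acc <- c(acc, mean(pm == tm))
  }
  c(dice = if (psum + tsum == 0) 1 else 2 * inter / (psum + tsum),
    dice_per_patch = mean(per), pixel_accuracy = mean(acc),
    n = length(idx))
}
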