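#' Assemble a patch dataset for the tumor/non-tumor classifier
#'
#' Collects labeled patches (from \code{\link{exportPatchDataset}} exports)
#' into the dataset object used by \code{\link{splitDataset}} and
#' \code{\link{trainPatchClassifier}}.
#'
#' @param patches named list of (p x p x 3) arrays.
#' @param labels character/factor vector (\code{tumor} / \code{non_tumor}),
#'   same length and order as \code{patches}.
#' @param slide_id character vector of source slide ids (for slide-level
#'   splitting).
#' @return list of class \code{patchDataset}.
#' @export
patchDataset <- function(patches, labels, slide_id) {
  stopifnot(length(patches) == length(labels),
            length(labels) == length(slide_id))
  if (!length(patches)) .stopf("empty dataset")
  structure(list(patches = patches,
                 labels = factor(as.character(labels),
                                 levels = c("non_tumor", "tumor")),
                 slide_id = as.character(slide_id),
                 split = rep(NA_character_, length(patches))),
            class = "patchDataset")
}

#' Collect classifier patches from a cohort of synthetic slides
#'
#' Convenience wrapper: exports every slide's patch grid at \code{patch_px}
#' and pools patches and tumor/non-tumor labels across slides.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param patch_px patch side in pixels (desk-scale default 64).
#' @return a \code{\link{patchDataset}}.
#' @export
cohortPatchDataset <- function(cohort, patch_px = 64L) {
  patches <- list(); labels <- character(0); sid <- character(0)
  for (b in cohort$slides) {
    ex <- exportPatchDataset(b$slide, b$truth, patch_px)
    patches <- c(patches, ex$patches)
    labels <- c(labels, ex$manifest$label)
    sid <- c(sid, ex$manifest$slide_id)
  }
  patchDataset(patches, labels, sid)
}

#' Split a patch dataset into train/validation/test subsets
#'
#' Deterministic given the seed. \code{patch} mode assigns individual
#' patches at the requested ratio (6:2:2 by default); \code{slide} mode
#' keeps all patches of one slide in a single split (no slide spans two
#' splits), trading exact proportions for leakage control.
#'
#' @param dataset a \code{\link{patchDataset}}.
#' @param ratio integer triple (train, val, test).
#' @param mode \code{"patch"} or \code{"slide"}.
#' @param seed RNG seed.
#' @return the dataset with its \code{split} field assigned.
#' @export
splitDataset <- function(dataset, ratio = c(6, 2, 2), mode = c("patch", "slide"),
                         seed = 1L) {
  mode <- match.arg(mode)
  n <- length(dataset$patches)
  if (!n) .stopf("empty dataset")
  pr <- ratio / sum(ratio)
  .withSeed(seed, {
    if (mode == "patch") {
      nTrain <- round(n * pr[1]); nVal <- round(n * pr[2])
      nTrain <- min(nTrain, n); nVal <- min(nVal, n - nTrain)
      lab <- c(rep("train", nTrain), rep("val", nVal),
               rep("test", n - nTrain - nVal))
      dataset$split <- lab[sample.int(n)]
    } else {
      ids <- unique(dataset$slide_id)
      if (length(ids) < 3L) .stopf("slide-level split needs >= 3 slides")
      ids <- sample(ids)
      sizes <- table(dataset$slide_id)[ids]
      assign <- character(length(ids)); names(assign) <- ids
      filled <- c(train = 0, val = 0, test = 0)
      target <- pr * n
      for (id in ids) {
        # greedy: put the slide where the deficit is largest
        deficit <- target - filled
        pick <- names(deficit)[which.max(deficit)]
        assign[id] <- pick
        filled[pick] <- filled[pick] + sizes[[id]]
      }
      dataset$split <- unname(assign[dataset$slide_id])
    }
  })
  dataset
}

#' Build a patch classifier handle
#'
#' Configures the tumor/non-tumor patch classifier: a random forest over a
#' pooled color/texture descriptor of each patch (stain-response channels,
#' channel statistics, edge density). The handle is untrained until passed
#' to \code{\link{trainPatchClassifier}}.
#'
#' @param input_px expected patch side in pixels (NA accepts any size).
#' @param n_trees number of trees (>= 1).
#' @param seed seed used for forest construction.
#' @return list of class \code{patchClassifier}.
#' @export
buildPatchClassifier <- function(input_px = 64L, n_trees = 200L, seed = 1L) {
  if (n_trees < 1L) .stopf("n_trees must be >= 1")
  structure(list(input_px = input_px, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), fit = NULL),
            class = "patchClassifier")
}

#' Train the patch classifier
#'
#' Fits the forest on the \code{train} split, optionally enriching it with
#' label-preserving augmented copies (random flip, 90-degree rotation,
#' Gaussian blur with sigma in [0, 1.5]). Training errors if only one class
#' is present. The returned handle carries the fit and a small history
#' (out-of-bag error, split sizes).
#'
#' @param model a \code{\link{buildPatchClassifier}} handle.
#' @param dataset a split \code{\link{patchDataset}} (or unsplit: all
#'   patches train).
#' @param augment character subset of \code{c("flip", "rotation", "blur")};
#'   empty disables augmentation.
#' @param n_augment augmented copies per training patch.
#' @param seed RNG seed for augmentation sampling.
#' @return the trained handle.
#' @export
trainPatchClassifier <- function(model, dataset,
                                 augment = c("flip", "rotation", "blur"),
                                 n_augment = 1L, seed = 1L) {
  stopifnot(inherits(model, "patchClassifier"))
  tr <- if (all(is.na(dataset$split))) seq_along(dataset$patches)
        else which(dataset$split == "train")
  if (!length(tr)) .stopf("empty training split")
  labs <- dataset$labels[tr]
  if (length(unique(labs)) < 2L)
    .stopf("training split contains a single class")
  patches <- dataset$patches[tr]
  if (!is.na(model$input_px) &&
      !all(vapply(patches, function(p) all(dim(p)[1:2] == model$input_px),
                  logical(1))))
    .stopf("patch size does not match the classifier input size")
  aug <- list(); auglab <- character(0)
  if (length(augment) && n_augment > 0L) {
    .withSeed(seed, {
      for (rep in seq_len(n_augment)) {
        for (i in seq_along(patches)) {
          a <- .augmentOnce(patches[[i]],
                            flip = "flip" %in% augment,
                            rotation = "rotation" %in% augment,
                            blur = "blur" %in% augment)
          aug[[length(aug) + 1L]] <- a$patch
          auglab <- c(auglab, as.character(labs[i]))
        }
      }
    })
  }
  X <- .patchFeatureMatrix(c(patches, aug))
  y <- factor(c(as.character(labs), auglab), levels = levels(dataset$labels))
  df <- data.frame(X, y = y)
  fit <- ranger::ranger(y ~ ., data = df, num.trees = model$n_trees,
                        probability = TRUE, seed = model$seed,
                        num.threads = 1L)
  model$fit <- fit
  model$history <- data.frame(
    n_train = length(tr), n_augmented = length(aug),
    oob_error = fit$prediction.error)
  model
}

#' Classify patches as tumor-containing or non-tumor
#'
#' Deterministic inference; batch order does not affect per-patch outputs
#' and duplicated patches get identical results. An empty input yields an
#' empty result.
#'
#' @param model a trained \code{\link{buildPatchClassifier}} handle.
#' @param patches list of (p x p x 3) arrays.
#' @return data.frame with \code{label} (\code{tumor}/\code{non_tumor}) and
#'   \code{prob_tumor}.
#' @export
predictPatches <- function(model, patches) {
  stopifnot(inherits(model, "patchClassifier"))
  if (is.null(model$fit)) .stopf("classifier is not trained")
  if (!length(patches))
    return(data.frame(label = character(0), prob_tumor = numeric(0)))
  if (!is.na(model$input_px) &&
      !all(vapply(patches, function(p) all(dim(p)[1:2] == model$input_px),
                  logical(1))))
    .stopf("patch size does not match the classifier input size")
  X <- data.frame(.patchFeatureMatrix(patches))
  pr <- stats::predict(model$fit, X, num.threads = 1L)$predictions
  prob <- pr[, "tumor"]
  data.frame(label = ifelse(prob >= 0.5, "tumor", "non_tumor"),
             prob_tumor = prob, stringsAsFactors = FALSE)
}

# confusion-matrix point estimates; zero-denominator metrics are NA
.classPointMetrics <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- sdiv(tp, tp + fp); rec <- sdiv(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  c(accuracy = sdiv(tp + tn, tp + tn + fp + fn),
    precision = prec, recall = rec,
    specificity = sdiv(tn, tn + fp), f1 = f1)
}

#' Classification metrics with bootstrap confidence intervals
#'
#' Accuracy, precision, recall, specificity and F1 from the pooled
#' confusion matrix, each with a 95\% percentile-bootstrap CI over samples
#' (1000 resamples by default). Metrics with a zero denominator are
#' reported as NA, not 0.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the positive-class label (default \code{"tumor"}).
#' @param n_bootstrap bootstrap resamples for the CIs (0 skips CIs).
#' @param seed bootstrap seed.
#' @return data.frame: \code{metric, estimate, ci_lower, ci_upper}.
#' @export
classificationMetrics <- function(pred, truth, positive = "tumor",
                                  n_bootstrap = 1000L, seed = 1L) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (!length(pred) || length(pred) != length(truth))
    .stopf("pred and truth must be nonempty and of equal length")
  est <- .classPointMetrics(pred, truth, positive)
  lo <- hi <- rep(NA_real_, length(est))
  if (n_bootstrap > 0L) {
    n <- length(pred)
    .withSeed(seed, {
      boot <- replicate(n_bootstrap, {
        i <- sample.int(n, n, replace = TRUE)
        .classPointMetrics(pred[i], truth[i], positive)
      })
      qsafe <- function(v, p) if (all(is.na(v))) NA_real_ else
        stats::quantile(v, p, na.rm = TRUE, names = FALSE)
      lo <- apply(boot, 1, qsafe, p = 0.025)
      hi <- apply(boot, 1, qsafe, p = 0.975)
    })
  }
  data.frame(metric = names(est), estimate = unname(est),
             ci_lower = lo, ci_upper = hi, stringsAsFactors = FALSE)
}
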