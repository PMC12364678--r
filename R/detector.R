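#' Intersection-over-union of two half-open pixel boxes
#'
#' Boxes are \code{c(x_min, y_min, x_max, y_max)}, half-open, so area is
#' \code{(x_max - x_min) * (y_max - y_min)}. Degenerate boxes error.
#'
#' @param a,b numeric length-4 boxes.
#' @return IoU in [0, 1].
#' @export
boxIou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    .stopf("degenerate box")
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IoU of one box against the rows of a box matrix
.iouVec <- function(box, m) {
  if (!nrow(m)) return(numeric(0))
  ix <- pmax(0, pmin(box[3], m[, 3]) - pmax(box[1], m[, 1]))
  iy <- pmax(0, pmin(box[4], m[, 4]) - pmax(box[2], m[, 2]))
  inter <- ix * iy
  union <- (box[3] - box[1]) * (box[4] - box[2]) +
    (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter
  inter / union
}

#' Greedy non-maximum suppression
#'
#' Sorts detections by confidence (ties by input order), keeps the highest
#' and discards any remaining detection overlapping a kept one with IoU
#' above \code{nms_iou}. Intended to be applied per class.
#'
#' @param det data.frame with \code{x_min,y_min,x_max,y_max,confidence}.
#' @param nms_iou suppression threshold.
#' @return the surviving subset of \code{det}.
#' @export
nonMaxSuppression <- function(det, nms_iou = 0.45) {
  if (!nrow(det)) return(det)
  ord <- order(-det$confidence, seq_len(nrow(det)))
  det <- det[ord, , drop = FALSE]
  m <- as.matrix(det[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (any(keep)) {
      iou <- .iouVec(m[i, ], m[keep, , drop = FALSE])
      if (any(iou > nms_iou)) next
    }
    keep[i] <- TRUE
  }
  det[keep, , drop = FALSE]
}

#' Build a cell detector handle
#'
#' Configures the one-stage three-class cell detector (PD-L1+ tumor,
#' PD-L1- tumor, PD-L1+ immune cells): stain-positive connected components
#' propose candidate boxes anchor-free, and a random forest scores each
#' candidate over shape and inner/rim color features into the three cell
#' classes plus background, giving per-box class confidences.
#'
#' @param input_px expected patch side (NA accepts any size).
#' @param n_trees trees in the candidate-scoring forest.
#' @param blue_thr,brown_thr stain-response thresholds for proposals.
#' @param min_area,max_area candidate component area limits (px).
#' @param seed forest seed.
#' @return list of class \code{cellDetector}.
#' @export
buildCellDetector <- function(input_px = 128L, n_trees = 200L,
                              blue_thr = 0.18, brown_thr = 0.25,
                              min_area = 4L, max_area = 600L, seed = 1L) {
  if (n_trees < 1L) .stopf("n_trees must be >= 1")
  structure(list(input_px = input_px, n_trees = as.integer(n_trees),
                 blue_thr = blue_thr, brown_thr = brown_thr,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 seed = as.integer(seed), fit = NULL,
                 classes = c("tumor_pos", "tumor_neg", "immune_pos")),
            class = "cellDetector")
}

# remap boxes under horizontal flip / 90 deg CW rotation of a (W x H) patch
.flipBoxesH <- function(b, W) {
  x0 <- W - b$x_max; x1 <- W - b$x_min
  b$x_min <- x0; b$x_max <- x1
  b
}

.rotBoxes90 <- function(b, H) {
  # (x, y) -> (H - 1 - y, x) on pixel centers; half-open boxes map to
  # (H - y_max, x_min, H - y_min, x_max)
  nb <- b
  nb$x_min <- H - b$y_max; nb$x_max <- H - b$y_min
  nb$y_min <- b$x_min; nb$y_max <- b$x_max
  nb
}

# label candidates by greedy IoU >= thr match against ground-truth boxes
.labelCandidates <- function(cand, gtBoxes, thr = 0.5) {
  lab <- rep("background", nrow(cand))
  if (is.null(gtBoxes) || !nrow(gtBoxes)) return(lab)
  gm <- as.matrix(gtBoxes[, c("x_min", "y_min", "x_max", "y_max")])
  for (i in seq_len(nrow(cand))) {
    iou <- .iouVec(as.numeric(cand[i, c("x_min", "y_min", "x_max", "y_max")]),
                   gm)
    j <- which.max(iou)
    if (length(j) && iou[j] >= thr) lab[i] <- gtBoxes$class[j]
  }
  lab
}

#' Train the cell detector
#'
#' Builds the candidate training set from annotated patches, labels each
#' candidate by IoU >= 0.5 match against ground-truth boxes (unmatched
#' candidates become background), optionally enriches the set with flipped/
#' rotated/HSV-jittered patches and mosaic/mixup composites (box
#' bookkeeping exact by construction), and fits the scoring forest.
#' Errors unless all three cell classes appear in the training boxes.
#'
#' @param model a \code{\link{buildCellDetector}} handle.
#' @param patches list of (p x p x 3) arrays.
#' @param boxes data.frame with \code{patch_id,x_min,y_min,x_max,y_max,class}
#'   where \code{patch_id} indexes into \code{names(patches)}.
#' @param augment subset of
#'   \code{c("flip", "rotation", "hsv", "mosaic", "mixup")}; empty
#'   disables augmentation (the dataset passes through unmodified).
#' @param n_mosaic,n_mixup numbers of composites to add.
#' @param seed RNG seed.
#' @return the trained handle.
#' @export
trainCellDetector <- function(model, patches, boxes,
                              augment = c("flip", "rotation", "hsv",
                                          "mosaic", "mixup"),
                              n_mosaic = 20L, n_mixup = 20L, seed = 1L) {
  stopifnot(inherits(model, "cellDetector"))
  if (!length(patches)) .stopf("no training patches")
  if (is.null(names(patches))) names(patches) <- as.character(seq_along(patches))
  missing <- setdiff(model$classes, unique(boxes$class))
  if (length(missing))
    .stopf("class absent from training boxes: %s",
           paste(missing, collapse = ", "))
  boxesBy <- split(boxes, boxes$patch_id)
  items <- lapply(names(patches), function(id)
    list(patch = patches[[id]], boxes = boxesBy[[id]]))
  .withSeed(seed, {
    if (length(augment)) {
      extra <- list()
      if (any(c("flip", "rotation", "hsv") %in% augment)) {
        for (it in items) {
          p <- it$patch; b <- it$boxes
          W <- dim(p)[1]; H <- dim(p)[2]
          if ("flip" %in% augment && stats::runif(1) < 0.5) {
            p <- .flipH(p)
            if (!is.null(b) && nrow(b)) b <- .flipBoxesH(b, W)
          }
          if ("rotation" %in% augment) {
            k <- sample.int(4L, 1L) - 1L
            for (r in seq_len(k)) {
              p <- .rot90(p, 1L)
              if (!is.null(b) && nrow(b)) b <- .rotBoxes90(b, dim(p)[1])
            }
          }
          if ("hsv" %in% augment) p <- .hsvJitter(p)
          extra[[length(extra) + 1L]] <- list(patch = p, boxes = b)
        }
      }
      if ("mosaic" %in% augment && length(items) >= 4L) {
        for (m in seq_len(n_mosaic)) {
          pick <- sample.int(length(items), 4L, replace = TRUE)
          mo <- mosaicCompose(lapply(items[pick], `[[`, "patch"),
                              lapply(items[pick], `[[`, "boxes"))
          extra[[length(extra) + 1L]] <- list(patch = mo$patch,
                                              boxes = mo$boxes)
        }
      }
      if ("mixup" %in% augment && length(items) >= 2L) {
        for (m in seq_len(n_mixup)) {
          pick <- sample.int(length(items), 2L)
          lam <- stats::runif(1, 0.35, 0.65)
          mx <- mixupCompose(items[[pick[1]]]$patch, items[[pick[1]]]$boxes,
                             items[[pick[2]]]$patch, items[[pick[2]]]$boxes,
                             lambda = lam)
          extra[[length(extra) + 1L]] <- list(patch = mx$patch,
                                              boxes = mx$boxes)
        }
      }
      items <- c(items, extra)
    }
  })
  Xs <- list(); ys <- character(0)
  for (it in items) {
    cand <- .cellCandidates(it$patch, model$blue_thr, model$brown_thr,
                            model$min_area, model$max_area)
    if (is.null(cand)) next
    lab <- .labelCandidates(cand, it$boxes)
    Xs[[length(Xs) + 1L]] <- as.matrix(cand[, .candidateFeatureNames])
    ys <- c(ys, lab)
  }
  if (!length(ys)) .stopf("no candidates found in training patches")
  y <- factor(ys, levels = c("background", model$classes))
  df <- data.frame(do.call(rbind, Xs), y = y)
  model$fit <- ranger::ranger(y ~ ., data = df, num.trees = model$n_trees,
                              probability = TRUE, seed = model$seed,
                              num.threads = 1L)
  model$history <- data.frame(n_candidates = length(ys),
                              oob_error = model$fit$prediction.error)
  model
}

#' Detect cells in a patch
#'
#' Proposal, scoring, confidence filtering and per-class greedy NMS.
#' Deterministic for a fixed input; an empty patch yields an empty record
#' list and the output count never exceeds the pre-NMS candidate count.
#'
#' @param model trained \code{\link{buildCellDetector}} handle.
#' @param patch (p x p x 3) array.
#' @param conf_threshold minimum class confidence (default 0.25).
#' @param nms_iou per-class NMS threshold (default 0.45).
#' @return data.frame of detection records:
#'   \code{x_min,y_min,x_max,y_max,class,confidence} (patch coordinates,
#'   half-open, clipped to the patch).
#' @export
detectCells <- function(model, patch, conf_threshold = 0.25,
                        nms_iou = 0.45) {
  stopifnot(inherits(model, "cellDetector"))
  if (is.null(model$fit)) .stopf("detector is not trained")
  empty <- data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      class = character(0), confidence = numeric(0))
  cand <- .cellCandidates(patch, model$blue_thr, model$brown_thr,
                          model$min_area, model$max_area)
  if (is.null(cand)) return(empty)
  X <- data.frame(as.matrix(cand[, .candidateFeatureNames]))
  pr <- stats::predict(model$fit, X, num.threads = 1L)$predictions
  cellProb <- pr[, model$classes, drop = FALSE]
  cls <- model$classes[max.col(cellProb, ties.method = "first")]
  conf <- cellProb[cbind(seq_len(nrow(cand)), match(cls, model$classes))]
  det <- data.frame(x_min = cand$x_min, y_min = cand$y_min,
                    x_max = cand$x_max, y_max = cand$y_max,
                    class = cls, confidence = conf,
                    stringsAsFactors = FALSE)
  det <- det[det$confidence >= conf_threshold, , drop = FALSE]
  if (!nrow(det)) return(empty)
  out <- NULL
  for (cl in model$classes) {
    sub <- det[det$class == cl, , drop = FALSE]
    if (nrow(sub)) out <- rbind(out, nonMaxSuppression(sub, nms_iou))
  }
  out <- out[order(-out$confidence, out$x_min, out$y_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average precision of detections at a fixed IoU threshold
#'
#' Per class: predictions are sorted by confidence (descending, ties by
#' input order) and greedily matched, each to the highest-IoU unmatched
#' ground-truth box of the same class and image with IoU at or above the
#' threshold; a matched prediction is a true positive, anything else a
#' false positive, and no two predictions can claim one truth. AP is the
#' area under the all-point interpolated precision-recall curve. Classes
#' with zero ground-truth boxes get NA (absent), and the mean AP averages
#' the defined classes.
#'
#' @param preds data.frame \code{x_min,y_min,x_max,y_max,class,confidence}
#'   plus an \code{image_id} column (use a constant for a single image).
#' @param truths data.frame \code{x_min,y_min,x_max,y_max,class} plus
#'   \code{image_id}.
#' @param iou_threshold match threshold (default 0.5).
#' @param classes class set to evaluate (default the three cell classes).
#' @return list with \code{per_class} (named numeric) and \code{mean_ap}.
#' @export
averagePrecision <- function(preds, truths, iou_threshold = 0.5,
                             classes = c("tumor_pos", "tumor_neg",
                                         "immune_pos")) {
  if (is.null(preds$image_id)) preds$image_id <- "img"
  if (is.null(truths$image_id)) truths$image_id <- "img"
  ap <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    tr <- truths[truths$class == cl, , drop = FALSE]
    if (!nrow(tr)) next
    pd <- preds[preds$class == cl, , drop = FALSE]
    if (!nrow(pd)) { ap[cl] <- 0; next }
    pd <- pd[order(-pd$confidence, seq_len(nrow(pd))), , drop = FALSE]
    matched <- rep(FALSE, nrow(tr))
    tp <- numeric(nrow(pd))
    for (i in seq_len(nrow(pd))) {
      sameImg <- which(tr$image_id == pd$image_id[i] & !matched)
      if (length(sameImg)) {
        iou <- .iouVec(as.numeric(pd[i, c("x_min", "y_min",
                                          "x_max", "y_max")]),
                       as.matrix(tr[sameImg, c("x_min", "y_min",
                                               "x_max", "y_max")]))
        j <- which.max(iou)
        if (iou[j] >= iou_threshold) {
          matched[sameImg[j]] <- TRUE
          tp[i] <- 1
        }
      }
    }
    cumTp <- cumsum(tp)
    prec <- cumTp / seq_along(tp)
    rec <- cumTp / nrow(tr)
    # all-point interpolation: integrate max precision to the right
    mprec <- rev(cummax(rev(prec)))
    ap[cl] <- sum((rec - c(0, rec[-length(rec)])) * mprec)
  }
  defined <- ap[!is.na(ap)]
  list(per_class = ap,
       mean_ap = if (length(defined)) mean(defined) else NA_real_)
}
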