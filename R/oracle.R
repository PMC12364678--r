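# model dispatch used by scoreSlide: trained handles and ground-truth
# oracle stand-ins share the same three entry points

.modelClassifyTiles <- function(model, slide, tls, p, getPatch) {
  if (inherits(model, "oracleClassifier")) {
    cells <- cellTable(model$truth)
    tcells <- cells[cells$class %in% c("tumor_pos", "tumor_neg"), ,
                    drop = FALSE]
    cpx <- floor(tcells$cx); cpy <- floor(tcells$cy)
    vapply(seq_len(nrow(tls)), function(i) {
      x <- tls$x[i]; y <- tls$y[i]
      if (any(cpx >= x & cpx < x + p & cpy >= y & cpy < y + p))
        "tumor" else "non_tumor"
    }, character(1))
  } else if (inherits(model, "constantClassifier")) {
    rep(model$label, nrow(tls))
  } else {
    patches <- lapply(seq_len(nrow(tls)), getPatch)
    predictPatches(model, patches)$label
  }
}

.modelSegment <- function(model, slide, tile, patch) {
  p <- dim(patch)[1]
  if (inherits(model, "oracleSegmenter")) {
    .cropMask(tumorMask(model$truth), tile$x, tile$y, p)
  } else {
    segmentPatch(model, patch, any_size = TRUE)
  }
}

.modelDetect <- function(model, slide, tile, patch, conf_threshold, nms_iou) {
  p <- dim(patch)[1]
  if (inherits(model, "oracleDetector")) {
    cells <- cellTable(model$truth)
    cpx <- floor(cells$cx); cpy <- floor(cells$cy)
    sel <- cpx >= tile$x & cpx < tile$x + p &
      cpy >= tile$y & cpy < tile$y + p
    b <- cells[sel, , drop = FALSE]
    data.frame(x_min = pmax(0L, b$x_min - tile$x),
               y_min = pmax(0L, b$y_min - tile$y),
               x_max = pmin(p, b$x_max - tile$x),
               y_max = pmin(p, b$y_max - tile$y),
               class = b$class, confidence = rep(1, nrow(b)),
               stringsAsFactors = FALSE)
  } else {
    detectCells(model, patch, conf_threshold = conf_threshold,
                nms_iou = nms_iou)
  }
}

#' Ground-truth oracle stand-ins for the three models
#'
#' Builds perfect classifier/segmenter/detector substitutes from a
#' \linkS4class{SlideGroundTruth}: the classifier labels a tile tumor iff
#' it contains a tumor-class cell center, the segmenter returns the exact
#' tumor-mask crop, and the detector returns the ground-truth boxes of the
#' tile (each cell assigned to the unique tile holding its center) at
#' confidence 1. Used by end-to-end recovery tests and as the perfect-
#' classifier arm of the gating comparison; any subset can be mixed with
#' trained handles.
#'
#' @param truth a \linkS4class{SlideGroundTruth}.
#' @return list with \code{classifier}, \code{segmenter}, \code{detector}.
#' @export
oracleModels <- function(truth) {
  stopifnot(is(truth, "SlideGroundTruth"))
  list(classifier = structure(list(truth = truth),
                              class = "oracleClassifier"),
       segmenter = structure(list(truth = truth),
                             class = "oracleSegmenter"),
       detector = structure(list(truth = truth),
                            class = "oracleDetector"))
}

#' Constant patch classifier
#'
#' A classifier stand-in that labels every tile with a fixed label; the
#' \code{"tumor"} constant makes the consensus gate vacuous, which is the
#' degenerate case where gated and ungated runs coincide.
#'
#' @param label the constant label (default \code{"tumor"}).
#' @return a classifier stand-in usable in \code{\link{scoreSlide}}.
#' @export
constantClassifier <- function(label = "tumor") {
  structure(list(label = label), class = "constantClassifier")
}
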