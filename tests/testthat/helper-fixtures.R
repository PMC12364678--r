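# memoized fixtures (built once per test run) and independent brute-force
# oracles used across test files

.fx <- new.env(parent = emptyenv())

fxMemo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small single slide used by fast unit tests
fxSlide <- function() fxMemo("slide", function() {
  generateSlide(synthParams(canvas_px = c(512, 512), n_tumor_pos = 40,
                            n_tumor_neg = 90, n_immune_pos = 20, seed = 42))
})

# clean rendering fixture: no noise, no jitter, no weak staining
fxCleanSlide <- function() fxMemo("clean_slide", function() {
  generateSlide(synthParams(canvas_px = c(512, 512), n_tumor_pos = 40,
                            n_tumor_neg = 90, n_immune_pos = 20,
                            noise_sd = 0, color_jitter = 0, weak_fraction = 0,
                            seed = 43))
})

# training cohort for the three models
fxTrainCohort <- function() fxMemo("train_cohort", function() {
  generateCohort(6, seed = 11, params = synthParams(
    canvas_px = c(640, 640), n_tumor_pos = 60, n_tumor_neg = 140,
    n_immune_pos = 30, seed = 1))
})

fxClassifierDataset <- function() fxMemo("cls_dataset", function() {
  splitDataset(cohortPatchDataset(fxTrainCohort(), patch_px = 64), seed = 3)
})

fxClassifier <- function() fxMemo("classifier", function() {
  trainPatchClassifier(buildPatchClassifier(input_px = 64, seed = 5),
                       fxClassifierDataset(), seed = 5)
})

fxSegSamples <- function() fxMemo("seg_samples", function() {
  sampleSegPatches(fxTrainCohort(), n_samples = 150, patch_px = 128, seed = 7)
})

fxSegmenter <- function() fxMemo("segmenter", function() {
  trainTumorSegmenter(buildTumorSegmenter(input_px = 128, seed = 7),
                      fxSegSamples(), seed = 7)
})

# detector trained on slides 1-4; slides 5-6 are held out for evaluation
fxDetectorData <- function() fxMemo("det_data", function() {
  patches <- list(); boxes <- NULL
  for (b in fxTrainCohort()$slides[1:4]) {
    ex <- exportPatchDataset(b$slide, b$truth, 128)
    patches <- c(patches, ex$patches)
    boxes <- rbind(boxes, ex$boxes)
  }
  list(patches = patches, boxes = boxes)
})

fxDetector <- function() fxMemo("detector", function() {
  dd <- fxDetectorData()
  trainCellDetector(buildCellDetector(input_px = 128, seed = 9),
                    dd$patches, dd$boxes, seed = 9)
})

# oracle-recovery cohort: 20 slides spanning both sides of the CPS=1 cutoff
fxOracleCohort <- function() fxMemo("oracle_cohort", function() {
  generateCohort(20,
                 cps_targets = c(0, 0.5, 3, 31.6, 55, 0.8, 10, 120, 1.5, 80),
                 seed = 101, denominator = 150,
                 params = synthParams(canvas_px = c(512, 512),
                                      tissue_fraction = 0.6,
                                      tumor_region_fraction = 0.5, seed = 1))
})

# gating-efficiency cohort: tumor occupies 10% of an all-tissue canvas
fxGatingCohort <- function() fxMemo("gating_cohort", function() {
  generateCohort(20, cps_targets = c(40, 0, 12, 0.6, 70), seed = 77,
                 denominator = 110,
                 params = synthParams(canvas_px = c(640, 640),
                                      tissue_fraction = 1.0,
                                      tumor_region_fraction = 0.1, seed = 1))
})

# 128-px classifier matched to the gating cohort's tile size
fxGatingClassifier <- function() fxMemo("gating_classifier", function() {
  tr <- generateCohort(4, seed = 33, params = synthParams(
    canvas_px = c(640, 640), tissue_fraction = 1.0,
    tumor_region_fraction = 0.1, n_tumor_pos = 40, n_tumor_neg = 70,
    n_immune_pos = 15, seed = 1))
  ds <- splitDataset(cohortPatchDataset(tr, 128), seed = 3)
  trainPatchClassifier(buildPatchClassifier(128, seed = 5), ds, seed = 5)
})

# noise-free scoring configuration used with oracle model stand-ins
fxOracleConfig <- function() {
  runConfig(patch_px = 128, tissue_filter = "none",
            min_tissue_fraction = 0, min_tumor_fraction = 0)
}

## ---- independent brute-force oracles -------------------------------------

# exhaustive Otsu: scan all 256 thresholds, scalar arithmetic
bruteOtsu <- function(gray) {
  v <- as.integer(pmin(pmax(floor(gray), 0), 255))
  n <- length(v)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (!length(c0) || !length(c1)) next
    w0 <- length(c0) / n; w1 <- length(c1) / n
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# tally-and-divide CPS oracle (plain arithmetic on the three counts)
bruteCps <- function(pos, neg, imm) {
  den <- pos + neg
  if (den == 0) return(list(valid = FALSE, cps = NA_real_))
  list(valid = TRUE, cps = 100 * (pos + imm) / den)
}

# scalar dice / pixel accuracy
bruteSegMetrics <- function(pred, truth) {
  inter <- 0; p <- 0; t <- 0; match <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1) p <- p + 1
    if (truth[i] == 1) t <- t + 1
    if (pred[i] == 1 && truth[i] == 1) inter <- inter + 1
    if (pred[i] == truth[i]) match <- match + 1
  }
  c(dice = if (p + t == 0) 1 else 2 * inter / (p + t),
    pixel_accuracy = match / length(pred))
}

# scalar IoU of two half-open boxes
bruteIou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

# PR-curve enumeration AP oracle for one class, single image set; greedy
# matching per the definition, then AP as sum over the n_truth recall
# steps of the max precision at recall >= k/n (equivalent to the area
# under the all-point interpolated curve, computed independently)
bruteAp <- function(preds, truths, iou_thr = 0.5) {
  if (nrow(truths) == 0) return(NA_real_)
  if (nrow(preds) == 0) return(0)
  ord <- order(-preds$confidence, seq_len(nrow(preds)))
  preds <- preds[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(truths))
  isTp <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    bestJ <- 0; bestIou <- -1
    for (j in seq_len(nrow(truths))) {
      if (used[j]) next
      if (truths$image_id[j] != preds$image_id[i]) next
      iou <- bruteIou(as.numeric(preds[i, c("x_min", "y_min",
                                            "x_max", "y_max")]),
                      as.numeric(truths[j, c("x_min", "y_min",
                                             "x_max", "y_max")]))
      if (iou > bestIou) { bestIou <- iou; bestJ <- j }
    }
    if (bestJ > 0 && bestIou >= iou_thr) { used[bestJ] <- TRUE; isTp[i] <- TRUE }
  }
  n <- nrow(truths)
  prec <- cumsum(isTp) / seq_along(isTp)
  rec <- cumsum(isTp) / n
  total <- 0
  for (k in seq_len(n)) {
    atLeast <- prec[rec >= k / n]
    total <- total + (if (length(atLeast)) max(atLeast) else 0) / n
  }
  total
}

# closed-form Cohen's kappa for a 2x2 table
bruteKappa <- function(m) {
  n <- sum(m)
  po <- (m[1, 1] + m[2, 2]) / n
  pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

# rational comparison of 100*a/b vs 100*c/d by cross multiplication
rationalLess <- function(a, b, c, d) a * d < c * b
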