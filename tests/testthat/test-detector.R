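# cell detector: IoU, NMS, AP vs brute-force PR enumeration, mosaic/mixup
# bookkeeping, training separability and count fidelity

test_that("box IoU matches closed forms and rejects degenerate boxes", {
  expect_equal(boxIou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(boxIou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(boxIou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_error(boxIou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("NMS collapses duplicate detections and never adds records", {
  det <- data.frame(x_min = c(0, 1, 40), y_min = c(0, 1, 40),
                    x_max = c(10, 11, 50), y_max = c(10, 11, 50),
                    confidence = c(0.9, 0.8, 0.7))
  kept <- nonMaxSuppression(det, nms_iou = 0.45)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$confidence[1], 0.9)  # the duplicate kept is the stronger
  expect_lte(nrow(kept), nrow(det))
})

test_that("AP handles the canonical one- and two-prediction cases", {
  t1 <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   class = "tumor_pos")
  hit <- data.frame(x_min = 0, y_min = 1, x_max = 10, y_max = 11,
                    class = "tumor_pos", confidence = 0.9)
  expect_equal(averagePrecision(hit, t1)$per_class[["tumor_pos"]], 1)
  # higher-confidence miss before the hit halves AP
  two <- data.frame(x_min = c(50, 0), y_min = c(50, 1),
                    x_max = c(60, 10), y_max = c(60, 11),
                    class = "tumor_pos", confidence = c(0.95, 0.9))
  expect_equal(averagePrecision(two, t1)$per_class[["tumor_pos"]], 0.5)
  # class with zero truths is reported absent
  ap <- averagePrecision(hit, t1)
  expect_true(is.na(ap$per_class[["immune_pos"]]))
})

test_that("AP equals the brute-force PR oracle on random small instances", {
  withr::with_seed(777, {
    for (i in 1:40) {
      nT <- sample(1:6, 1); nP <- sample(0:10, 1)
      truths <- data.frame(
        x_min = sample(0:50, nT, TRUE), y_min = sample(0:50, nT, TRUE),
        class = "tumor_pos", image_id = sample(c("a", "b"), nT, TRUE))
      truths$x_max <- truths$x_min + sample(5:15, nT, TRUE)
      truths$y_max <- truths$y_min + sample(5:15, nT, TRUE)
      if (nP == 0) {
        preds <- data.frame(x_min = numeric(0), y_min = numeric(0),
                            x_max = numeric(0), y_max = numeric(0),
                            class = character(0), confidence = numeric(0),
                            image_id = character(0))
      } else {
        base <- truths[sample(nT, nP, TRUE), ]
        preds <- data.frame(
          x_min = base$x_min + sample(-6:6, nP, TRUE),
          y_min = base$y_min + sample(-6:6, nP, TRUE),
          class = "tumor_pos",
          confidence = round(runif(nP), 2),
          image_id = base$image_id)
        preds$x_max <- preds$x_min + sample(5:15, nP, TRUE)
        preds$y_max <- preds$y_min + sample(5:15, nP, TRUE)
      }
      got <- averagePrecision(preds, truths,
                              classes = "tumor_pos")$per_class[["tumor_pos"]]
      want <- bruteAp(preds, truths)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("AP is invariant to monotone confidence rescaling and never double-matches", {
  withr::with_seed(88, {
    truths <- data.frame(x_min = c(0, 30), y_min = c(0, 30),
                         x_max = c(10, 40), y_max = c(10, 40),
                         class = "tumor_pos", image_id = "a")
    preds <- data.frame(x_min = c(1, 2, 31), y_min = c(1, 2, 31),
                        x_max = c(11, 12, 41), y_max = c(11, 12, 41),
                        class = "tumor_pos",
                        confidence = c(0.9, 0.8, 0.7), image_id = "a")
    a <- averagePrecision(preds, truths, classes = "tumor_pos")$mean_ap
    preds2 <- preds; preds2$confidence <- preds$confidence^3 / 2
    b <- averagePrecision(preds2, truths, classes = "tumor_pos")$mean_ap
    expect_equal(a, b)
    # two near-identical predictions cannot both claim the one truth:
    # the second must register as a false positive, so AP < 1 with 3 preds
    expect_lt(a, 1)
  })
})

test_that("mosaic remaps all boxes into the composite canvas", {
  p <- lapply(1:4, function(i) array(i / 4, dim = c(64, 64, 3)))
  b <- lapply(1:4, function(i)
    data.frame(x_min = c(0, 10, 20), y_min = c(0, 10, 20),
               x_max = c(8, 18, 28), y_max = c(8, 18, 28),
               class = "tumor_pos"))
  mo <- mosaicCompose(p, b)
  expect_equal(dim(mo$patch), c(128, 128, 3))
  expect_equal(nrow(mo$boxes), 12)
  expect_true(all(mo$boxes$x_min >= 0 & mo$boxes$x_max <= 128))
  expect_true(all(mo$boxes$y_min >= 0 & mo$boxes$y_max <= 128))
})

test_that("mixup blends images and pools the box union", {
  a <- array(0, dim = c(32, 32, 3)); b <- array(1, dim = c(32, 32, 3))
  ba <- data.frame(x_min = 0, y_min = 0, x_max = 5, y_max = 5,
                   class = "tumor_neg")
  bb <- data.frame(x_min = 10, y_min = 10, x_max = 15, y_max = 15,
                   class = "immune_pos")
  mx <- mixupCompose(a, ba, b, bb, lambda = 0.25)
  expect_equal(mx$patch[1, 1, 1], 0.75)
  expect_equal(nrow(mx$boxes), 2)
  expect_setequal(mx$boxes$class, c("tumor_neg", "immune_pos"))
})

test_that("training requires all three classes; detection is deterministic", {
  dd <- fxDetectorData()
  oneClass <- dd$boxes[dd$boxes$class == "tumor_neg", ]
  expect_error(trainCellDetector(buildCellDetector(128), dd$patches,
                                 oneClass),
               "class absent")
  det <- fxDetector()
  p <- dd$patches[[which(vapply(dd$patches, function(x) TRUE, logical(1)))[5]]]
  d1 <- detectCells(det, p); d2 <- detectCells(det, p)
  expect_identical(d1, d2)
  # empty patch yields an empty record list
  blank <- array(0.96, dim = c(128, 128, 3))
  expect_equal(nrow(detectCells(det, blank)), 0)
})

test_that("trained tiny detector reaches held-out mean AP@0.5 >= 0.70", {
  det <- fxDetector()
  preds <- NULL; truths <- NULL
  for (b in fxTrainCohort()$slides[5:6]) {
    ex <- exportPatchDataset(b$slide, b$truth, 128)
    for (pid in names(ex$patches)) {
      d <- detectCells(det, ex$patches[[pid]])
      if (nrow(d)) { d$image_id <- pid; preds <- rbind(preds, d) }
    }
    tb <- ex$boxes; tb$image_id <- tb$patch_id
    truths <- rbind(truths, tb)
  }
  ap <- averagePrecision(preds, truths)
  expect_gte(ap$mean_ap, 0.70)
})

test_that("detector recovers per-class counts within 10% on clean slides", {
  det <- fxDetector()
  sl <- generateSlide(synthParams(canvas_px = c(640, 640), n_tumor_pos = 60,
                                  n_tumor_neg = 140, n_immune_pos = 30,
                                  noise_sd = 0, weak_fraction = 0,
                                  seed = 202))
  ex <- exportPatchDataset(sl$slide, sl$truth, 128)
  cnt <- c(tumor_pos = 0, tumor_neg = 0, immune_pos = 0)
  for (pid in names(ex$patches)) {
    d <- detectCells(det, ex$patches[[pid]])
    if (nrow(d)) cnt <- cnt + table(factor(d$class, names(cnt)))
  }
  truth <- trueCounts(sl$truth)
  for (cl in names(cnt)) {
    expect_lt(abs(cnt[[cl]] - truth[[paste0("n_", cl)]]) /
                truth[[paste0("n_", cl)]], 0.10)
  }
})
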