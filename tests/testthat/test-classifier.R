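# patch classifier: splitting, training separability, deterministic
# inference, metric definitions

test_that("patch-mode split hits the 6:2:2 ratio and is seed-deterministic", {
  ds <- patchDataset(replicate(1000, array(0.5, dim = c(8, 8, 3)),
                               simplify = FALSE),
                     rep(c("tumor", "non_tumor"), 500),
                     rep(sprintf("s%02d", 1:10), each = 100))
  a <- splitDataset(ds, seed = 4)
  expect_equal(sum(a$split == "train"), 600)
  expect_equal(sum(a$split == "val"), 200)
  expect_equal(sum(a$split == "test"), 200)
  b <- splitDataset(ds, seed = 4)
  expect_identical(a$split, b$split)
  c <- splitDataset(ds, seed = 5)
  expect_false(identical(a$split, c$split))
})

test_that("slide-mode split never lets a slide span two splits", {
  ds <- patchDataset(replicate(120, array(0.5, dim = c(8, 8, 3)),
                               simplify = FALSE),
                     rep(c("tumor", "non_tumor"), 60),
                     rep(sprintf("s%02d", 1:6), each = 20))
  s <- splitDataset(ds, mode = "slide", seed = 1)
  tab <- table(s$slide_id, s$split)
  expect_true(all(rowSums(tab > 0) == 1))
  small <- patchDataset(ds$patches[1:40], ds$labels[1:40], ds$slide_id[1:40])
  expect_error(splitDataset(small, mode = "slide"), ">= 3 slides")
})

test_that("trained tiny classifier separates synthetic tumor patches", {
  ds <- fxClassifierDataset()
  cls <- fxClassifier()
  te <- which(ds$split == "test")
  pr <- predictPatches(cls, ds$patches[te])
  acc <- mean(pr$label == as.character(ds$labels[te]))
  expect_gte(acc, 0.95)
  expect_true(all(pr$prob_tumor >= 0 & pr$prob_tumor <= 1))
})

test_that("prediction is deterministic and per-patch (batch-order free)", {
  ds <- fxClassifierDataset()
  cls <- fxClassifier()
  p <- ds$patches[1:6]
  a <- predictPatches(cls, p)
  b <- predictPatches(cls, rev(p))
  expect_equal(a$prob_tumor, rev(b$prob_tumor))
  # duplicated patch in one batch gets identical outputs
  dup <- predictPatches(cls, list(p[[1]], p[[2]], p[[1]]))
  expect_identical(dup$prob_tumor[1], dup$prob_tumor[3])
  # empty input
  expect_equal(nrow(predictPatches(cls, list())), 0)
  # resolution mismatch errors
  expect_error(predictPatches(cls, list(array(0.5, dim = c(32, 32, 3)))),
               "input size")
  # single-class training refuses
  ss <- patchDataset(ds$patches[1:10], rep("tumor", 10), rep("s", 10))
  expect_error(trainPatchClassifier(buildPatchClassifier(64), ss),
               "single class")
})

test_that("augmentation preserves the label distribution", {
  ds <- fxClassifierDataset()
  tr <- which(ds$split == "train")[1:20]
  sub <- patchDataset(ds$patches[tr], as.character(ds$labels[tr]),
                      ds$slide_id[tr])
  m <- trainPatchClassifier(buildPatchClassifier(64, n_trees = 10, seed = 1),
                            sub, augment = c("flip", "rotation", "blur"),
                            n_augment = 2, seed = 1)
  # each augmentation round adds one copy of every training patch,
  # carrying its own label
  expect_equal(m$history$n_augmented, 2 * length(tr))
})

test_that("classification metrics match their closed forms", {
  # worked confusion matrix: TP=90 FN=10 TN=80 FP=20
  truth <- c(rep("tumor", 100), rep("non_tumor", 100))
  pred <- c(rep("tumor", 90), rep("non_tumor", 10),
            rep("non_tumor", 80), rep("tumor", 20))
  m <- classificationMetrics(pred, truth, n_bootstrap = 0)
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["accuracy"]], 0.85)
  expect_equal(est[["precision"]], 90 / 110)
  expect_equal(est[["recall"]], 0.90)
  expect_equal(est[["specificity"]], 0.80)
  expect_equal(est[["f1"]], 2 * (90 / 110) * 0.9 / (90 / 110 + 0.9))
  # perfect prediction
  mp <- classificationMetrics(truth, truth, n_bootstrap = 0)
  expect_true(all(mp$estimate == 1))
  # all-positive predictions on balanced labels
  ap <- classificationMetrics(rep("tumor", 200), truth, n_bootstrap = 0)
  estAp <- setNames(ap$estimate, ap$metric)
  expect_equal(estAp[["recall"]], 1)
  expect_equal(estAp[["specificity"]], 0)
  # undefined metrics are NA, not zero
  an <- classificationMetrics(rep("non_tumor", 200), truth, n_bootstrap = 0)
  expect_true(is.na(setNames(an$estimate, an$metric)[["precision"]]))
})

test_that("metrics equal closed forms on random confusion matrices", {
  withr::with_seed(555, {
    for (i in 1:50) {
      tp <- sample(0:30, 1); fn <- sample(0:30, 1)
      tn <- sample(0:30, 1); fp <- sample(0:30, 1)
      if (tp + fn + tn + fp == 0) next
      truth <- c(rep("tumor", tp + fn), rep("non_tumor", tn + fp))
      pred <- c(rep("tumor", tp), rep("non_tumor", fn),
                rep("non_tumor", tn), rep("tumor", fp))
      m <- setNames(classificationMetrics(pred, truth, n_bootstrap = 0)$estimate,
                    c("accuracy", "precision", "recall", "specificity", "f1"))
      expAcc <- (tp + tn) / (tp + tn + fp + fn)
      expect_equal(m[["accuracy"]], expAcc)
      if (tp + fp > 0) expect_equal(m[["precision"]], tp / (tp + fp))
      else expect_true(is.na(m[["precision"]]))
      if (tp + fn > 0) expect_equal(m[["recall"]], tp / (tp + fn))
      else expect_true(is.na(m[["recall"]]))
      if (tn + fp > 0) expect_equal(m[["specificity"]], tn / (tn + fp))
      else expect_true(is.na(m[["specificity"]]))
      if (!is.na(m[["precision"]]) && !is.na(m[["recall"]]) &&
          m[["precision"]] + m[["recall"]] > 0) {
        expect_equal(m[["f1"]],
                     2 * m[["precision"]] * m[["recall"]] /
                       (m[["precision"]] + m[["recall"]]))
      }
    }
  })
})

test_that("bootstrap CIs bracket the point estimate", {
  truth <- rep(c("tumor", "non_tumor"), 50)
  pred <- truth; pred[1:10] <- "non_tumor"
  m <- classificationMetrics(pred, truth, n_bootstrap = 200, seed = 7)
  ok <- !is.na(m$estimate)
  expect_true(all(m$ci_lower[ok] <= m$estimate[ok] + 1e-9))
  expect_true(all(m$ci_upper[ok] >= m$estimate[ok] - 1e-9))
})
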