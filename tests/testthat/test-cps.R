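# CPS engine: gate semantics, region tagging, proximity rule, exact
# formula, end-to-end oracle recovery, gating efficiency

test_that("consensus gate requires both the classifier and the segmenter", {
  m <- matrix(0L, 64, 64); m[1:32, 1:40] <- 1L  # ~31% tumor
  g <- consensusGate("tumor", m, 0.01)
  expect_true(g$pass)
  expect_identical(g$mask, m)
  expect_false(consensusGate("non_tumor", m, 0.01)$pass)       # classifier veto
  expect_false(consensusGate("tumor", matrix(0L, 64, 64), 0)$pass)  # segmenter veto
  # below the fraction cutoff the gate fails
  tiny <- matrix(0L, 64, 64); tiny[1, 1:10] <- 1L
  expect_false(consensusGate("tumor", tiny, 0.01)$pass)
})

test_that("region tagging uses the center pixel and partitions detections", {
  mask <- matrix(0L, 100, 100); mask[1:50, ] <- 1L
  det <- data.frame(x_min = c(10, 70), y_min = c(10, 10),
                    x_max = c(20, 80), y_max = c(20, 20),
                    class = c("tumor_pos", "immune_pos"))
  tagged <- assignCells(det, mask)
  expect_equal(tagged$region, c("inside_tumor", "outside_tumor"))
  # empty mask: everything outside
  all_out <- assignCells(det, matrix(0L, 100, 100))
  expect_true(all(all_out$region == "outside_tumor"))
  # center outside the slide errors
  bad <- data.frame(x_min = 95, y_min = 95, x_max = 120, y_max = 120,
                    class = "tumor_pos")
  expect_error(assignCells(bad, mask), "outside the slide")
})

test_that("proximity radius matches the 0.5 mm rule at scanner resolution", {
  expect_identical(proximityRadiusPx(500, 0.475), 1053L)
  expect_identical(proximityRadiusPx(500, 1), 500L)
  expect_error(proximityRadiusPx(500, 0), "mpp")
})

test_that("immune cells just inside/outside the dilated boundary are kept/excluded", {
  mask <- matrix(0L, 200, 200); mask[1:20, 1:200] <- 1L  # tumor slab at x<20
  # mpp 10 um/px makes the 500 um radius an exact 50 px band
  det <- data.frame(x_min = c(60, 78), y_min = c(100, 100),
                    x_max = c(68, 86), y_max = c(108, 108),
                    class = "immune_pos")
  # centers at x=64 (dist 45 <= 50: keep) and x=82 (dist 63 > 50: drop)
  kept <- proximityFilter(det, mask, radius_um = 500, mpp = 10)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x_min, 60)
  # a cell adjacent to the boundary is kept; one 2 mm away is excluded
  adj <- data.frame(x_min = 21, y_min = 1, x_max = 27, y_max = 7,
                    class = "immune_pos")
  expect_equal(nrow(proximityFilter(adj, mask, 500, mpp = 10)), 1)
  far <- data.frame(x_min = 190, y_min = 1, x_max = 198, y_max = 9,
                    class = "immune_pos")  # center 175 px from tumor = 1.75 mm
  expect_equal(nrow(proximityFilter(far, mask, 500, mpp = 10)), 0)
})

test_that("compute_cps matches the worked examples exactly", {
  r1 <- computeCps(c(n_tumor_pos = 50L, n_tumor_neg = 140L,
                     n_immune_pos = 10L))
  expect_equal(r1@cpsRaw, 100 * 60 / 190)
  expect_equal(cpsValue(r1), 31.57894736842105, tolerance = 1e-12)
  expect_equal(pdl1Call(r1), "positive")

  r2 <- computeCps(c(n_tumor_pos = 0L, n_tumor_neg = 200L,
                     n_immune_pos = 1L))
  expect_equal(cpsValue(r2), 0.5)
  expect_equal(pdl1Call(r2), "negative")

  r3 <- computeCps(c(n_tumor_pos = 300L, n_tumor_neg = 10L,
                     n_immune_pos = 50L))
  expect_equal(r3@cpsRaw, 100 * 350 / 310)
  expect_equal(cpsValue(r3), 100)  # capped
  r3u <- computeCps(c(n_tumor_pos = 300L, n_tumor_neg = 10L,
                      n_immune_pos = 50L), cap_at_100 = FALSE)
  expect_gt(cpsValue(r3u), 100)

  r4 <- computeCps(c(n_tumor_pos = 0L, n_tumor_neg = 0L, n_immune_pos = 5L))
  expect_equal(pdl1Call(r4), "not_evaluable")
  expect_equal(cpsStatus(r4), "no_tumor_cells")

  r5 <- computeCps(c(n_tumor_pos = 5L, n_tumor_neg = 20L, n_immune_pos = 2L))
  expect_equal(cpsStatus(r5), "insufficient_tumor_cells")
  expect_equal(r5@cpsRaw, 28)  # still computed
  expect_error(computeCps(c(n_tumor_pos = -1L, n_tumor_neg = 5L,
                            n_immune_pos = 0L)), "non-negative")
})

test_that("compute_cps equals the tally-and-divide oracle on 1000 random triples", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      pos <- sample(0:400, 1); neg <- sample(0:400, 1)
      imm <- sample(0:150, 1)
      got <- computeCps(c(n_tumor_pos = pos, n_tumor_neg = neg,
                          n_immune_pos = imm), cap_at_100 = FALSE,
                        min_tumor_cells = 0)
      want <- bruteCps(pos, neg, imm)
      if (!want$valid) {
        expect_equal(cpsStatus(got), "no_tumor_cells")
      } else {
        expect_identical(got@cpsRaw, want$cps)  # bit-exact
        expect_identical(got@numerator, as.integer(pos + imm))
        expect_identical(got@denominator, as.integer(pos + neg))
      }
    }
  })
})

test_that("CPS is monotone in each count, per the rational-arithmetic oracle", {
  withr::with_seed(31, {
    for (i in 1:100) {
      pos <- sample(1:200, 1); neg <- sample(1:200, 1)
      imm <- sample(0:80, 1)
      base <- computeCps(c(n_tumor_pos = pos, n_tumor_neg = neg,
                           n_immune_pos = imm), cap_at_100 = FALSE)
      up <- computeCps(c(n_tumor_pos = pos, n_tumor_neg = neg,
                         n_immune_pos = imm + 1L), cap_at_100 = FALSE)
      dn <- computeCps(c(n_tumor_pos = pos, n_tumor_neg = neg + 1L,
                         n_immune_pos = imm), cap_at_100 = FALSE)
      # adding one immune cell strictly increases:
      # (n+1)/d > n/d by cross multiplication
      expect_true(rationalLess(base@numerator, base@denominator,
                               up@numerator, up@denominator))
      expect_gt(up@cpsRaw, base@cpsRaw)
      # adding one negative tumor cell strictly decreases
      expect_true(rationalLess(dn@numerator, dn@denominator,
                               base@numerator, base@denominator))
      expect_lt(dn@cpsRaw, base@cpsRaw)
      # adding one positive tumor cell moves toward (n+1)/(d+1)
      pp <- computeCps(c(n_tumor_pos = pos + 1L, n_tumor_neg = neg,
                         n_immune_pos = imm), cap_at_100 = FALSE)
      if (base@cpsRaw < 100) expect_gt(pp@cpsRaw, base@cpsRaw)
    }
  })
})

test_that("aggregate counts equal an independent brute tally over detections", {
  sl <- fxSlide()
  cfg <- fxOracleConfig()
  sc <- scoreSlide(sl$slide, oracleModels(sl$truth), cfg)
  det <- sc$detections
  # independent tally straight off the tagged detection table
  gated <- tumorMaskFromScore <- NULL
  pos <- sum(det$class == "tumor_pos" & det$region == "inside_tumor")
  neg <- sum(det$class == "tumor_neg" & det$region == "inside_tumor")
  imm <- sum(det$class == "immune_pos" & det$kept)
  expect_identical(sc$counts,
                   c(n_tumor_pos = as.integer(pos),
                     n_tumor_neg = as.integer(neg),
                     n_immune_pos = as.integer(imm)))
})

test_that("oracle-model scoring recovers the true CPS exactly on every slide", {
  cfg <- fxOracleConfig()
  for (b in fxOracleCohort()$slides) {
    sc <- scoreSlide(b$slide, oracleModels(b$truth), cfg)
    tc <- trueCps(b$truth)
    expect_identical(sc$counts, trueCounts(b$truth))
    if (tc$valid) {
      expect_identical(sc$result@numerator, tc$numerator)
      expect_identical(sc$result@denominator, tc$denominator)
      expect_identical(sc$result@cpsRaw, tc$cps)
    } else {
      expect_equal(pdl1Call(sc$result), "not_evaluable")
    }
  }
})

test_that("a constant-tumor classifier makes gating vacuous", {
  b <- fxSlide()
  cfg <- fxOracleConfig()
  om <- oracleModels(b$truth)
  mc <- om; mc$classifier <- constantClassifier("tumor")
  gated <- scoreSlide(b$slide, mc, cfg)
  cfgU <- cfg; cfgU$bypass_classifier <- TRUE
  ungated <- scoreSlide(b$slide, om, cfgU)
  expect_identical(gated$counts, ungated$counts)
  expect_identical(cpsValue(gated$result), cpsValue(ungated$result))
  # and gating can only remove segmentation work
  real <- scoreSlide(b$slide, om, cfg)
  expect_lte(real$seg_invocations, ungated$seg_invocations)
})

test_that("gating halves segmentation work on small-tumor slides without changing calls", {
  cfg <- fxOracleConfig()
  co <- fxGatingCohort()
  bm <- benchmarkPipeline(co$slides, config = cfg, models_fn = oracleModels)
  expect_lte(bm$summary$seg_invocation_ratio, 0.5)
  expect_equal(bm$summary$call_agreement, 1)
  g <- bm$records[bm$records$arm == "gated", ]
  u <- bm$records[bm$records$arm == "ungated", ]
  expect_true(all(g$seg_invocations <= u$seg_invocations))
})

test_that("slide report echoes thresholds and separates timings", {
  sl <- fxSlide()
  sc <- scoreSlide(sl$slide, oracleModels(sl$truth), fxOracleConfig())
  dir <- withr::local_tempdir()
  writeSlideReport(sc, dir)
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$pd_l1_call, pdl1Call(sc$result))
  expect_equal(rep$thresholds$radius_um, 500)
  expect_null(rep$timings)
  expect_true(file.exists(file.path(dir, "timings.json")))
  expect_true(file.exists(file.path(dir, "detections.csv")))
  writeOverlayPng(sc, sl$slide, file.path(dir, "overlay.png"))
  ov <- readSlide(file.path(dir, "overlay.png"))
  expect_equal(dim(slideRaster(ov))[1:2], dim(slideRaster(sl$slide))[1:2])
})
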