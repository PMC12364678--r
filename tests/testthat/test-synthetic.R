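# synthetic slide generator: determinism, ground-truth consistency,
# export partitioning, cohort targeting

test_that("ground-truth CPS follows the formula, including degenerate cases", {
  sp <- synthParams(canvas_px = c(512, 512), n_tumor_pos = 50,
                    n_tumor_neg = 140, n_immune_pos = 10,
                    tumor_region_fraction = 0.6, seed = 2)
  sl <- generateSlide(sp)
  tc <- trueCps(sl$truth)
  expect_true(tc$valid)
  expect_equal(tc$cps, (50 + 10) / (50 + 140) * 100)
  expect_equal(tc$cps, 31.578947368, tolerance = 1e-9)

  empty <- generateSlide(synthParams(canvas_px = c(256, 256), n_tumor_pos = 0,
                                     n_tumor_neg = 0, n_immune_pos = 0,
                                     seed = 3))
  expect_false(trueCps(empty$truth)$valid)
  expect_true(is.na(trueCps(empty$truth)$cps))
})

test_that("identical seeds give bit-identical slides and ground truth", {
  sp <- synthParams(canvas_px = c(320, 320), n_tumor_pos = 15,
                    n_tumor_neg = 30, n_immune_pos = 8, seed = 99)
  a <- generateSlide(sp); b <- generateSlide(sp)
  expect_identical(slideRaster(a$slide), slideRaster(b$slide))
  expect_identical(cellTable(a$truth), cellTable(b$truth))
  expect_identical(tumorMask(a$truth), tumorMask(b$truth))
})

test_that("ground truth is internally consistent", {
  sl <- fxSlide()
  cells <- cellTable(sl$truth)
  d <- dim(slideRaster(sl$slide))
  # boxes inside canvas, consistent ordering
  expect_true(all(cells$x_min >= 0 & cells$y_min >= 0))
  expect_true(all(cells$x_max <= d[1] & cells$y_max <= d[2]))
  expect_true(all(cells$x_min < cells$x_max & cells$y_min < cells$y_max))
  # counts match the tally
  expect_identical(trueCounts(sl$truth),
                   c(n_tumor_pos = sum(cells$class == "tumor_pos"),
                     n_tumor_neg = sum(cells$class == "tumor_neg"),
                     n_immune_pos = sum(cells$class == "immune_pos")))
  # tumor-class cells only inside the tumor mask
  tcells <- cells[cells$class %in% c("tumor_pos", "tumor_neg"), ]
  expect_true(all(tcells$region == "inside_tumor"))
  # immune cells appear on both sides of the mask (configured split)
  icells <- cells[cells$class == "immune_pos", ]
  expect_true(any(icells$region == "inside_tumor"))
  expect_true(any(icells$region == "outside_tumor"))
})

test_that("rendered cell centers carry their class color signature", {
  sl <- fxCleanSlide()
  r <- slideRaster(sl$slide)
  cells <- cellTable(sl$truth)
  px <- floor(cells$cx) + 1L; py <- floor(cells$cy) + 1L
  rr <- r[cbind(px, py, 1L)]; bb <- r[cbind(px, py, 3L)]
  gg <- r[cbind(px, py, 2L)]
  blueish <- bb - (rr + gg) / 2 > 0.18   # counterstained nucleus
  brownish <- rr - bb > 0.25             # DAB-stained immune cell body
  okay <- ifelse(cells$class == "immune_pos", brownish, blueish)
  expect_gte(mean(okay), 0.99)
})

test_that("capacity failure names the limiting class", {
  sp <- synthParams(canvas_px = c(128, 128), n_tumor_pos = 0,
                    n_tumor_neg = 1000, n_immune_pos = 0,
                    tumor_region_fraction = 0.3, seed = 5)
  expect_error(generateSlide(sp), "tumor_neg|capacity")
})

test_that("patch export forms a 4x4 grid and partitions the cell list", {
  sl <- fxSlide()  # 512 x 512
  ex <- exportPatchDataset(sl$slide, sl$truth, 128)
  expect_equal(nrow(ex$manifest), 16)
  # every cell appears in exactly one patch (center rule: no loss, no dup)
  expect_equal(nrow(ex$boxes), nrow(cellTable(sl$truth)))
  for (cl in c("tumor_pos", "tumor_neg", "immune_pos")) {
    expect_equal(sum(ex$boxes$class == cl),
                 unname(trueCounts(sl$truth)[paste0("n_", cl)]))
  }
  # patches without tumor-cell centers are labeled non_tumor
  byPatch <- split(ex$boxes$class, ex$boxes$patch_id)
  for (i in seq_len(nrow(ex$manifest))) {
    pid <- ex$manifest$patch_id[i]
    hasTumor <- any(byPatch[[pid]] %in% c("tumor_pos", "tumor_neg"))
    expect_equal(ex$manifest$label[i],
                 if (hasTumor) "tumor" else "non_tumor")
  }
  small <- generateSlide(synthParams(canvas_px = c(256, 256),
                                     n_tumor_pos = 5, n_tumor_neg = 10,
                                     n_immune_pos = 2, seed = 8))
  expect_error(exportPatchDataset(sl$slide, small$truth, 128),
               "dimensions differ")
})

test_that("cohort targets are met within 0.5 CPS and span the cutoff", {
  counts <- solveCountsForCps(31.6, denominator = 190)
  v <- 100 * (counts[["n_tumor_pos"]] + counts[["n_immune_pos"]]) /
    (counts[["n_tumor_pos"]] + counts[["n_tumor_neg"]])
  expect_lt(abs(v - 31.6), 0.5)
  # integer search oracle: no count triple at this denominator does better
  # than the returned one by more than the rounding bound
  best <- Inf
  for (n in 0:(2 * 190)) best <- min(best, abs(100 * n / 190 - 31.6))
  expect_lte(abs(v - 31.6), best + 0.5)

  zero <- solveCountsForCps(0)
  expect_equal(zero[["n_tumor_pos"]], 0)
  expect_equal(zero[["n_immune_pos"]], 0)
  expect_gt(zero[["n_tumor_neg"]], 0)

  expect_error(solveCountsForCps(-5), "unattainable")

  co <- fxOracleCohort()
  expect_equal(nrow(co$manifest), 20)
  ok <- !is.na(co$manifest$target_cps)
  expect_true(all(abs(co$manifest$true_cps - co$manifest$target_cps)[ok] <= 0.5))
  expect_true(any(co$manifest$true_call == "positive"))
  expect_true(any(co$manifest$true_call == "negative"))
  # reproducible manifest
  co2 <- generateCohort(3, cps_targets = c(0, 0.5, 3), seed = 101,
                        denominator = 150,
                        params = synthParams(canvas_px = c(512, 512),
                                             tissue_fraction = 0.6,
                                             tumor_region_fraction = 0.5,
                                             seed = 1))
  expect_identical(co2$manifest, co$manifest[1:3, ])
})

test_that("slide bundles round-trip through disk", {
  sl <- fxCleanSlide()
  dir <- withr::local_tempdir()
  writeSlideBundle(sl, dir)
  back <- readSlideBundle(dir, slideId(sl$slide))
  expect_equal(mpp(back$slide), mpp(sl$slide))
  expect_identical(tumorMask(back$truth), tumorMask(sl$truth))
  expect_identical(trueCounts(back$truth), trueCounts(sl$truth))
  expect_equal(trueCps(back$truth)$cps, trueCps(sl$truth)$cps)
})
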