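#' Consensus gate for one tile
#'
#' A tile enters cell counting only when the patch classifier calls it
#' tumor AND the segmenter finds tumor pixels in it: the gate passes iff
#' the classifier label is \code{tumor}, the segmented tumor fraction is at
#' least \code{min_tumor_fraction}, and at least one tumor pixel exists
#' (so an empty mask is always a segmenter veto). On pass the segmentation
#' mask is returned; on fail an empty mask.
#'
#' @param cls_label classifier label (\code{tumor} / \code{non_tumor}).
#' @param seg_mask 0/1 tumor mask at patch resolution.
#' @param min_tumor_fraction minimum tumor-pixel fraction (default 0.01).
#' @return list with \code{pass} (flag) and \code{mask}.
#' @export
consensusGate <- function(cls_label, seg_mask, min_tumor_fraction = 0.01) {
  frac <- mean(seg_mask == 1L)
  pass <- identical(as.character(cls_label), "tumor") &&
    frac >= min_tumor_fraction && any(seg_mask == 1L)
  list(pass = pass,
       mask = if (pass) seg_mask else matrix(0L, nrow(seg_mask),
                                             ncol(seg_mask)))
}

#' Tag detections as inside or outside the tumor region
#'
#' Each detection is tagged by its box-center pixel's value in the
#' slide-level tumor mask (every detection gets exactly one tag). Centers
#' outside the slide error.
#'
#' @param detections data.frame with slide-coordinate boxes.
#' @param tumor_mask slide-level 0/1 mask (width x height).
#' @return \code{detections} with a \code{region} column
#'   (\code{inside_tumor} / \code{outside_tumor}).
#' @export
assignCells <- function(detections, tumor_mask) {
  if (!nrow(detections)) {
    detections$region <- character(0)
    return(detections)
  }
  cx <- floor((detections$x_min + detections$x_max) / 2)
  cy <- floor((detections$y_min + detections$y_max) / 2)
  if (any(cx < 0 | cy < 0 | cx >= nrow(tumor_mask) | cy >= ncol(tumor_mask)))
    .stopf("detection center outside the slide")
  detections$region <- ifelse(
    tumor_mask[cbind(cx + 1, cy + 1)] == 1L, "inside_tumor", "outside_tumor")
  detections
}

#' Proximity radius in pixels
#'
#' The 0.5 mm immune-cell proximity rule expressed at analysis scale:
#' \code{round(radius_um / mpp)} pixels (1053 px at 0.475 um/px).
#'
#' @param radius_um radius in microns (default 500 = 0.5 mm).
#' @param mpp microns per pixel (> 0).
#' @return integer pixel radius.
#' @export
proximityRadiusPx <- function(radius_um = 500, mpp) {
  if (!is.finite(mpp) || mpp <= 0) .stopf("mpp must be > 0")
  as.integer(round(radius_um / mpp))
}

#' Filter outside-tumor immune cells by proximity to tumor
#'
#' Keeps an outside-tumor immune detection iff its center lies within the
#' tumor mask dilated by the proximity radius — equivalently, iff its
#' center-to-nearest-tumor-pixel distance is at most
#' \code{round(radius_um / mpp)}. Implemented with a distance transform of
#' the mask complement (O(image), not O(cells x pixels)). Inside-tumor
#' immune cells are not subject to this rule and should not be passed here.
#'
#' @param immune_outside data.frame of outside-tumor immune detections in
#'   slide coordinates.
#' @param tumor_mask slide-level 0/1 tumor mask.
#' @param radius_um proximity radius in microns (default 500).
#' @param mpp microns per pixel.
#' @param dist precomputed distance map from \code{tumor_mask} (optional).
#' @return the kept subset of \code{immune_outside}.
#' @export
proximityFilter <- function(immune_outside, tumor_mask, radius_um = 500,
                            mpp, dist = NULL) {
  if (!nrow(immune_outside)) return(immune_outside)
  r <- proximityRadiusPx(radius_um, mpp)
  if (is.null(dist)) dist <- .distToMask(tumor_mask)
  cx <- floor((immune_outside$x_min + immune_outside$x_max) / 2)
  cy <- floor((immune_outside$y_min + immune_outside$y_max) / 2)
  keep <- dist[cbind(cx + 1, cy + 1)] <= r
  immune_outside[keep, , drop = FALSE]
}

#' Aggregate cell counts under the scoring rules
#'
#' PD-L1+/- tumor cells are counted only when their centers lie inside the
#' gated tumor region (necrosis never enters: it is excluded from the
#' tumor mask upstream); immune cells count when inside the tumor region,
#' or outside but within the proximity rule (the \code{kept_immune} set).
#' The tally is independent of patch processing order.
#'
#' @param detections region-tagged detections (\code{\link{assignCells}}).
#' @param kept_immune proximity-filtered outside-tumor immune detections
#'   (\code{\link{proximityFilter}}).
#' @return named integer vector \code{n_tumor_pos, n_tumor_neg,
#'   n_immune_pos}.
#' @export
aggregateCounts <- function(detections, kept_immune) {
  inside <- detections$region == "inside_tumor"
  counts <- c(
    n_tumor_pos = sum(detections$class == "tumor_pos" & inside),
    n_tumor_neg = sum(detections$class == "tumor_neg" & inside),
    n_immune_pos = sum(detections$class == "immune_pos" & inside) +
      nrow(kept_immune))
  storage.mode(counts) <- "integer"
  counts
}

#' Compute the Combined Positive Score from cell counts
#'
#' CPS = (PD-L1+ tumor cells + PD-L1+ immune cells) /
#' (PD-L1+ tumor cells + PD-L1- tumor cells) x 100, kept as an exact
#' integer ratio. A zero denominator gives status \code{no_tumor_cells}
#' and a \code{not_evaluable} call; a denominator below
#' \code{min_tumor_cells} flags \code{insufficient_tumor_cells} but still
#' reports the score. The reported value is capped at 100 when
#' \code{cap_at_100} (clinical reporting convention); the call is positive
#' iff the reported CPS is >= 1.
#'
#' @param counts named integer vector \code{n_tumor_pos, n_tumor_neg,
#'   n_immune_pos} (negative counts error).
#' @param cap_at_100 cap the reported CPS at 100 (default TRUE).
#' @param min_tumor_cells evaluability minimum for the denominator
#'   (default 100; flags, never suppresses the number).
#' @return a \linkS4class{CpsResult}.
#' @examples
#' computeCps(c(n_tumor_pos = 50, n_tumor_neg = 140, n_immune_pos = 10))
#' @export
computeCps <- function(counts, cap_at_100 = TRUE, min_tumor_cells = 100L) {
  counts <- counts[c("n_tumor_pos", "n_tumor_neg", "n_immune_pos")]
  if (any(is.na(counts))) .stopf("counts must be named and complete")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  counts <- stats::setNames(as.integer(counts),
                            c("n_tumor_pos", "n_tumor_neg", "n_immune_pos"))
  num <- counts[["n_tumor_pos"]] + counts[["n_immune_pos"]]
  den <- counts[["n_tumor_pos"]] + counts[["n_tumor_neg"]]
  if (den == 0L) {
    return(new("CpsResult", counts = counts, numerator = num,
               denominator = 0L, cpsRaw = NA_real_, cpsReported = NA_real_,
               status = "no_tumor_cells", call = "not_evaluable"))
  }
  raw <- 100 * num / den
  rep <- if (cap_at_100) min(raw, 100) else raw
  status <- if (den < min_tumor_cells) "insufficient_tumor_cells" else "valid"
  call <- if (status == "valid") {
    if (rep >= 1) "positive" else "negative"
  } else if (rep >= 1) "positive" else "negative"
  new("CpsResult", counts = counts, numerator = as.integer(num),
      denominator = as.integer(den), cpsRaw = raw, cpsReported = rep,
      status = status, call = call)
}

#' Score a slide end-to-end
#'
#' Runs the fully automated pipeline with no manual step: tissue
#' localization and tiling, patch classification, gated segmentation
#' (segmenter invoked only on classifier-positive tiles, unless
#' \code{bypass_classifier} reproduces the segmentation-only arm), the
#' consensus gate, cell detection over tissue tiles within the proximity
#' zone of the gated tumor region, region assignment, the 0.5 mm immune
#' proximity rule, count aggregation and the CPS.
#'
#' @param slide a \linkS4class{SlideImage} (must carry mpp).
#' @param models list with \code{classifier}, \code{segmenter},
#'   \code{detector} — trained handles or oracle stand-ins from
#'   \code{\link{oracleModels}}.
#' @param config a \code{\link{runConfig}} list.
#' @return list of class \code{slideScore}: \code{result}
#'   (\linkS4class{CpsResult}), \code{counts}, \code{grid}, \code{gate}
#'   (per-tile decisions), \code{detections} (slide coordinates, region
#'   tags, kept flag), \code{n_patches}, \code{seg_invocations},
#'   \code{det_invocations}, \code{arm}, \code{timings}, \code{config}.
#' @export
scoreSlide <- function(slide, models, config = runConfig()) {
  stopifnot(is(slide, "SlideImage"))
  if (!is.finite(mpp(slide)) || mpp(slide) <= 0)
    .stopf("slide has no valid mpp")
  config <- validateRunConfig(config)
  needed <- c(if (!config$bypass_classifier) "classifier",
              "segmenter", "detector")
  for (m in needed)
    if (is.null(models[[m]])) .stopf("missing model: %s", m)
  timings <- c(); tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  tm <- if (config$tissue_filter == "otsu") {
    tissueMask(slide, downsample = config$mask_downsample,
               fg_is_dark = config$fg_is_dark,
               min_object_px = config$min_object_px)
  } else NULL
  grid <- buildGrid(slide, tm, patch_px = config$patch_px,
                    min_tissue_fraction = config$min_tissue_fraction)
  tls <- tiles(grid)
  timings["preprocess"] <- tic() - t0

  d <- dim(slideRaster(slide)); W <- d[1]; H <- d[2]
  p <- config$patch_px
  getPatch <- function(i) .cropPatch(slideRaster(slide), tls$x[i], tls$y[i], p)

  t1 <- tic()
  arm <- if (config$bypass_classifier) "ungated" else "gated"
  clsLabels <- if (config$bypass_classifier || !nrow(tls)) {
    rep(NA_character_, nrow(tls))
  } else {
    .modelClassifyTiles(models$classifier, slide, tls, p, getPatch)
  }
  timings["classify"] <- tic() - t1

  t2 <- tic()
  segTarget <- if (config$bypass_classifier) seq_len(nrow(tls))
               else which(!is.na(clsLabels) & clsLabels == "tumor")
  gatedMask <- matrix(0L, W, H)
  gateTbl <- data.frame(row = tls$row, col = tls$col,
                        cls_label = if (nrow(tls)) clsLabels else character(0),
                        seg_fraction = NA_real_,
                        pass = FALSE)
  segInvocations <- 0L
  for (i in segTarget) {
    sm <- .modelSegment(models$segmenter, slide, tls[i, ], getPatch(i))
    segInvocations <- segInvocations + 1L
    gateLabel <- if (config$bypass_classifier) "tumor" else clsLabels[i]
    g <- consensusGate(gateLabel, sm, config$min_tumor_fraction)
    gateTbl$seg_fraction[i] <- mean(sm == 1L)
    gateTbl$pass[i] <- g$pass
    if (g$pass) {
      gatedMask[(tls$x[i] + 1L):(tls$x[i] + p),
                (tls$y[i] + 1L):(tls$y[i] + p)] <- g$mask
    }
  }
  timings["segment"] <- tic() - t2

  t3 <- tic()
  distMap <- .distToMask(gatedMask)
  radiusPx <- proximityRadiusPx(config$radius_um, mpp(slide))
  # detector runs on tissue tiles intersecting the proximity zone of the
  # gated tumor region (a superset of consensus tiles), so peritumoral
  # immune cells in wholly non-tumor tiles stay countable
  detTarget <- which(vapply(seq_len(nrow(tls)), function(i) {
    any(distMap[(tls$x[i] + 1L):(tls$x[i] + p),
                (tls$y[i] + 1L):(tls$y[i] + p)] <= radiusPx)
  }, logical(1)))
  detections <- NULL
  detInvocations <- 0L
  for (i in detTarget) {
    det <- .modelDetect(models$detector, slide, tls[i, ], getPatch(i),
                        config$conf_threshold, config$nms_iou)
    detInvocations <- detInvocations + 1L
    if (nrow(det)) {
      det$x_min <- det$x_min + tls$x[i]; det$x_max <- det$x_max + tls$x[i]
      det$y_min <- det$y_min + tls$y[i]; det$y_max <- det$y_max + tls$y[i]
      det$tile_row <- tls$row[i]; det$tile_col <- tls$col[i]
      detections <- rbind(detections, det)
    }
  }
  if (is.null(detections)) {
    detections <- data.frame(x_min = integer(0), y_min = integer(0),
                             x_max = integer(0), y_max = integer(0),
                             class = character(0), confidence = numeric(0),
                             tile_row = integer(0), tile_col = integer(0))
  }
  timings["detect"] <- tic() - t3

  t4 <- tic()
  rownames(detections) <- NULL
  detections <- assignCells(detections, gatedMask)
  immuneOut <- detections[detections$class == "immune_pos" &
                            detections$region == "outside_tumor", ,
                          drop = FALSE]
  keptImmune <- proximityFilter(immuneOut, gatedMask,
                                radius_um = config$radius_um,
                                mpp = mpp(slide), dist = distMap)
  kept <- detections$region == "inside_tumor"
  kept[as.integer(rownames(keptImmune))] <- TRUE
  detections$kept <- kept
  counts <- aggregateCounts(detections, keptImmune)
  result <- computeCps(counts, cap_at_100 = config$cap_at_100,
                       min_tumor_cells = config$min_tumor_cells)
  timings["score"] <- tic() - t4
  timings["total"] <- tic() - t0

  structure(list(
    slide_id = slideId(slide), mpp = mpp(slide), result = result,
    counts = counts, grid = grid, gate = gateTbl, detections = detections,
    gated_mask = gatedMask,
    n_patches = list(total = nrow(tiles(grid, keptOnly = FALSE)),
                     tissue = nrow(tls),
                     classifier_positive = sum(!is.na(clsLabels) &
                                                 clsLabels == "tumor"),
                     consensus = sum(gateTbl$pass),
                     detector = length(detTarget)),
    seg_invocations = segInvocations, det_invocations = detInvocations,
    arm = arm, radius_px = radiusPx, timings = as.list(timings),
    config = config), class = "slideScore")
}

#' Write a scoring overlay image
#'
#' Renders the slide with the gated tumor region outlined and each counted
#' detection marked by a class-colored box (PD-L1+ tumor red, PD-L1- tumor
#' blue, immune green; uncounted detections dimmed), for visual review of
#' a \code{\link{scoreSlide}} result.
#'
#' @param score a \code{\link{scoreSlide}} result.
#' @param slide the scored \linkS4class{SlideImage}.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeOverlayPng <- function(score, slide, path) {
  r <- slideRaster(slide)
  W <- dim(r)[1]; H <- dim(r)[2]
  # gated tumor contour: mask minus its erosion
  gm <- score$gated_mask
  edge <- gm - .erodeMask(gm, 2L)
  r <- .paintColor(r, edge == 1L, c(0.1, 0.1, 0.1))
  pal <- list(tumor_pos = c(0.9, 0.1, 0.1), tumor_neg = c(0.1, 0.2, 0.9),
              immune_pos = c(0.1, 0.7, 0.2))
  det <- score$detections
  for (k in seq_len(nrow(det))) {
    col <- pal[[det$class[k]]]
    if (!isTRUE(det$kept[k])) col <- 0.5 * col + 0.5
    xs <- (det$x_min[k] + 1L):min(W, det$x_max[k])
    ys <- (det$y_min[k] + 1L):min(H, det$y_max[k])
    for (ch in 1:3) {
      r[xs, c(ys[1], ys[length(ys)]), ch] <- col[ch]
      r[c(xs[1], xs[length(xs)]), ys, ch] <- col[ch]
    }
  }
  EBImage::writeImage(EBImage::Image(r, colormode = "Color"), path)
  invisible(path)
}

#' Write the per-slide scoring report
#'
#' Writes \code{report.json} (identifiers, counts, CPS, status, call,
#' patch-stage counts and every threshold used — byte-stable across reruns
#' of the same configuration), \code{timings.json} (wall times, kept
#' separate so reports are reproducible), and \code{detections.csv} /
#' \code{grid.csv}.
#'
#' @param score a \code{\link{scoreSlide}} result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSlideReport <- function(score, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- score$result
  .writeJson(list(
    slide_id = score$slide_id, mpp = score$mpp, arm = score$arm,
    counts = as.list(score$counts),
    cps_raw = if (is.na(res@cpsRaw)) NULL else res@cpsRaw,
    cps_reported = if (is.na(res@cpsReported)) NULL else res@cpsReported,
    numerator = res@numerator, denominator = res@denominator,
    status = res@status, pd_l1_call = res@call,
    n_patches = score$n_patches,
    seg_invocations = score$seg_invocations,
    det_invocations = score$det_invocations,
    thresholds = score$config[c("patch_px", "mask_downsample",
                                "tissue_filter", "min_tissue_fraction",
                                "min_tumor_fraction", "conf_threshold",
                                "nms_iou", "cap_at_100", "min_tumor_cells",
                                "radius_um", "bypass_classifier")]),
    file.path(dir, "report.json"))
  .writeJson(score$timings, file.path(dir, "timings.json"))
  det <- score$detections
  det$slide_id <- score$slide_id
  writeCellCsv(det, file.path(dir, "detections.csv"))
  writeTileGrid(score$grid, score$slide_id, file.path(dir, "grid.csv"))
  invisible(dir)
}
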