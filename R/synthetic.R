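#' Parameters for the synthetic IHC slide generator
#'
#' Builds the parameter set for \code{\link{generateSlide}}. The generator
#' emulates a 22C3-style PD-L1 IHC field at 20x (0.475 um/px): a tissue
#' blob of counterstained stroma containing a tumor bed, brown-membrane
#' PD-L1+ tumor cells, counterstained PD-L1- tumor cells, small round brown
#' PD-L1+ immune cells, plus distractor structures (textured necrosis
#' excluded from the tumor mask, ring-shaped normal glands outside it).
#' Cells are ellipses with a class-specific fill and, for PD-L1+ classes, a
#' brown membrane ring; immune cells are smaller and rounder than tumor
#' cells, giving detectors a learnable morphological signal.
#'
#' @param canvas_px integer pair (width, height) in pixels.
#' @param mpp microns per pixel (default 0.475, a 20x scan).
#' @param n_tumor_pos,n_tumor_neg,n_immune_pos requested cell counts.
#' @param tissue_fraction fraction of the canvas covered by tissue
#'   (values above 0.7 render edge-to-edge tissue).
#' @param tumor_region_fraction fraction of the tissue area occupied by the
#'   tumor bed, in [0, 1].
#' @param immune_inside_fraction fraction of immune cells placed inside the
#'   tumor bed (the rest go to peritumoral stroma).
#' @param necrosis,glands render the distractor structures?
#' @param weak_fraction fraction of PD-L1+ cells rendered with reduced
#'   chroma (weak staining, a documented source of scoring inconsistency).
#' @param noise_sd additive Gaussian pixel noise (on the [0, 1] scale).
#' @param color_jitter per-cell stain color jitter (0 disables).
#' @param stain_palette named list of mean RGB colors (positive membrane
#'   brown, counterstain blue, background, stroma, tumor_bed, necrosis,
#'   gland).
#' @param tumor_radius_px,immune_radius_px min/max ellipse radii in px.
#' @param membrane_px membrane ring thickness for PD-L1+ tumor cells.
#' @param min_spacing_px minimum gap between cell boundaries.
#' @param slide_id identifier written into outputs.
#' @param seed integer RNG seed; identical seeds give bit-identical slides.
#' @return a validated list of class \code{synthParams}.
#' @export
synthParams <- function(canvas_px = c(1024L, 1024L),
                        mpp = 0.475,
                        n_tumor_pos = 120L,
                        n_tumor_neg = 280L,
                        n_immune_pos = 50L,
                        tissue_fraction = 0.55,
                        tumor_region_fraction = 0.35,
                        immune_inside_fraction = 0.5,
                        necrosis = TRUE,
                        glands = TRUE,
                        weak_fraction = 0.05,
                        noise_sd = 0.02,
                        color_jitter = 0.02,
                        stain_palette = list(
                          positive     = c(0.55, 0.33, 0.12),
                          counterstain = c(0.26, 0.28, 0.62),
                          background   = c(0.96, 0.96, 0.97),
                          stroma       = c(0.93, 0.82, 0.87),
                          tumor_bed    = c(0.86, 0.76, 0.89),
                          necrosis     = c(0.62, 0.52, 0.42),
                          gland        = c(0.58, 0.48, 0.76)),
                        tumor_radius_px = c(3.5, 5),
                        immune_radius_px = c(1.5, 2.5),
                        membrane_px = 1.5,
                        min_spacing_px = 3,
                        slide_id = "synth",
                        seed = 1L) {
  p <- list(canvas_px = as.integer(canvas_px), mpp = mpp,
            n_tumor_pos = as.integer(n_tumor_pos),
            n_tumor_neg = as.integer(n_tumor_neg),
            n_immune_pos = as.integer(n_immune_pos),
            tissue_fraction = tissue_fraction,
            tumor_region_fraction = tumor_region_fraction,
            immune_inside_fraction = immune_inside_fraction,
            necrosis = isTRUE(necrosis), glands = isTRUE(glands),
            weak_fraction = weak_fraction, noise_sd = noise_sd,
            color_jitter = color_jitter, stain_palette = stain_palette,
            tumor_radius_px = tumor_radius_px,
            immune_radius_px = immune_radius_px,
            membrane_px = membrane_px, min_spacing_px = min_spacing_px,
            slide_id = slide_id, seed = as.integer(seed))
  if (length(p$canvas_px) != 2L || any(p$canvas_px < 64L))
    .stopf("canvas_px must be a pair of integers >= 64")
  if (!is.finite(p$mpp) || p$mpp <= 0) .stopf("mpp must be > 0")
  if (any(c(p$n_tumor_pos, p$n_tumor_neg, p$n_immune_pos) < 0L))
    .stopf("cell counts must be >= 0")
  if (p$tumor_region_fraction < 0 || p$tumor_region_fraction > 1)
    .stopf("tumor_region_fraction must be in [0, 1]")
  if (p$tissue_fraction <= 0 || p$tissue_fraction > 1)
    .stopf("tissue_fraction must be in (0, 1]")
  if (p$weak_fraction < 0 || p$weak_fraction > 1)
    .stopf("weak_fraction must be in [0, 1]")
  class(p) <- "synthParams"
  p
}

# ellipse mask with target area frac*W*H, jittered center/aspect; snaps to the
# full canvas above the largest inscribable ellipse (~0.72 of the canvas)
.tissueRegion <- function(W, H, frac) {
  if (frac > 0.70) {
    return(matrix(1L, W, H))
  }
  A <- frac * W * H
  q <- stats::runif(1, 0.75, 1.25)
  a <- sqrt(A * q / pi); b <- A / (pi * a)
  a <- min(a, 0.48 * W); b <- min(A / (pi * a), 0.48 * H)
  cx <- (W - 1) / 2 + stats::runif(1, -0.03, 0.03) * W
  cy <- (H - 1) / 2 + stats::runif(1, -0.03, 0.03) * H
  .paintEllipse(matrix(0L, W, H), cx, cy, a, b)
}

.subEllipse <- function(region, frac, qrange = c(0.75, 1.25), jitter = 0.25) {
  if (frac <= 0 || !any(region == 1L)) {
    return(matrix(0L, nrow(region), ncol(region)))
  }
  if (frac >= 0.999) return(region)
  A <- frac * sum(region)
  idx <- which(region == 1L, arr.ind = TRUE)
  cx0 <- mean(idx[, 1]) - 1; cy0 <- mean(idx[, 2]) - 1
  spanx <- diff(range(idx[, 1])); spany <- diff(range(idx[, 2]))
  q <- stats::runif(1, qrange[1], qrange[2])
  a <- sqrt(A * q / pi); b <- A / (pi * a)
  cx <- cx0 + stats::runif(1, -jitter, jitter) * max(0, spanx / 2 - a)
  cy <- cy0 + stats::runif(1, -jitter, jitter) * max(0, spany / 2 - b)
  m <- .paintEllipse(matrix(0L, nrow(region), ncol(region)), cx, cy, a, b)
  m * region
}

# sequential random placement with pairwise spacing; R is the per-cell
# outer radius (ellipse max semi-axis + membrane)
.placeCells <- function(eligible, n, rmin, rmax, spacing, what,
                        existing = NULL) {
  if (n == 0L) {
    return(data.frame(cx = numeric(0), cy = numeric(0),
                      rx = numeric(0), ry = numeric(0)))
  }
  idx <- which(eligible == 1L)
  if (length(idx) == 0L)
    .stopf("cannot place %d %s cells: no eligible area", n, what)
  W <- nrow(eligible)
  ox <- if (is.null(existing)) numeric(0) else existing$cx
  oy <- if (is.null(existing)) numeric(0) else existing$cy
  oR <- if (is.null(existing)) numeric(0) else existing$R
  cx <- cy <- rx <- ry <- numeric(n)
  placed <- 0L
  tries <- 0L; maxTries <- 200L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      .stopf(paste0("placement capacity exceeded for %s cells: placed %d of ",
                    "%d requested; reduce the count or enlarge the region"),
             what, placed, n)
    i <- idx[sample.int(length(idx), 1L)]
    px <- (i - 1L) %% W; py <- (i - 1L) %/% W
    H <- ncol(eligible)
    jx <- min(max(px + stats::runif(1) - 0.5, 0.01), W - 1.01)
    jy <- min(max(py + stats::runif(1) - 0.5, 0.01), H - 1.01)
    r1 <- stats::runif(1, rmin, rmax); r2 <- stats::runif(1, rmin, rmax)
    R <- max(r1, r2)
    allx <- c(ox, cx[seq_len(placed)]); ally <- c(oy, cy[seq_len(placed)])
    allR <- c(oR, pmax(rx, ry)[seq_len(placed)])
    if (length(allx)) {
      d2 <- (allx - jx)^2 + (ally - jy)^2
      if (any(d2 < (allR + R + spacing)^2)) next
    }
    placed <- placed + 1L
    cx[placed] <- jx; cy[placed] <- jy; rx[placed] <- r1; ry[placed] <- r2
  }
  data.frame(cx = cx, cy = cy, rx = rx, ry = ry)
}

# render one ellipse cell; returns the raster
.renderCell <- function(raster, cx, cy, rx, ry, fill, ring = NULL,
                        ring_px = 0) {
  W <- dim(raster)[1]; H <- dim(raster)[2]
  Rx <- rx + ring_px; Ry <- ry + ring_px
  xs <- max(0L, floor(cx - Rx)):min(W - 1L, ceiling(cx + Rx))
  ys <- max(0L, floor(cy - Ry)):min(H - 1L, ceiling(cy + Ry))
  eIn <- outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, `+`)
  inside <- eIn <= 1
  for (ch in 1:3) {
    sub <- raster[xs + 1L, ys + 1L, ch]
    if (!is.null(ring)) {
      eOut <- outer(((xs - cx) / Rx)^2, ((ys - cy) / Ry)^2, `+`)
      sub[eOut <= 1 & !inside] <- ring[ch]
    }
    sub[inside] <- fill[ch]
    raster[xs + 1L, ys + 1L, ch] <- sub
  }
  raster
}

#' Generate one synthetic IHC slide with exact ground truth
#'
#' Renders the slide described by \code{params} and returns both the image
#' and its \linkS4class{SlideGroundTruth}. Tumor cells (both classes) are
#' placed only inside the tumor mask; immune cells are split between the
#' tumor bed and peritumoral stroma; necrosis and gland distractors never
#' intersect the tumor mask. Identical seeds give bit-identical output.
#' If the requested counts cannot be placed without overlap, a capacity
#' error names the limiting class.
#'
#' @param params a \code{\link{synthParams}} object.
#' @return list with elements \code{slide} (\linkS4class{SlideImage}) and
#'   \code{truth} (\linkS4class{SlideGroundTruth}).
#' @examples
#' sp <- synthParams(canvas_px = c(256, 256), n_tumor_pos = 10,
#'                   n_tumor_neg = 25, n_immune_pos = 5, seed = 7)
#' sl <- generateSlide(sp)
#' trueCps(sl$truth)$cps
#' @export
generateSlide <- function(params) {
  stopifnot(inherits(params, "synthParams"))
  .withSeed(params$seed, .generateSlideImpl(params))
}

.generateSlideImpl <- function(params) {
  W <- params$canvas_px[1]; H <- params$canvas_px[2]
  pal <- params$stain_palette
  tissue <- .tissueRegion(W, H, params$tissue_fraction)
  tumor0 <- .subEllipse(tissue, params$tumor_region_fraction)

  # distractors
  necro <- matrix(0L, W, H); gland <- matrix(0L, W, H)
  if (params$necrosis && sum(tumor0) > 4000) {
    core <- .erodeMask(tumor0, 12L)
    if (any(core == 1L)) {
      r <- 0.09 * sqrt(sum(tumor0))
      i <- which(core == 1L)[sample.int(sum(core), 1L)]
      necro <- .paintEllipse(necro, (i - 1L) %% W, (i - 1L) %/% W,
                             r * stats::runif(1, 0.8, 1.2),
                             r * stats::runif(1, 0.8, 1.2))
      necro <- necro * tumor0
    }
  }
  if (params$glands) {
    outside <- tissue * (1L - tumor0)
    elig <- .erodeMask(outside, 20L)
    ng <- if (any(elig == 1L)) 2L else 0L
    gcent <- NULL
    for (k in seq_len(ng)) {
      idx <- which(elig == 1L)
      if (!length(idx)) break
      i <- idx[sample.int(length(idx), 1L)]
      gx <- (i - 1L) %% W; gy <- (i - 1L) %/% W
      if (!is.null(gcent) && any((gcent[, 1] - gx)^2 + (gcent[, 2] - gy)^2 < 40^2))
        next
      gcent <- rbind(gcent, c(gx, gy))
      r <- stats::runif(1, 10, 15)
      ring <- .paintEllipse(matrix(0L, W, H), gx, gy, r, r) -
        .paintEllipse(matrix(0L, W, H), gx, gy, r - 3, r - 3)
      gland[ring == 1L] <- 1L
    }
  }
  glandFull <- if (any(gland == 1L)) {
    EBImage::imageData(EBImage::fillHull(EBImage::Image(gland)))
  } else gland
  storage.mode(glandFull) <- "integer"

  tumorMask <- tumor0 * (1L - necro) * (1L - glandFull)

  # paint regions
  raster <- array(rep(pal$background, each = W * H), dim = c(W, H, 3))
  raster <- .paintColor(raster, tissue == 1L, pal$stroma)
  raster <- .paintColor(raster, tumor0 == 1L, pal$tumor_bed)
  if (any(necro == 1L)) {
    raster <- .paintColor(raster, necro == 1L, pal$necrosis)
    # granular debris texture
    speck <- matrix(stats::rnorm(W * H, 0, 0.07), W, H)
    for (ch in 1:3) {
      plane <- raster[, , ch]
      plane[necro == 1L] <- .clip01(plane[necro == 1L] + speck[necro == 1L])
      raster[, , ch] <- plane
    }
  }
  if (any(gland == 1L)) {
    raster <- .paintColor(raster, gland == 1L, pal$gland)
    lumen <- glandFull * (1L - gland)
    raster <- .paintColor(raster, lumen == 1L,
                          .clip01(pal$background - 0.02))
  }

  # cell placement
  tr <- params$tumor_radius_px; ir <- params$immune_radius_px
  marginT <- ceiling(tr[2] + params$membrane_px) + 2L
  marginI <- ceiling(ir[2]) + 2L
  eligT <- .shrinkBorder(.erodeMask(tumorMask, marginT), marginT)
  nT <- params$n_tumor_pos + params$n_tumor_neg
  if (nT > 0L && !any(eligT == 1L))
    .stopf("cannot place %d tumor cells: tumor region too small or absent", nT)
  nIn <- round(params$n_immune_pos * params$immune_inside_fraction)
  if (sum(tumorMask) == 0L) nIn <- 0L
  nOut <- params$n_immune_pos - nIn
  outsideMask <- tissue * (1L - tumor0) * (1L - glandFull)
  eligI_in <- .shrinkBorder(.erodeMask(tumorMask, marginI), marginI)
  eligI_out <- .shrinkBorder(.erodeMask(outsideMask, marginI), marginI)
  if (nOut > 0L && !any(eligI_out == 1L))
    .stopf("cannot place %d immune cells outside the tumor: no eligible area",
           nOut)

  sp <- params$min_spacing_px
  cellsTP <- .placeCells(eligT, params$n_tumor_pos, tr[1], tr[2], sp,
                         "tumor_pos")
  acc <- data.frame(cx = cellsTP$cx, cy = cellsTP$cy,
                    R = pmax(cellsTP$rx, cellsTP$ry) + params$membrane_px)
  cellsTN <- .placeCells(eligT, params$n_tumor_neg, tr[1], tr[2], sp,
                         "tumor_neg", existing = acc)
  acc <- rbind(acc, data.frame(cx = cellsTN$cx, cy = cellsTN$cy,
                               R = pmax(cellsTN$rx, cellsTN$ry)))
  cellsIPin <- .placeCells(eligI_in, nIn, ir[1], ir[2], sp, "immune_pos",
                           existing = acc)
  acc <- rbind(acc, data.frame(cx = cellsIPin$cx, cy = cellsIPin$cy,
                               R = pmax(cellsIPin$rx, cellsIPin$ry)))
  cellsIPout <- .placeCells(eligI_out, nOut, ir[1], ir[2], sp, "immune_pos",
                            existing = acc)

  jit <- function(col) {
    if (params$color_jitter <= 0) return(col)
    .clip01(col + stats::runif(3, -params$color_jitter, params$color_jitter))
  }
  weakMix <- function(col, base) 0.5 * col + 0.5 * base

  buildRows <- function(df, cls, ringed, ring_px) {
    n <- nrow(df)
    if (!n) return(NULL)
    weak <- if (cls %in% c("tumor_pos", "immune_pos")) {
      stats::runif(n) < params$weak_fraction
    } else rep(FALSE, n)
    data.frame(cx = df$cx, cy = df$cy, rx = df$rx, ry = df$ry,
               class = cls, weak = weak, ring_px = ring_px,
               stringsAsFactors = FALSE)
  }
  allCells <- rbind(
    buildRows(cellsTP, "tumor_pos", TRUE, params$membrane_px),
    buildRows(cellsTN, "tumor_neg", FALSE, 0),
    buildRows(rbind(cellsIPin, cellsIPout), "immune_pos", FALSE, 0))

  if (!is.null(allCells) && nrow(allCells)) {
    for (k in seq_len(nrow(allCells))) {
      cl <- allCells[k, ]
      if (cl$class == "tumor_pos") {
        ring <- jit(pal$positive)
        if (cl$weak) ring <- weakMix(ring, pal$tumor_bed)
        raster <- .renderCell(raster, cl$cx, cl$cy, cl$rx, cl$ry,
                              fill = jit(pal$counterstain), ring = ring,
                              ring_px = cl$ring_px)
      } else if (cl$class == "tumor_neg") {
        raster <- .renderCell(raster, cl$cx, cl$cy, cl$rx, cl$ry,
                              fill = jit(pal$counterstain))
      } else {
        fill <- jit(pal$positive)
        if (cl$weak) fill <- weakMix(fill, pal$stroma)
        raster <- .renderCell(raster, cl$cx, cl$cy, cl$rx, cl$ry, fill = fill)
      }
    }
  }

  if (params$noise_sd > 0) {
    raster <- .clip01(raster + stats::rnorm(length(raster), 0,
                                            params$noise_sd))
  }

  # ground truth table: half-open boxes covering the rendered extent
  if (is.null(allCells) || !nrow(allCells)) {
    cells <- data.frame(slide_id = character(0), class = character(0),
                        cx = numeric(0), cy = numeric(0),
                        x_min = integer(0), y_min = integer(0),
                        x_max = integer(0), y_max = integer(0),
                        region = character(0), weak = logical(0))
  } else {
    # tight half-open box over the rendered extent: pixels x with
    # |x - cx| <= Rx are exactly ceiling(cx - Rx) .. floor(cx + Rx)
    Rx <- allCells$rx + allCells$ring_px; Ry <- allCells$ry + allCells$ring_px
    x_min <- pmax(0L, as.integer(ceiling(allCells$cx - Rx)))
    y_min <- pmax(0L, as.integer(ceiling(allCells$cy - Ry)))
    x_max <- pmin(W, as.integer(floor(allCells$cx + Rx)) + 1L)
    y_max <- pmin(H, as.integer(floor(allCells$cy + Ry)) + 1L)
    px <- as.integer(floor(allCells$cx)); py <- as.integer(floor(allCells$cy))
    region <- ifelse(tumorMask[cbind(px + 1L, py + 1L)] == 1L,
                     "inside_tumor", "outside_tumor")
    cells <- data.frame(slide_id = params$slide_id, class = allCells$class,
                        cx = allCells$cx, cy = allCells$cy,
                        x_min = x_min, y_min = y_min,
                        x_max = x_max, y_max = y_max,
                        region = region, weak = allCells$weak,
                        stringsAsFactors = FALSE)
  }

  counts <- c(n_tumor_pos = sum(cells$class == "tumor_pos"),
              n_tumor_neg = sum(cells$class == "tumor_neg"),
              n_immune_pos = sum(cells$class == "immune_pos"))
  storage.mode(counts) <- "integer"
  num <- counts[["n_tumor_pos"]] + counts[["n_immune_pos"]]
  den <- counts[["n_tumor_pos"]] + counts[["n_tumor_neg"]]
  trueCps <- list(numerator = num, denominator = den,
                  cps = if (den > 0L) 100 * num / den else NA_real_,
                  valid = den > 0L)

  slide <- new("SlideImage", raster = raster, mpp = params$mpp,
               slideId = params$slide_id)
  truth <- new("SlideGroundTruth", tumorMask = tumorMask, cells = cells,
               trueCounts = counts, trueCps = trueCps)
  list(slide = slide, truth = truth)
}

#' Export a labeled patch dataset from a slide and its ground truth
#'
#' Tiles the slide into non-overlapping \code{patch_px} patches (row-major,
#' edge remainders dropped) and emits, per patch: the image crop, the
#' tumor-mask crop, the patch label (\code{tumor} iff at least one
#' ground-truth tumor-class cell center pixel falls in the patch, half-open
#' grid) and the cell boxes remapped to patch coordinates (clipped at patch
#' borders; a cell belongs to the unique patch containing its center pixel).
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param truth the matching \linkS4class{SlideGroundTruth}.
#' @param patch_px patch side in pixels.
#' @param dir optional output directory; when given, patches/masks are
#'   written as PNG and annotations as CSV.
#' @return list with \code{manifest} (patch table), \code{patches} (list of
#'   arrays), \code{masks} (list of matrices), \code{boxes} (data.frame of
#'   per-patch cell boxes with \code{patch_id} and patch-local coordinates).
#' @export
exportPatchDataset <- function(slide, truth, patch_px, dir = NULL) {
  d <- dim(slideRaster(slide))
  if (!all(d[1:2] == dim(tumorMask(truth))))
    .stopf("slide and ground truth dimensions differ")
  p <- as.integer(patch_px)
  nx <- d[1] %/% p; ny <- d[2] %/% p
  if (nx < 1L || ny < 1L) .stopf("patch_px larger than the canvas")
  cells <- cellTable(truth)
  cpx <- as.integer(floor(cells$cx)); cpy <- as.integer(floor(cells$cy))
  manifest <- NULL; patches <- list(); masks <- list(); boxes <- NULL
  k <- 0L
  for (row in 0:(ny - 1L)) {
    for (col in 0:(nx - 1L)) {
      k <- k + 1L
      x <- col * p; y <- row * p
      sel <- cpx >= x & cpx < x + p & cpy >= y & cpy < y + p
      tumorCell <- any(sel & cells$class %in% c("tumor_pos", "tumor_neg"))
      pid <- sprintf("%s_r%03d_c%03d", slideId(slide), row, col)
      manifest <- rbind(manifest, data.frame(
        patch_id = pid, slide_id = slideId(slide), row = row, col = col,
        x = x, y = y, label = if (tumorCell) "tumor" else "non_tumor",
        n_cells = sum(sel), stringsAsFactors = FALSE))
      patches[[pid]] <- .cropPatch(slideRaster(slide), x, y, p)
      masks[[pid]] <- .cropMask(tumorMask(truth), x, y, p)
      if (any(sel)) {
        b <- cells[sel, , drop = FALSE]
        boxes <- rbind(boxes, data.frame(
          patch_id = pid, slide_id = slideId(slide),
          x_min = pmax(0L, b$x_min - x), y_min = pmax(0L, b$y_min - y),
          x_max = pmin(p, b$x_max - x), y_max = pmin(p, b$y_max - y),
          class = b$class, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(boxes)) {
    boxes <- data.frame(patch_id = character(0), slide_id = character(0),
                        x_min = integer(0), y_min = integer(0),
                        x_max = integer(0), y_max = integer(0),
                        class = character(0))
  }
  out <- list(manifest = manifest, patches = patches, masks = masks,
              boxes = boxes, patch_px = p)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in manifest$patch_id) {
      EBImage::writeImage(EBImage::Image(patches[[pid]],
                                         colormode = "Color"),
                          file.path(dir, paste0(pid, ".png")))
      EBImage::writeImage(EBImage::Image(masks[[pid]]),
                          file.path(dir, paste0(pid, "_mask.png")))
    }
    utils::write.csv(manifest, file.path(dir, "patches.csv"),
                     row.names = FALSE)
    utils::write.csv(boxes, file.path(dir, "boxes.csv"), row.names = FALSE)
  }
  out
}

#' Solve integer cell counts approximating a target CPS
#'
#' Finds counts (n_tumor_pos, n_tumor_neg, n_immune_pos) whose CPS
#' \code{100 * (pos + imm) / (pos + neg)} is within \code{tol} of the target.
#'
#' @param target desired CPS (>= 0).
#' @param denominator desired viable-tumor-cell count (pos + neg).
#' @param immune_share fraction of the numerator carried by immune cells.
#' @param tol maximum absolute deviation from the target (default 0.5).
#' @return named integer vector of the three counts.
#' @export
solveCountsForCps <- function(target, denominator = 190L,
                              immune_share = 0.25, tol = 0.5) {
  if (!is.finite(target) || target < 0)
    .stopf("unattainable CPS target: %s", format(target))
  d0 <- as.integer(denominator)
  best <- NULL; bestErr <- Inf
  for (d in max(10L, d0 - 40L):(d0 + 40L)) {
    n <- round(target * d / 100)
    err <- abs(100 * n / d - target)
    pref <- abs(d - d0)
    if (err < bestErr - 1e-12 ||
        (abs(err - bestErr) < 1e-12 && !is.null(best) && pref < best$pref)) {
      best <- list(n = n, d = d, pref = pref); bestErr <- err
    }
  }
  if (bestErr > tol)
    .stopf("CPS target %s unattainable within +/-%s at denominator ~%d",
           format(target), format(tol), d0)
  n <- best$n; d <- best$d
  imm <- if (target == 0) 0L else as.integer(round(immune_share * n))
  pos <- n - imm
  if (pos > d) { imm <- imm + (pos - d); pos <- d }
  if (pos < 0L) { imm <- imm + pos; pos <- 0L }
  c(n_tumor_pos = as.integer(pos), n_tumor_neg = as.integer(d - pos),
    n_immune_pos = as.integer(imm))
}

#' Generate a cohort of synthetic slides
#'
#' Produces \code{n_slides} slides from a shared parameter template, each
#' with its own derived seed. When \code{cps_targets} is given the per-slide
#' counts are solved so each slide's true CPS is within 0.5 of its target
#' (targets recycle over slides), letting cohorts span both sides of the
#' CPS = 1 cutoff.
#'
#' @param n_slides number of slides (>= 1).
#' @param cps_targets optional numeric vector of target CPS values.
#' @param seed cohort seed; slide i uses a seed derived from it.
#' @param params \code{\link{synthParams}} template.
#' @param denominator viable-tumor-cell count used when solving targets.
#' @return list with \code{slides} (list of \code{list(slide, truth)}) and
#'   \code{manifest} (per-slide table: id, seed, counts, true CPS, call).
#' @export
generateCohort <- function(n_slides, cps_targets = NULL, seed = 1L,
                           params = synthParams(), denominator = 190L) {
  if (n_slides < 1L) .stopf("n_slides must be >= 1")
  slides <- vector("list", n_slides)
  manifest <- NULL
  for (i in seq_len(n_slides)) {
    p <- params
    p$seed <- .subSeed(seed, i)
    p$slide_id <- sprintf("slide_%03d", i)
    tgt <- NA_real_
    if (!is.null(cps_targets)) {
      tgt <- cps_targets[[((i - 1L) %% length(cps_targets)) + 1L]]
      cnt <- solveCountsForCps(tgt, denominator = denominator)
      p$n_tumor_pos <- cnt[["n_tumor_pos"]]
      p$n_tumor_neg <- cnt[["n_tumor_neg"]]
      p$n_immune_pos <- cnt[["n_immune_pos"]]
    }
    slides[[i]] <- generateSlide(p)
    tc <- trueCps(slides[[i]]$truth)
    manifest <- rbind(manifest, data.frame(
      slide_id = p$slide_id, seed = p$seed, target_cps = tgt,
      n_tumor_pos = p$n_tumor_pos, n_tumor_neg = p$n_tumor_neg,
      n_immune_pos = p$n_immune_pos,
      true_cps = if (tc$valid) tc$cps else NA_real_,
      true_call = if (!tc$valid) "not_evaluable" else
        if (tc$cps >= 1) "positive" else "negative",
      stringsAsFactors = FALSE))
  }
  list(slides = slides, manifest = manifest)
}
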