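# internal helpers shared across modules

# clamp to [0,1]
.clip01 <- function(x) pmin(pmax(x, 0), 1)

# crop a (width, height, 3) raster at 0-based tile origin; half-open box
.cropPatch <- function(raster, x, y, w, h = w) {
  raster[(x + 1L):(x + w), (y + 1L):(y + h), , drop = FALSE]
}

.cropMask <- function(mask, x, y, w, h = w) {
  mask[(x + 1L):(x + w), (y + 1L):(y + h), drop = FALSE]
}

# ellipse raster: 0/1 matrix over the full canvas (cx, cy, rx, ry in pixels,
# 0-based centers); vectorized over the bounding box only
.paintEllipse <- function(mask, cx, cy, rx, ry, value = 1L) {
  w <- nrow(mask); h <- ncol(mask)
  xs <- max(0L, floor(cx - rx)):min(w - 1L, ceiling(cx + rx))
  ys <- max(0L, floor(cy - ry)):min(h - 1L, ceiling(cy + ry))
  ex <- ((xs - cx) / rx)^2
  ey <- ((ys - cy) / ry)^2
  inside <- outer(ex, ey, `+`) <= 1
  sub <- mask[xs + 1L, ys + 1L, drop = FALSE]
  sub[inside] <- value
  mask[xs + 1L, ys + 1L] <- sub
  mask
}

# set raster color over a logical canvas mask
.paintColor <- function(raster, where, rgb) {
  for (ch in 1:3) {
    plane <- raster[, , ch]
    plane[where] <- rgb[ch]
    raster[, , ch] <- plane
  }
  raster
}

# mix raster color toward rgb with weight alpha over mask
.blendColor <- function(raster, where, rgb, alpha) {
  for (ch in 1:3) {
    plane <- raster[, , ch]
    plane[where] <- (1 - alpha) * plane[where] + alpha * rgb[ch]
    raster[, , ch] <- plane
  }
  raster
}

# EBImage binary morphology on (width, height) 0/1 matrices
.erodeMask <- function(mask, radius) {
  if (radius < 1) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::erode(EBImage::Image(mask), k)
  m <- EBImage::imageData(out)
  storage.mode(m) <- "integer"
  m
}

# zero out a border band of width m (placement eligibility must never
# touch the canvas edge: erosion alone keeps border pixels when the
# structuring element extends past the image)
.shrinkBorder <- function(mask, m) {
  if (m < 1) return(mask)
  w <- nrow(mask); h <- ncol(mask)
  m <- min(m, floor((min(w, h) - 1) / 2))
  if (m >= 1) {
    mask[c(1:m, (w - m + 1):w), ] <- 0L
    mask[, c(1:m, (h - m + 1):h)] <- 0L
  }
  mask
}

# distance (in px) of every pixel to the nearest foreground pixel of `mask`
.distToMask <- function(mask) {
  if (!any(mask == 1L)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  EBImage::imageData(EBImage::distmap(EBImage::Image(1L - mask)))
}

# seed-scoped evaluation (restores RNG state)
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a bounded sub-seed
.subSeed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483629L
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# canonical JSON writer used for reports and manifests
.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
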