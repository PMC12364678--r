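#' Convert an RGB image to 8-bit grayscale
#'
#' Rec. 601 luma weighting (0.299 R + 0.587 G + 0.114 B) of a
#' (width, height, 3) array with values in [0, 1]; returns a matrix scaled
#' to [0, 255]. A gray input (R = G = B) maps to its own 8-bit value.
#'
#' @param image numeric array (width, height, 3), values in [0, 1].
#' @return numeric matrix (width, height) in [0, 255].
#' @export
toGrayscale <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    .stopf("expected a width x height x 3 image")
  if (any(d[1:2] == 0L)) .stopf("empty image")
  255 * (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Otsu threshold over a 256-bin histogram
#'
#' Exhaustive maximization of the between-class variance
#' \eqn{w0 w1 (mu0 - mu1)^2} over all 256 candidate thresholds t, with the
#' two classes being gray levels \code{<= t} and \code{> t}. Ties are broken
#' toward the lower threshold. The input is binned to 8-bit levels by
#' truncation.
#'
#' @param gray numeric matrix/vector of gray values in [0, 255].
#' @return the integer threshold t in 0..254.
#' @export
otsuThreshold <- function(gray) {
  v <- as.integer(pmin(pmax(floor(gray), 0), 255))
  if (length(v) == 0L) .stopf("empty image")
  if (length(unique(v)) < 2L)
    .stopf("constant image: Otsu threshold undefined")
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  cw <- cumsum(h)                 # class 0 counts for t = 0..255
  cs <- cumsum(h * lev)           # class 0 intensity sums
  tot <- cs[256]
  t <- 0:254
  w0 <- cw[t + 1L]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cs[t + 1L] / w0; mu1 <- (tot - cs[t + 1L]) / w1
  sigma <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  t[which.max(sigma)]             # which.max takes the first (lowest) maximum
}

#' Tissue localization by low-magnification Otsu thresholding
#'
#' Downsamples the slide by \code{downsample} (32 maps 20x analysis
#' resolution to 0.625x localization, the scale used for tissue detection),
#' converts to grayscale, applies \code{\link{otsuThreshold}}, and keeps the
#' dark side as tissue (when \code{fg_is_dark}). Connected components
#' smaller than \code{min_object_px} mask pixels are removed. A blank slide
#' yields an empty mask, not an error.
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param downsample integer downsample factor for the localization scale.
#' @param fg_is_dark tissue is darker than background (TRUE for brightfield).
#' @param min_object_px minimum component area at mask resolution.
#' @return a \linkS4class{TissueMask}.
#' @export
tissueMask <- function(slide, downsample = 32L, fg_is_dark = TRUE,
                       min_object_px = 4L) {
  r <- slideRaster(slide)
  d <- dim(r)
  mw <- max(1L, d[1] %/% as.integer(downsample))
  mh <- max(1L, d[2] %/% as.integer(downsample))
  small <- EBImage::imageData(EBImage::resize(
    EBImage::Image(r, colormode = "Color"), w = mw, h = mh))
  gray <- toGrayscale(array(small, dim = c(mw, mh, 3)))
  if (length(unique(as.integer(floor(gray)))) < 2L) {
    m <- matrix(0L, mw, mh)
    return(new("TissueMask", mask = m, downsample = as.numeric(downsample),
               threshold = NA_real_))
  }
  t <- otsuThreshold(gray)
  m <- if (fg_is_dark) ifelse(floor(gray) <= t, 1L, 0L)
       else ifelse(floor(gray) > t, 1L, 0L)
  if (min_object_px > 0L && any(m == 1L)) {
    lab <- EBImage::bwlabel(EBImage::Image(m))
    sizes <- table(lab[lab > 0])
    drop <- as.integer(names(sizes)[sizes < min_object_px])
    if (length(drop)) m[EBImage::imageData(lab) %in% drop] <- 0L
  }
  storage.mode(m) <- "integer"
  new("TissueMask", mask = m, downsample = as.numeric(downsample),
      threshold = as.numeric(t))
}

# nearest-neighbor upsample of a tissue mask to analysis scale (W x H)
.upsampleMask <- function(tmask, W, H) {
  m <- tmask@mask; ds <- tmask@downsample
  xi <- pmin(nrow(m), floor((0:(W - 1)) / ds) + 1L)
  yi <- pmin(ncol(m), floor((0:(H - 1)) / ds) + 1L)
  m[xi, yi, drop = FALSE]
}

#' Build the non-overlapping tile grid over tissue
#'
#' Partitions the slide into \code{patch_px} x \code{patch_px} tiles in
#' deterministic row-major order; tiles that would cross the slide border
#' (edge remainders) are dropped, not padded. Each tile's tissue fraction is
#' computed from the nearest-neighbor-upsampled tissue mask; tiles with
#' fraction >= \code{min_tissue_fraction} are marked \code{keep}. All
#' candidate tiles stay in the table so the kept/rejected partition is
#' auditable.
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param tissue a \linkS4class{TissueMask}, or NULL to treat the whole
#'   slide as tissue (localization bypass).
#' @param patch_px tile side in pixels (default 256).
#' @param min_tissue_fraction minimum tissue fraction to keep a tile
#'   (default 0.10).
#' @return a \linkS4class{TileGrid}.
#' @export
buildGrid <- function(slide, tissue = NULL, patch_px = 256L,
                      min_tissue_fraction = 0.10) {
  p <- as.integer(patch_px)
  if (p <= 0L) .stopf("patch_px must be positive")
  d <- dim(slideRaster(slide))
  W <- d[1]; H <- d[2]
  nx <- W %/% p; ny <- H %/% p
  up <- if (is.null(tissue)) matrix(1L, W, H) else .upsampleMask(tissue, W, H)
  rows <- integer(0); cols <- integer(0); fr <- numeric(0)
  # per-tile tissue fraction via column/row block sums
  if (nx >= 1L && ny >= 1L) {
    cs <- matrix(0, nx, ny)
    for (row in 0:(ny - 1L)) {
      for (col in 0:(nx - 1L)) {
        blk <- up[(col * p + 1L):((col + 1L) * p),
                  (row * p + 1L):((row + 1L) * p)]
        cs[col + 1L, row + 1L] <- mean(blk)
      }
    }
    rows <- rep(0:(ny - 1L), each = nx)
    cols <- rep(0:(nx - 1L), times = ny)
    fr <- cs[cbind(cols + 1L, rows + 1L)]
  }
  t <- data.frame(row = rows, col = cols,
                  x = cols * p, y = rows * p,
                  tissue_fraction = fr,
                  keep = fr >= min_tissue_fraction & fr > 0)
  new("TileGrid", patchPx = p, tiles = t, slideDim = c(W, H))
}

#' Serialize a tile grid to CSV
#'
#' Writes \code{slide_id,row,col,x,y,tissue_fraction,keep}.
#'
#' @param grid a \linkS4class{TileGrid}.
#' @param slide_id slide identifier column value.
#' @param path output CSV path.
#' @export
writeTileGrid <- function(grid, slide_id, path) {
  t <- tiles(grid, keptOnly = FALSE)
  utils::write.csv(cbind(slide_id = slide_id, t), path, row.names = FALSE)
  invisible(path)
}
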