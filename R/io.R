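#' Read and write slides, masks and cell tables
#'
#' Slides are stored as PNG or TIFF plus a JSON sidecar manifest carrying
#' \code{slide_id} and \code{mpp}; tumor masks as single-channel PNG
#' (255 = tumor); cell boxes as CSV with columns
#' \code{x_min,y_min,x_max,y_max,class,slide_id} (0-based pixels, half-open
#' boxes).
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param path image file path (.png or .tif/.tiff); the sidecar is
#'   \code{<path>.json}.
#' @return \code{readSlide} returns a \linkS4class{SlideImage};
#'   the writers return their path invisibly.
#' @name slide-io
NULL

#' @rdname slide-io
#' @export
writeSlide <- function(slide, path) {
  EBImage::writeImage(EBImage::Image(slideRaster(slide), colormode = "Color"),
                      path)
  d <- dim(slideRaster(slide))
  .writeJson(list(slide_id = slideId(slide), mpp = mpp(slide),
                  width = d[1], height = d[2]),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname slide-io
#' @export
readSlide <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new("SlideImage", raster = a,
      mpp = as.numeric(meta$mpp %||% 0.475),
      slideId = as.character(meta$slide_id %||%
                               sub("\\.[^.]+$", "", basename(path))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname slide-io
#' @param mask a 0/1 integer matrix (width x height).
#' @export
writeMaskPng <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(mask), path)
  invisible(path)
}

#' @rdname slide-io
#' @export
readMaskPng <- function(path) {
  m <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- ifelse(m > 0.5, 1L, 0L)
  storage.mode(m) <- "integer"
  m
}

#' @rdname slide-io
#' @param cells data.frame of cell boxes (ground truth or detections).
#' @export
writeCellCsv <- function(cells, path) {
  cols <- c("x_min", "y_min", "x_max", "y_max", "class", "slide_id")
  extra <- intersect(c("confidence", "region"), names(cells))
  utils::write.csv(cells[, c(cols, extra), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname slide-io
#' @export
readCellCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a full synthetic slide bundle
#'
#' Writes the slide image (+ JSON sidecar), tumor mask PNG, cell CSV and a
#' ground-truth JSON (counts, true CPS) into a directory, as produced by
#' \code{\link{generateSlide}}.
#'
#' @param bundle list(slide, truth) from \code{\link{generateSlide}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSlideBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- slideId(bundle$slide)
  writeSlide(bundle$slide, file.path(dir, paste0(id, ".png")))
  writeMaskPng(tumorMask(bundle$truth),
               file.path(dir, paste0(id, "_tumor_mask.png")))
  writeCellCsv(cellTable(bundle$truth),
               file.path(dir, paste0(id, "_cells.csv")))
  tc <- trueCps(bundle$truth)
  .writeJson(list(slide_id = id,
                  true_counts = as.list(trueCounts(bundle$truth)),
                  true_cps = if (tc$valid) tc$cps else "invalid",
                  numerator = tc$numerator, denominator = tc$denominator),
             file.path(dir, paste0(id, "_truth.json")))
  invisible(dir)
}

#' @rdname writeSlideBundle
#' @param id slide id of the bundle to read back.
#' @export
readSlideBundle <- function(dir, id) {
  slide <- readSlide(file.path(dir, paste0(id, ".png")))
  mask <- readMaskPng(file.path(dir, paste0(id, "_tumor_mask.png")))
  cells <- readCellCsv(file.path(dir, paste0(id, "_cells.csv")))
  if (!nrow(cells)) {
    cells <- data.frame(slide_id = character(0), class = character(0),
                        cx = numeric(0), cy = numeric(0),
                        x_min = integer(0), y_min = integer(0),
                        x_max = integer(0), y_max = integer(0),
                        region = character(0), weak = logical(0))
  } else {
    cells$cx <- (cells$x_min + cells$x_max) / 2
    cells$cy <- (cells$y_min + cells$y_max) / 2
    px <- pmin(pmax(as.integer(floor(cells$cx)), 0L), nrow(mask) - 1L)
    py <- pmin(pmax(as.integer(floor(cells$cy)), 0L), ncol(mask) - 1L)
    cells$region <- ifelse(mask[cbind(px + 1L, py + 1L)] == 1L,
                           "inside_tumor", "outside_tumor")
    cells$weak <- FALSE
  }
  counts <- c(n_tumor_pos = sum(cells$class == "tumor_pos"),
              n_tumor_neg = sum(cells$class == "tumor_neg"),
              n_immune_pos = sum(cells$class == "immune_pos"))
  storage.mode(counts) <- "integer"
  num <- counts[["n_tumor_pos"]] + counts[["n_immune_pos"]]
  den <- counts[["n_tumor_pos"]] + counts[["n_tumor_neg"]]
  truth <- new("SlideGroundTruth", tumorMask = mask, cells = cells,
               trueCounts = counts,
               trueCps = list(numerator = num, denominator = den,
                              cps = if (den > 0L) 100 * num / den else NA_real_,
                              valid = den > 0L))
  list(slide = slide, truth = truth)
}
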