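# label-preserving augmentation ops; rotations restricted to multiples of
# 90 degrees so masks and boxes transform exactly (no interpolation noise)

.flipH <- function(patch) patch[dim(patch)[1]:1, , , drop = FALSE]
.flipV <- function(patch) patch[, dim(patch)[2]:1, , drop = FALSE]

.rot90 <- function(patch, k = 1L) {
  k <- k %% 4L
  out <- patch
  for (i in seq_len(k)) {
    # 90 deg clockwise: (x, y) -> (H - 1 - y, x)
    out <- aperm(out, c(2, 1, 3))[dim(out)[2]:1, , , drop = FALSE]
  }
  out
}

.blurPatch <- function(patch, sigma) {
  if (sigma <= 0) return(patch)
  EBImage::imageData(EBImage::gblur(EBImage::Image(patch, colormode = "Color"),
                                    sigma = sigma))
}

# hue/saturation/value perturbation; ranges kept small so brown vs blue
# stain identity (hence every label) is preserved
.hsvJitter <- function(patch, dh = 0.05, ds = 0.2, dv = 0.2) {
  d <- dim(patch)
  m <- matrix(c(patch[, , 1], patch[, , 2], patch[, , 3]),
              nrow = 3, byrow = TRUE)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + stats::runif(1, -dh, dh)) %% 1
  hsv[2, ] <- .clip01(hsv[2, ] * (1 + stats::runif(1, -ds, ds)))
  hsv[3, ] <- .clip01(hsv[3, ] * (1 + stats::runif(1, -dv, dv)))
  col <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  rgb <- grDevices::col2rgb(col) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), dim = d)
}

# random augmented copy of (patch [, mask]); returns list(patch, mask)
.augmentOnce <- function(patch, mask = NULL, flip = TRUE, rotation = TRUE,
                         blur = FALSE, hsv = FALSE, blur_sigma_max = 1.5) {
  mpatch <- if (is.null(mask)) NULL else
    array(mask, dim = c(dim(mask), 1L))
  if (flip && stats::runif(1) < 0.5) {
    patch <- .flipH(patch)
    if (!is.null(mpatch)) mpatch <- .flipH(mpatch)
  }
  if (rotation) {
    k <- sample.int(4L, 1L) - 1L
    patch <- .rot90(patch, k)
    if (!is.null(mpatch)) mpatch <- .rot90(mpatch, k)
  }
  if (blur) patch <- .blurPatch(patch, stats::runif(1, 0, blur_sigma_max))
  if (hsv) patch <- .hsvJitter(patch)
  list(patch = patch,
       mask = if (is.null(mpatch)) NULL else mpatch[, , 1])
}

#' Mosaic augmentation: compose four patches into one canvas
#'
#' Places four equally sized patches in a 2x2 composite and remaps their
#' box annotations into composite coordinates. Used during detector
#' training to vary object context; the box bookkeeping is exact by
#' construction.
#'
#' @param patches list of four (p x p x 3) arrays.
#' @param boxes list of four data.frames with columns
#'   \code{x_min,y_min,x_max,y_max,class} in patch coordinates.
#' @return list with \code{patch} (2p x 2p x 3) and \code{boxes}
#'   (all input boxes remapped, all inside the composite canvas).
#' @export
mosaicCompose <- function(patches, boxes) {
  stopifnot(length(patches) == 4L, length(boxes) == 4L)
  p <- dim(patches[[1]])[1]
  canvas <- array(0, dim = c(2L * p, 2L * p, 3L))
  offs <- list(c(0L, 0L), c(p, 0L), c(0L, p), c(p, p))
  out <- NULL
  for (k in 1:4) {
    ox <- offs[[k]][1]; oy <- offs[[k]][2]
    canvas[(ox + 1L):(ox + p), (oy + 1L):(oy + p), ] <- patches[[k]]
    b <- boxes[[k]]
    if (!is.null(b) && nrow(b)) {
      b$x_min <- b$x_min + ox; b$x_max <- b$x_max + ox
      b$y_min <- b$y_min + oy; b$y_max <- b$y_max + oy
      out <- rbind(out, b)
    }
  }
  if (is.null(out)) {
    out <- data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      class = character(0))
  }
  list(patch = canvas, boxes = out)
}

#' Mixup augmentation: blend two patches and pool their boxes
#'
#' Convex blend of two equally sized images with weight \code{lambda};
#' the annotation set of the blend is the union of both box sets.
#'
#' @param patch_a,patch_b (p x p x 3) arrays.
#' @param boxes_a,boxes_b box data.frames as in \code{\link{mosaicCompose}}.
#' @param lambda blend weight for \code{patch_a} in (0, 1).
#' @return list with \code{patch} and \code{boxes}.
#' @export
mixupCompose <- function(patch_a, boxes_a, patch_b, boxes_b, lambda = 0.5) {
  stopifnot(all(dim(patch_a) == dim(patch_b)), lambda > 0, lambda < 1)
  empty <- data.frame(x_min = integer(0), y_min = integer(0),
                      x_max = integer(0), y_max = integer(0),
                      class = character(0))
  ba <- if (is.null(boxes_a)) empty else boxes_a
  bb <- if (is.null(boxes_b)) empty else boxes_b
  list(patch = lambda * patch_a + (1 - lambda) * patch_b,
       boxes = rbind(ba, bb))
}
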