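#' @import methods
NULL

#' SlideImage: an IHC image with physical scale
#'
#' Container for one slide (or slide region) to be scored. The raster is a
#' numeric array of dimension \code{c(width, height, 3)} with RGB values in
#' \code{[0, 1]}; pixel \code{(x, y)} (0-based, x right, y down) lives at
#' \code{raster[x + 1, y + 1, ]}. \code{mpp} is the physical scale in microns
#' per pixel at analysis magnification (0.475 um/px corresponds to a 20x scan).
#'
#' @slot raster numeric array \code{c(width, height, 3)}, values in [0, 1].
#' @slot mpp microns per pixel (> 0).
#' @slot slideId character identifier.
#' @exportClass SlideImage
setClass("SlideImage",
  representation(raster = "array", mpp = "numeric", slideId = "character"),
  validity = function(object) {
    d <- dim(object@raster)
    if (length(d) != 3L || d[3] != 3L)
      return("raster must be a width x height x 3 array")
    if (any(d[1:2] < 1L)) return("raster has empty dimensions")
    if (!is.numeric(object@raster)) return("raster must be numeric")
    if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0)
      return("mpp must be a single positive number")
    if (length(object@slideId) != 1L || !nzchar(object@slideId))
      return("slideId must be a non-empty string")
    TRUE
  })

#' SlideGroundTruth: exact annotations for a synthetic slide
#'
#' Ground truth paired with a generated \linkS4class{SlideImage}: the binary
#' tumor-region mask (necrosis and glands excluded), the cell table with
#' half-open pixel boxes and classes, the per-class tallies and the CPS value
#' implied by them. This is the oracle used by recovery tests.
#'
#' @slot tumorMask integer matrix \code{c(width, height)}, 1 = tumor region.
#' @slot cells data.frame with columns \code{slide_id, class, cx, cy, x_min,
#'   y_min, x_max, y_max, region, weak}; classes are \code{tumor_pos},
#'   \code{tumor_neg}, \code{immune_pos}; \code{region} is
#'   \code{inside_tumor} or \code{outside_tumor} by center pixel.
#' @slot trueCounts named integer vector \code{n_tumor_pos, n_tumor_neg,
#'   n_immune_pos}.
#' @slot trueCps list with \code{numerator}, \code{denominator}, \code{cps}
#'   (numeric, \code{NA} when the denominator is zero) and \code{valid}.
#' @exportClass SlideGroundTruth
setClass("SlideGroundTruth",
  representation(tumorMask = "matrix", cells = "data.frame",
                 trueCounts = "integer", trueCps = "list"),
  validity = function(object) {
    if (!all(object@tumorMask %in% c(0L, 1L))) return("tumorMask must be 0/1")
    need <- c("slide_id", "class", "cx", "cy", "x_min", "y_min",
              "x_max", "y_max", "region")
    if (!all(need %in% names(object@cells)))
      return("cells is missing required columns")
    if (nrow(object@cells) &&
        !all(object@cells$class %in% c("tumor_pos", "tumor_neg", "immune_pos")))
      return("unknown cell class")
    if (!identical(names(object@trueCounts),
                   c("n_tumor_pos", "n_tumor_neg", "n_immune_pos")))
      return("trueCounts must be named n_tumor_pos, n_tumor_neg, n_immune_pos")
    tal <- c(sum(object@cells$class == "tumor_pos"),
             sum(object@cells$class == "tumor_neg"),
             sum(object@cells$class == "immune_pos"))
    if (!all(tal == unname(object@trueCounts)))
      return("trueCounts does not match the cell tally")
    w <- nrow(object@tumorMask); h <- ncol(object@tumorMask)
    if (nrow(object@cells) &&
        (any(object@cells$x_min < 0) || any(object@cells$y_min < 0) ||
         any(object@cells$x_max > w) || any(object@cells$y_max > h)))
      return("cell boxes must lie within the canvas")
    TRUE
  })

#' TissueMask: low-magnification foreground mask
#'
#' Binary tissue mask computed at a downsampled resolution; \code{downsample}
#' is the ratio of analysis resolution to mask resolution (32 maps 20x
#' analysis to 0.625x localization).
#'
#' @slot mask integer matrix \code{c(mask_width, mask_height)}, 1 = tissue.
#' @slot downsample single positive integer factor.
#' @slot threshold the Otsu threshold used (8-bit units), or NA for a blank
#'   slide / bypassed localization.
#' @exportClass TissueMask
setClass("TissueMask",
  representation(mask = "matrix", downsample = "numeric", threshold = "numeric"),
  validity = function(object) {
    if (!all(object@mask %in% c(0L, 1L))) return("mask must be 0/1")
    if (object@downsample < 1) return("downsample must be >= 1")
    TRUE
  })

#' TileGrid: non-overlapping patch grid over a slide
#'
#' Row-major grid of \code{patch_px} x \code{patch_px} tiles fully inside the
#' slide (edge remainders dropped). Every candidate tile is retained in the
#' table with its tissue fraction; \code{keep} marks tiles at or above the
#' tissue-fraction cutoff. Coordinates are 0-based pixel offsets of the tile's
#' top-left corner.
#'
#' @slot patchPx tile side in pixels.
#' @slot tiles data.frame: \code{row, col, x, y, tissue_fraction, keep}.
#' @slot slideDim integer pair (width, height) of the slide.
#' @exportClass TileGrid
setClass("TileGrid",
  representation(patchPx = "integer", tiles = "data.frame", slideDim = "integer"),
  validity = function(object) {
    if (object@patchPx <= 0L) return("patchPx must be positive")
    need <- c("row", "col", "x", "y", "tissue_fraction", "keep")
    if (!all(need %in% names(object@tiles))) return("tiles missing columns")
    t <- object@tiles
    if (nrow(t)) {
      if (any(t$x < 0) || any(t$y < 0) ||
          any(t$x + object@patchPx > object@slideDim[1]) ||
          any(t$y + object@patchPx > object@slideDim[2]))
        return("tiles must lie within slide bounds")
      if (anyDuplicated(t[, c("row", "col")])) return("duplicate tiles")
    }
    TRUE
  })

#' CpsResult: the Combined Positive Score for one slide
#'
#' CPS = (PD-L1+ tumor cells + PD-L1+ immune cells) /
#' (PD-L1+ tumor cells + PD-L1- tumor cells) x 100, kept as an exact
#' integer ratio alongside the numeric value. \code{status} is \code{valid},
#' \code{insufficient_tumor_cells} (denominator below the evaluability
#' minimum; the score is still computed) or \code{no_tumor_cells}
#' (zero denominator). The binary call is positive iff the reported CPS is
#' >= 1 and the status is valid.
#'
#' @slot counts named integer vector \code{n_tumor_pos, n_tumor_neg,
#'   n_immune_pos}.
#' @slot numerator,denominator integer terms of the exact ratio (x100 applies
#'   to the quotient).
#' @slot cpsRaw numeric CPS before capping (NA when denominator is 0).
#' @slot cpsReported CPS after the cap at 100 (when the cap is enabled;
#'   in [0, 100] then).
#' @slot status one of \code{valid}, \code{insufficient_tumor_cells},
#'   \code{no_tumor_cells}.
#' @slot call one of \code{positive}, \code{negative}, \code{not_evaluable}.
#' @exportClass CpsResult
setClass("CpsResult",
  representation(counts = "integer", numerator = "integer",
                 denominator = "integer", cpsRaw = "numeric",
                 cpsReported = "numeric", status = "character",
                 call = "character"),
  validity = function(object) {
    if (any(object@counts < 0L)) return("counts must be non-negative")
    if (!object@status %in%
        c("valid", "insufficient_tumor_cells", "no_tumor_cells"))
      return("invalid status")
    if (!object@call %in% c("positive", "negative", "not_evaluable"))
      return("invalid call")
    if (object@status == "valid" &&
        (is.na(object@cpsReported) || object@cpsReported < 0))
      return("cpsReported must be non-negative when valid")
    TRUE
  })

#' AgreementResult: agreement between AI and reference PD-L1 calls
#'
#' 2x2 confusion matrix of binary PD-L1 calls (AI in rows, reference in
#' columns), Cohen's kappa with its interpretation label, and
#' accuracy/sensitivity/specificity with bootstrap 95% CIs.
#'
#' @slot confusion 2x2 integer matrix, dimnames ai/reference x
#'   positive/negative.
#' @slot kappa Cohen's kappa (NA when undefined).
#' @slot interpretation agreement label for kappa.
#' @slot metrics data.frame: \code{metric, estimate, ci_lower, ci_upper}.
#' @exportClass AgreementResult
setClass("AgreementResult",
  representation(confusion = "matrix", kappa = "numeric",
                 interpretation = "character", metrics = "data.frame"),
  validity = function(object) {
    if (!all(dim(object@confusion) == c(2L, 2L)))
      return("confusion must be 2x2")
    if (any(object@confusion < 0)) return("confusion entries must be >= 0")
    if (!is.na(object@kappa) && object@kappa == 1 &&
        sum(object@confusion[row(object@confusion) != col(object@confusion)]) != 0)
      return("kappa 1 requires zero off-diagonal mass")
    TRUE
  })
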