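#' Accessors for PDL1cps classes
#'
#' Small accessor generics: \code{slideRaster}, \code{mpp}, \code{slideId}
#' for \linkS4class{SlideImage}; \code{tumorMask}, \code{cellTable},
#' \code{trueCounts}, \code{trueCps} for \linkS4class{SlideGroundTruth};
#' \code{tiles} for \linkS4class{TileGrid}; \code{cellCounts},
#' \code{cpsValue}, \code{cpsStatus}, \code{pdl1Call} for
#' \linkS4class{CpsResult}.
#'
#' @param x an object of the matching class.
#' @param keptOnly for \code{tiles}: return only tiles passing the tissue
#'   cutoff (default TRUE).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slideRaster", function(x) standardGeneric("slideRaster"))
#' @rdname accessors
#' @export
setGeneric("mpp", function(x) standardGeneric("mpp"))
#' @rdname accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))
#' @rdname accessors
#' @export
setGeneric("trueCps", function(x) standardGeneric("trueCps"))
#' @rdname accessors
#' @export
setGeneric("tiles", function(x, keptOnly = TRUE) standardGeneric("tiles"))
#' @rdname accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setGeneric("cpsValue", function(x) standardGeneric("cpsValue"))
#' @rdname accessors
#' @export
setGeneric("cpsStatus", function(x) standardGeneric("cpsStatus"))
#' @rdname accessors
#' @export
setGeneric("pdl1Call", function(x) standardGeneric("pdl1Call"))

#' @rdname accessors
setMethod("slideRaster", "SlideImage", function(x) x@raster)
#' @rdname accessors
setMethod("mpp", "SlideImage", function(x) x@mpp)
#' @rdname accessors
setMethod("slideId", "SlideImage", function(x) x@slideId)
#' @rdname accessors
setMethod("tumorMask", "SlideGroundTruth", function(x) x@tumorMask)
#' @rdname accessors
setMethod("cellTable", "SlideGroundTruth", function(x) x@cells)
#' @rdname accessors
setMethod("trueCounts", "SlideGroundTruth", function(x) x@trueCounts)
#' @rdname accessors
setMethod("trueCps", "SlideGroundTruth", function(x) x@trueCps)
#' @rdname accessors
setMethod("tiles", "TileGrid", function(x, keptOnly = TRUE) {
  if (keptOnly) x@tiles[x@tiles$keep, , drop = FALSE] else x@tiles
})
#' @rdname accessors
setMethod("cellCounts", "CpsResult", function(x) x@counts)
#' @rdname accessors
setMethod("cpsValue", "CpsResult", function(x) x@cpsReported)
#' @rdname accessors
setMethod("cpsStatus", "CpsResult", function(x) x@status)
#' @rdname accessors
setMethod("pdl1Call", "CpsResult", function(x) x@call)

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@raster)
  cat("SlideImage '", object@slideId, "': ", d[1], " x ", d[2],
      " px, ", format(object@mpp), " um/px\n", sep = "")
})

setMethod("show", "SlideGroundTruth", function(object) {
  tc <- object@trueCounts
  cat("SlideGroundTruth: ", sum(object@tumorMask), " tumor px; cells ",
      "TP=", tc["n_tumor_pos"], " TN=", tc["n_tumor_neg"],
      " IP=", tc["n_immune_pos"], "; true CPS ",
      if (isTRUE(object@trueCps$valid))
        format(round(object@trueCps$cps, 3)) else "invalid",
      "\n", sep = "")
})

setMethod("show", "TissueMask", function(object) {
  cat("TissueMask ", nrow(object@mask), " x ", ncol(object@mask),
      " (downsample ", object@downsample, "), ",
      sum(object@mask), " tissue px\n", sep = "")
})

setMethod("show", "TileGrid", function(object) {
  cat("TileGrid: ", object@patchPx, " px tiles, ",
      sum(object@tiles$keep), "/", nrow(object@tiles),
      " tiles kept as tissue\n", sep = "")
})

setMethod("show", "CpsResult", function(object) {
  cat("CpsResult: CPS ",
      if (is.na(object@cpsReported)) "NA" else format(round(object@cpsReported, 3)),
      " (", object@numerator, "/", object@denominator, " x 100), status ",
      object@status, ", call ", object@call, "\n", sep = "")
})

setMethod("show", "AgreementResult", function(object) {
  cat("AgreementResult: kappa ",
      if (is.na(object@kappa)) "NA" else format(round(object@kappa, 3)),
      " (", object@interpretation, ")\n", sep = "")
  print(object@confusion)
})
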