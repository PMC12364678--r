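#' Pipeline run configuration
#'
#' All tunable thresholds of the scoring pipeline in one validated list.
#' Defaults: 256 px analysis tiles; tissue localization by Otsu at a 32x
#' downsample (20x analysis to 0.625x localization) keeping tiles with at
#' least 10\% tissue; consensus gate at 1\% tumor pixels; detector
#' confidence 0.25 with per-class NMS at IoU 0.45; CPS capped at 100 with
#' a 100-tumor-cell evaluability flag; 500 um immune proximity radius.
#'
#' @param patch_px analysis tile side in pixels.
#' @param mask_downsample tissue-mask downsample factor.
#' @param tissue_filter \code{"otsu"} or \code{"none"} (treat the whole
#'   slide as tissue; useful for noise-free oracle runs).
#' @param min_tissue_fraction minimum tile tissue fraction in [0, 1].
#' @param min_object_px small-object removal at mask resolution.
#' @param fg_is_dark tissue darker than background (brightfield).
#' @param min_tumor_fraction consensus-gate tumor-pixel fraction in [0, 1];
#'   0 keeps the any-tumor-pixel veto.
#' @param conf_threshold detector confidence threshold in [0, 1].
#' @param nms_iou per-class NMS IoU in [0, 1].
#' @param cap_at_100 cap reported CPS at 100.
#' @param min_tumor_cells evaluability minimum for the CPS denominator.
#' @param radius_um immune proximity radius in microns.
#' @param bypass_classifier run the segmentation-only (ungated) arm.
#' @param seed seed recorded into run manifests.
#' @return validated list of class \code{cpsRunConfig}.
#' @export
runConfig <- function(patch_px = 256L, mask_downsample = 32L,
                      tissue_filter = "otsu", min_tissue_fraction = 0.10,
                      min_object_px = 4L, fg_is_dark = TRUE,
                      min_tumor_fraction = 0.01, conf_threshold = 0.25,
                      nms_iou = 0.45, cap_at_100 = TRUE,
                      min_tumor_cells = 100L, radius_um = 500,
                      bypass_classifier = FALSE, seed = 1L) {
  cfg <- list(patch_px = as.integer(patch_px),
              mask_downsample = as.integer(mask_downsample),
              tissue_filter = tissue_filter,
              min_tissue_fraction = min_tissue_fraction,
              min_object_px = as.integer(min_object_px),
              fg_is_dark = isTRUE(fg_is_dark),
              min_tumor_fraction = min_tumor_fraction,
              conf_threshold = conf_threshold, nms_iou = nms_iou,
              cap_at_100 = isTRUE(cap_at_100),
              min_tumor_cells = as.integer(min_tumor_cells),
              radius_um = radius_um,
              bypass_classifier = isTRUE(bypass_classifier),
              seed = as.integer(seed))
  class(cfg) <- "cpsRunConfig"
  validateRunConfig(cfg)
}

#' @rdname runConfig
#' @param config a configuration list to validate (names outside the known
#'   set, or values outside their documented ranges, error naming the
#'   field).
#' @export
validateRunConfig <- function(config) {
  if (!inherits(config, "cpsRunConfig")) {
    known <- names(formals(runConfig))
    extra <- setdiff(names(config), known)
    if (length(extra))
      .stopf("unknown config field: %s", paste(extra, collapse = ", "))
    config <- do.call(runConfig, config)
    return(config)
  }
  chk <- function(cond, field, msg)
    if (!cond) .stopf("invalid config field '%s': %s", field, msg)
  chk(config$patch_px > 0L, "patch_px", "must be positive")
  chk(config$mask_downsample >= 1L, "mask_downsample", "must be >= 1")
  chk(config$tissue_filter %in% c("otsu", "none"), "tissue_filter",
      "must be 'otsu' or 'none'")
  chk(config$min_tissue_fraction >= 0 && config$min_tissue_fraction <= 1,
      "min_tissue_fraction", "must be in [0, 1]")
  chk(config$min_tumor_fraction >= 0 && config$min_tumor_fraction <= 1,
      "min_tumor_fraction", "must be in [0, 1]")
  chk(config$conf_threshold >= 0 && config$conf_threshold <= 1,
      "conf_threshold", "must be in [0, 1]")
  chk(config$nms_iou >= 0 && config$nms_iou <= 1, "nms_iou",
      "must be in [0, 1]")
  chk(config$min_tumor_cells >= 0L, "min_tumor_cells", "must be >= 0")
  chk(config$radius_um >= 0, "radius_um", "must be >= 0")
  config
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip unchanged through serialization; unknown
#' fields in a file error naming the field.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig} returns a validated \code{cpsRunConfig}.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  validateRunConfig(raw)
}

#' @rdname readRunConfig
#' @param config a \code{\link{runConfig}} list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(validateRunConfig(config)), path)
  invisible(path)
}
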