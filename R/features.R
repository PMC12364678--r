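# feature extraction shared by the three models; all operate on
# (width, height, 3) arrays in [0, 1]

# stain-response channels: DAB-like brownness and hematoxylin-like blueness
.brownness <- function(patch) patch[, , 1] - patch[, , 3]
.blueness <- function(patch) patch[, , 3] - (patch[, , 1] + patch[, , 2]) / 2

# pooled color/texture descriptor of one patch (patch classifier)
.patchFeatures <- function(patch) {
  r <- patch[, , 1]; g <- patch[, , 2]; b <- patch[, , 3]
  br <- .brownness(patch); bl <- .blueness(patch)
  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  grad <- abs(diff(gray)); gradv <- abs(t(diff(t(gray))))
  q <- function(x) stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  c(mean_r = mean(r), mean_g = mean(g), mean_b = mean(b),
    sd_r = stats::sd(r), sd_g = stats::sd(g), sd_b = stats::sd(b),
    q_r = q(r), q_g = q(g), q_b = q(b),
    mean_brown = mean(br), frac_brown = mean(br > 0.25),
    mean_blue = mean(bl), frac_blue = mean(bl > 0.18),
    violet = mean(b - g),
    edge = mean(grad) + mean(gradv),
    dark = mean(gray < 0.55))
}

.patchFeatureMatrix <- function(patches) {
  m <- t(vapply(patches, .patchFeatures, numeric(22L)))
  colnames(m) <- names(.patchFeatures(patches[[1]]))
  m
}

# per-pixel features for the segmenter: raw RGB plus two Gaussian scales
.pixelFeatures <- function(patch, sigmas = c(2, 4)) {
  W <- dim(patch)[1]; H <- dim(patch)[2]
  feats <- list(r = patch[, , 1], g = patch[, , 2], b = patch[, , 3])
  img <- EBImage::Image(patch, colormode = "Color")
  for (s in sigmas) {
    sm <- EBImage::imageData(EBImage::gblur(img, sigma = s))
    feats[[paste0("r", s)]] <- sm[, , 1]
    feats[[paste0("g", s)]] <- sm[, , 2]
    feats[[paste0("b", s)]] <- sm[, , 3]
  }
  out <- vapply(feats, as.numeric, numeric(W * H))
  colnames(out) <- names(feats)
  out
}

# connected-component cell candidates for the detector: stain-positive
# blobs with bounding boxes (0-based, half-open) and shape/color features
.cellCandidates <- function(patch, blue_thr = 0.18, brown_thr = 0.25,
                            min_area = 4L, max_area = 600L) {
  cm <- (.blueness(patch) > blue_thr) | (.brownness(patch) > brown_thr)
  if (!any(cm)) return(NULL)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cm + 0)))
  n <- max(lab)
  if (n == 0L) return(NULL)
  br <- .brownness(patch); bl <- .blueness(patch)
  W <- dim(patch)[1]; H <- dim(patch)[2]
  rows <- vector("list", n)
  idxAll <- which(lab > 0)
  labv <- lab[idxAll]
  ord <- order(labv)
  idxAll <- idxAll[ord]; labv <- labv[ord]
  bounds <- c(0L, cumsum(tabulate(labv, nbins = n)))
  for (k in seq_len(n)) {
    if (bounds[k + 1L] == bounds[k]) next
    idx <- idxAll[(bounds[k] + 1L):bounds[k + 1L]]
    area <- length(idx)
    if (area < min_area || area > max_area) next
    xs <- (idx - 1L) %% W; ys <- (idx - 1L) %/% W
    x0 <- min(xs); x1 <- max(xs) + 1L; y0 <- min(ys); y1 <- max(ys) + 1L
    w <- x1 - x0; h <- y1 - y0
    # interior = pixels more than 1 px from the component border box
    inner <- xs > x0 & xs < x1 - 1L & ys > y0 & ys < y1 - 1L
    innerIdx <- idx[inner]
    outerIdx <- idx[!inner]
    mn <- function(v, i) if (length(i)) mean(v[i]) else 0
    rows[[k]] <- c(
      x_min = x0, y_min = y0, x_max = x1, y_max = y1,
      area = area, width = w, height = h,
      aspect = w / h, fill = area / (w * h),
      mean_r = mean(patch[, , 1][idx]), mean_g = mean(patch[, , 2][idx]),
      mean_b = mean(patch[, , 3][idx]),
      mean_brown = mean(br[idx]), mean_blue = mean(bl[idx]),
      frac_brown = mean(br[idx] > brown_thr),
      frac_blue = mean(bl[idx] > blue_thr),
      inner_blue = mn(bl, innerIdx), inner_brown = mn(br, innerIdx),
      rim_brown = mn(br, outerIdx), rim_blue = mn(bl, outerIdx))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- as.data.frame(do.call(rbind, rows))
  out
}

.candidateFeatureNames <- c("area", "width", "height", "aspect", "fill",
                            "mean_r", "mean_g", "mean_b", "mean_brown",
                            "mean_blue", "frac_brown", "frac_blue",
                            "inner_blue", "inner_brown", "rim_brown",
                            "rim_blue")
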