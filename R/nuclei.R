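# T cell packing density: despeckle + blur a nuclei plane, segment nuclei by
# Otsu thresholding and distance-transform watershed, drop nuclei inside the
# stromal (PDPN+) mask, and report nuclei per 100 um^2.

#' Preprocess a nuclei plane (despeckle + Gaussian blur)
#'
#' A 3x3 median filter removes hot pixels, followed by a Gaussian blur with
#' `sigma = 2` px by default. Calibration is preserved.
#'
#' @param image a [CalibratedImage] (single z-plane).
#' @param sigma Gaussian blur sigma in px (default 2).
#' @return a preprocessed [CalibratedImage].
#' @export
preprocessNuclei <- function(image, sigma = 2) {
  stopifnot(is(image, "CalibratedImage"))
  m <- pixels(image)
  rng <- range(m)
  if (rng[2] - rng[1] > 0) {
    n01 <- normalize01(m)
    med <- EBImage::medianFilter(n01, size = 1)   # 3x3 window
    m <- med * (rng[2] - rng[1]) + rng[1]
  }
  if (sigma > 0) m <- EBImage::gblur(m, sigma = sigma)
  CalibratedImage(m, pixelSizeUm(image), channelLabel(image))
}

#' Segment nuclei by thresholding and watershed
#'
#' Otsu threshold gives the binary foreground; the Euclidean distance
#' transform of the foreground is flooded by a watershed whose local-maximum
#' neighbourhood radius is `peakMinDistancePx`, splitting touching nuclei.
#' Components smaller than `minAreaPx` (default a quarter of the median
#' component area) are discarded. A blank image yields an empty table, not an
#' error.
#'
#' @param image a preprocessed [CalibratedImage].
#' @param minAreaPx minimum component area in px (NULL for the data-derived
#'   default).
#' @param peakMinDistancePx minimum seed separation in px (roughly the
#'   expected nucleus diameter).
#' @return data.frame with columns `label`, `row`, `col` (centroid),
#'   `area_px`.
#' @export
segmentNuclei <- function(image, minAreaPx = NULL, peakMinDistancePx = 8) {
  stopifnot(is(image, "CalibratedImage"))
  m <- pixels(image)
  empty <- data.frame(label = integer(), row = numeric(), col = numeric(),
                      area_px = integer())
  if (max(m) - min(m) <= 0) return(empty)
  n01 <- normalize01(m)
  thr <- EBImage::otsu(n01, range = c(0, 1))
  bin <- n01 > thr
  if (!any(bin)) return(empty)
  dm <- EBImage::distmap(bin * 1)
  labels <- EBImage::watershed(dm, tolerance = 1,
                               ext = max(1L, round(peakMinDistancePx / 2)))
  labels <- as.matrix(labels)
  areas <- tabulate(labels[labels > 0])
  if (is.null(minAreaPx)) {
    minAreaPx <- 0.25 * stats::median(areas[areas > 0])
  }
  keep <- which(areas >= minAreaPx)
  if (!length(keep)) return(empty)
  idx <- which(labels > 0 & matrix(labels %in% keep, nrow(labels)))
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  agg <- data.frame(
    label = sort(unique(lab)),
    row = as.numeric(tapply(rows, lab, mean)),
    col = as.numeric(tapply(cols, lab, mean)),
    area_px = as.integer(tapply(rows, lab, length)))
  agg$label <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Partition detections by an exclusion mask
#'
#' A detection is excluded iff its centroid pixel (rounded) lies inside the
#' mask -- the rule used to clear nuclei inside the stromal stain.
#'
#' @param detections data.frame from [segmentNuclei()].
#' @param exclusionMask logical (or 0/1) matrix, same shape as the image.
#' @return list with `kept` and `excluded` data.frames.
#' @export
excludeInMask <- function(detections, exclusionMask) {
  exclusionMask <- as.matrix(exclusionMask)
  if (nrow(detections) == 0L)
    return(list(kept = detections, excluded = detections))
  r <- pmin(pmax(round(detections$row), 1), nrow(exclusionMask))
  c <- pmin(pmax(round(detections$col), 1), ncol(exclusionMask))
  inside <- exclusionMask[cbind(r, c)] > 0
  list(kept = detections[!inside, , drop = FALSE],
       excluded = detections[inside, , drop = FALSE])
}

#' Packing density: nuclei per 100 um^2 within an ROI
#'
#' Counts detections whose centroid falls inside the closed ROI and divides
#' by the ROI area in um^2, scaled to per-100-um^2. The denominator is the
#' full ROI area (not ROI minus the exclusion mask); set
#' `excludeMaskFromArea` with a mask to subtract the masked area instead --
#' the choice is recorded in the result.
#'
#' @param detections data.frame of kept detections (`row`, `col` centroids).
#' @param roi a closed [RegionROI], or NULL to use the whole image
#'   (`imageDim` then required).
#' @param pixelSizeUm microns per pixel.
#' @param imageDim image dimensions, required when `roi` is NULL.
#' @param excludeMaskFromArea optional logical matrix; its in-ROI area is
#'   subtracted from the denominator.
#' @return data.frame with `count`, `roi_area_um2`, `density_per_100um2`,
#'   `area_mode`.
#' @export
packingDensity <- function(detections, roi = NULL, pixelSizeUm,
                           imageDim = NULL, excludeMaskFromArea = NULL) {
  stopifnot(pixelSizeUm > 0)
  if (is.null(roi)) {
    if (is.null(imageDim)) stop("need 'imageDim' when 'roi' is NULL")
    areaUm2 <- prod(imageDim) * pixelSizeUm^2
    count <- nrow(detections)
    inRoiMask <- NULL
  } else {
    stopifnot(is(roi, "RegionROI"), roi@closed)
    areaUm2 <- roiAreaUm2(roi, pixelSizeUm)
    if (areaUm2 <= 0) stop("zero-area ROI")
    if (nrow(detections)) {
      bnd <- list(x = roi@vertices[, "col"], y = roi@vertices[, "row"])
      inside <- mgcv::in.out(cbind(bnd$x, bnd$y),
                             cbind(detections$col, detections$row))
      count <- sum(inside)
    } else count <- 0L
  }
  mode <- "full_roi"
  if (!is.null(excludeMaskFromArea)) {
    maskAreaUm2 <- sum(as.matrix(excludeMaskFromArea) > 0) * pixelSizeUm^2
    areaUm2 <- areaUm2 - maskAreaUm2
    if (areaUm2 <= 0) stop("exclusion mask covers the whole ROI")
    mode <- "roi_minus_mask"
  }
  data.frame(count = count, roi_area_um2 = areaUm2,
             density_per_100um2 = count / areaUm2 * 100,
             area_mode = mode)
}
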