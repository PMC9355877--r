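# Contractile-fiber scoring: hand-drawn F-actin fiber polylines are checked
# against the stromal (PDPN+) network mask, then scored for positivity on
# stained channels (pMLC; matrix alignment for perlecan) relative to an
# in-network background.

#' Pixels sampled by a widened fiber polyline
#'
#' All pixel centres within `widthPx / 2` of the polyline.
#'
#' @param roi an open-polyline [RegionROI].
#' @param imageDim image dimensions `(rows, cols)`.
#' @param widthPx sampling width in px (default 3).
#' @return integer matrix of `(row, col)` pixel coordinates.
#' @export
fiberPixels <- function(roi, imageDim, widthPx = 3) {
  stopifnot(is(roi, "RegionROI"), !roi@closed)
  v <- roi@vertices
  half <- widthPx / 2
  r0 <- max(1L, floor(min(v[, 1]) - half - 1))
  r1 <- min(imageDim[1], ceiling(max(v[, 1]) + half + 1))
  c0 <- max(1L, floor(min(v[, 2]) - half - 1))
  c1 <- min(imageDim[2], ceiling(max(v[, 2]) + half + 1))
  if (r1 < r0 || c1 < c0) return(matrix(integer(), 0, 2))
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(rep(c0:c1, each = r1 - r0 + 1L), r1 - r0 + 1L)
  dmin <- matrix(Inf, nrow(rr), ncol(rr))
  for (s in seq_len(nrow(v) - 1L))
    dmin <- pmin(dmin, distToSegment(rr, cc, v[s, ], v[s + 1L, ]))
  sel <- which(dmin <= half)
  cbind(row = rr[sel], col = cc[sel])
}

#' Is a fiber within the stromal network?
#'
#' TRUE iff at least `minFraction` of the fiber's sampled pixels fall inside
#' the network mask.
#'
#' @param roi fiber polyline [RegionROI].
#' @param networkMask logical (or 0/1) matrix of the stromal stain.
#' @param widthPx sampling width (default 3).
#' @param minFraction in-mask fraction required (default 0.5).
#' @return logical, with attribute `fraction`.
#' @export
fiberInNetwork <- function(roi, networkMask, widthPx = 3, minFraction = 0.5) {
  networkMask <- as.matrix(networkMask)
  px <- fiberPixels(roi, dim(networkMask), widthPx)
  if (nrow(px) == 0L) stop("fiber ROI samples no pixels")
  frac <- mean(networkMask[px] > 0)
  structure(frac >= minFraction, fraction = frac)
}

# Background statistics over in-network pixels not covered by any fiber.
fiberBackgroundStats <- function(channel, networkMask, allFiberPx) {
  bg <- as.matrix(networkMask) > 0
  if (nrow(allFiberPx)) bg[allFiberPx] <- FALSE
  vals <- channel[bg]
  if (length(vals) < 10L) stop("too few background pixels")
  list(mean = mean(vals), sd = stats::sd(vals))
}

#' Score one fiber on a stained channel
#'
#' The fiber is positive iff its mean intensity over the widened polyline
#' exceeds `background mean + z * background SD`. With degenerate background
#' (zero variance) an absolute fallback threshold of twice the background
#' mean is applied and the call is flagged.
#'
#' @param roi fiber polyline [RegionROI].
#' @param channel channel image ([CalibratedImage] or matrix).
#' @param background list with `mean` and `sd` (see [scoreFibers()] for the
#'   standard in-network background).
#' @param widthPx sampling width (default 3).
#' @param z background SD multiplier (default 2).
#' @return list with `mean_intensity`, `positive`, `flag`.
#' @export
scoreChannel <- function(roi, channel, background, widthPx = 3, z = 2) {
  m <- if (is(channel, "CalibratedImage")) pixels(channel) else
    as.matrix(channel)
  px <- fiberPixels(roi, dim(m), widthPx)
  mi <- mean(m[px])
  if (!is.finite(background$sd) || background$sd <= 0) {
    thr <- 2 * background$mean
    list(mean_intensity = mi, positive = mi > thr & mi > 0,
         flag = "degenerate_background")
  } else {
    list(mean_intensity = mi,
         positive = mi > background$mean + z * background$sd,
         flag = NA_character_)
  }
}

#' Score a set of fiber ROIs against network, contractility and matrix
#' channels
#'
#' Each fiber is first checked against the network mask; scoring is defined
#' only for in-network fibers. Contractility (pMLC) positivity is the
#' background-relative intensity call. Matrix alignment additionally
#' requires at least `alignOverlap` of the fiber's pixels to lie over
#' matrix-positive pixels (channel above the same background threshold).
#' Background is taken from in-network pixels not covered by any fiber, per
#' image.
#'
#' @param rois list of fiber polyline [RegionROI]s.
#' @param networkMask logical stromal-stain mask.
#' @param pmlcChannel,matrixChannel channel images (matrix or
#'   [CalibratedImage]); either may be NULL to skip that call.
#' @param widthPx sampling width (default 3).
#' @param z background SD multiplier (default 2).
#' @param minFraction in-network fraction required (default 0.5).
#' @param alignOverlap overlap fraction required for matrix alignment
#'   (default 0.5).
#' @return data.frame, one row per fiber: `fiber`, `in_network`,
#'   `network_fraction`, `pmlc_mean`, `pmlc_positive`, `matrix_mean`,
#'   `matrix_overlap`, `matrix_aligned` (calls NA for out-of-network fibers).
#' @export
scoreFibers <- function(rois, networkMask, pmlcChannel = NULL,
                        matrixChannel = NULL, widthPx = 3, z = 2,
                        minFraction = 0.5, alignOverlap = 0.5) {
  networkMask <- as.matrix(networkMask)
  getM <- function(ch) if (is(ch, "CalibratedImage")) pixels(ch) else
    as.matrix(ch)
  pxSets <- lapply(rois, fiberPixels, imageDim = dim(networkMask),
                   widthPx = widthPx)
  allPx <- do.call(rbind, pxSets)
  res <- lapply(seq_along(rois), function(i) {
    inn <- fiberInNetwork(rois[[i]], networkMask, widthPx, minFraction)
    row <- data.frame(fiber = i, in_network = as.logical(inn),
                      network_fraction = attr(inn, "fraction"),
                      pmlc_mean = NA_real_, pmlc_positive = NA,
                      matrix_mean = NA_real_, matrix_overlap = NA_real_,
                      matrix_aligned = NA)
    if (!row$in_network) return(row)
    if (!is.null(pmlcChannel)) {
      bg <- fiberBackgroundStats(getM(pmlcChannel), networkMask, allPx)
      sc <- scoreChannel(rois[[i]], pmlcChannel, bg, widthPx, z)
      row$pmlc_mean <- sc$mean_intensity
      row$pmlc_positive <- sc$positive
    }
    if (!is.null(matrixChannel)) {
      m <- getM(matrixChannel)
      bg <- fiberBackgroundStats(m, networkMask, allPx)
      sc <- scoreChannel(rois[[i]], matrixChannel, bg, widthPx, z)
      thr <- if (is.finite(bg$sd) && bg$sd > 0) bg$mean + z * bg$sd else
        2 * bg$mean
      ov <- mean(m[pxSets[[i]]] > thr)
      row$matrix_mean <- sc$mean_intensity
      row$matrix_overlap <- ov
      row$matrix_aligned <- sc$positive && ov >= alignOverlap
    }
    row
  })
  do.call(rbind, res)
}

#' Summarize fiber scores for one image
#'
#' Percentages are computed over in-network fibers only.
#'
#' @param scores data.frame from [scoreFibers()] with >= 1 in-network fiber.
#' @return one-row data.frame: `n_fibers_in_network`, `pct_pmlc_positive`,
#'   `pct_matrix_aligned` (NA where the channel was not scored).
#' @export
summarizeFibers <- function(scores) {
  inn <- scores[scores$in_network, , drop = FALSE]
  if (nrow(inn) == 0L) stop("no in-network fibers to summarize")
  pct <- function(x) if (all(is.na(x))) NA_real_ else
    100 * mean(x, na.rm = TRUE)
  data.frame(n_fibers_in_network = nrow(inn),
             pct_pmlc_positive = pct(inn$pmlc_positive),
             pct_matrix_aligned = pct(inn$matrix_aligned))
}
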