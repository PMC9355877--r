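# Gap analysis of the FRC network: binarize the stromal stain, then greedily
# pack the free space with maximal non-overlapping circles. The radius
# distribution summarizes mesh size; widening gaps report network stretching.

#' Binarize a network image
#'
#' Converts a fluorescence maximum projection of the stromal network into a
#' binary mask (TRUE = network foreground, FALSE = free space). The default is
#' Otsu's threshold on a lightly smoothed copy; a fixed threshold is available
#' for pre-scaled images. A constant image has no data-driven threshold: it is
#' returned as all-background with the `degenerate` provenance flag set and a
#' warning.
#'
#' @param image a [CalibratedImage] (or plain numeric matrix).
#' @param method "otsu" (default) or "fixed".
#' @param threshold numeric threshold for `method = "fixed"` (intensity units
#'   of the input image); foreground is `> threshold`.
#' @param smoothSigma Gaussian pre-smoothing sigma in px before Otsu
#'   (0 disables); kept light by default so thin fibers are not widened.
#' @param invert set TRUE for inverted-contrast input (network dark on bright
#'   background); the returned mask is the same as for the non-inverted image.
#' @return logical matrix with attribute `provenance` (method, threshold on
#'   the original intensity scale, smoothSigma, degenerate flag).
#' @export
binarizeNetwork <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, smoothSigma = 0.5,
                            invert = FALSE) {
  method <- match.arg(method)
  m <- if (is(image, "CalibratedImage")) pixels(image) else as.matrix(image)
  if (any(!is.finite(m))) stop("image contains non-finite values")
  if (invert) m <- max(m) - m
  rng <- range(m)
  degenerate <- (rng[2] - rng[1]) <= 0
  if (degenerate && method == "otsu") {
    warning("constant image: no data-driven threshold; returning all background")
    mask <- matrix(FALSE, nrow(m), ncol(m))
    attr(mask, "provenance") <- list(method = method, threshold = NA_real_,
                                     smoothSigma = smoothSigma,
                                     degenerate = TRUE, invert = invert)
    return(mask)
  }
  if (method == "otsu") {
    sm <- if (smoothSigma > 0) EBImage::gblur(m, sigma = smoothSigma) else m
    n01 <- normalize01(sm)
    thr01 <- EBImage::otsu(n01, range = c(0, 1))
    mask <- n01 > thr01
    thrOrig <- thr01 * (max(sm) - min(sm)) + min(sm)
  } else {
    if (is.null(threshold)) stop("'threshold' required for method = 'fixed'")
    mask <- m > threshold
    thrOrig <- threshold
  }
  attr(mask, "provenance") <- list(method = method, threshold = thrOrig,
                                   smoothSigma = smoothSigma,
                                   degenerate = FALSE, invert = invert)
  mask
}

# Feasible radius at every pixel centre: Euclidean distance to the nearest
# network pixel centre, with a virtual 1-px foreground ring outside the image
# so circles fit within bounds. Exact EDT via EBImage::distmap.
freeSpaceRadii <- function(mask) {
  d <- dim(mask)
  padded <- matrix(0, d[1] + 2L, d[2] + 2L)      # ring of obstacles
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- 1 - mask
  edt <- EBImage::distmap(padded)
  matrix(as.numeric(edt[2:(d[1] + 1L), 2:(d[2] + 1L)]), d[1], d[2])
}

#' Greedy maximal-circle packing of network free space
#'
#' Consecutively fits the largest circle (centred on a pixel centre) that
#' contains no network pixel strictly inside, lies within the image bounds,
#' and does not overlap any previously fitted circle; stops when the best
#' feasible radius drops below `rMinPx`. Touching is allowed both between
#' circles (centre distance equal to the radius sum) and between a circle and
#' the network (a foreground pixel exactly on the boundary). Ties in radius
#' break to the smallest `(row, col)` in lexicographic order, so output is
#' deterministic.
#'
#' @param mask logical/0-1 matrix, TRUE/1 = network foreground.
#' @param pixelSizeUm microns per pixel, for the reported `radius_um`.
#' @param rMinPx stopping radius in pixels (>= 1; default 2).
#' @param thresholdUm reporting threshold carried into the result (default 12).
#' @param maxCircles safety cap on iterations.
#' @return a [GapResult]; `gapCircles()` returns the ordered circle table.
#' @export
fitGapCircles <- function(mask, pixelSizeUm = 1, rMinPx = 2,
                          thresholdUm = 12, maxCircles = 100000L) {
  prov <- attr(mask, "provenance")
  if (is.logical(mask)) mask <- mask * 1
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("'mask' must be binary")
  if (rMinPx < 1) stop("'rMinPx' must be >= 1")
  d <- dim(mask)
  feas <- freeSpaceRadii(mask)
  rowIdx <- matrix(seq_len(d[1]), d[1], d[2])
  colIdx <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  circles <- list()
  while (length(circles) < maxCircles) {
    best <- max(feas)
    if (best < rMinPx) break
    cand <- which(feas == best)
    if (length(cand) > 1L) {
      cr <- rowIdx[cand]; cc <- colIdx[cand]
      cand <- cand[order(cr, cc)][1L]
    }
    r0 <- rowIdx[cand]; c0 <- colIdx[cand]
    circles[[length(circles) + 1L]] <- c(r0, c0, best)
    # continuous-geometry non-overlap: the new circle lowers the feasible
    # radius everywhere to (distance to its centre) - its radius
    feas <- pmin(feas, sqrt((rowIdx - r0)^2 + (colIdx - c0)^2) - best)
  }
  tab <- if (length(circles)) {
    m <- do.call(rbind, circles)
    data.frame(rank = seq_len(nrow(m)) - 1L, row = m[, 1], col = m[, 2],
               radius_px = m[, 3], radius_um = m[, 3] * pixelSizeUm)
  } else {
    data.frame(rank = integer(), row = numeric(), col = numeric(),
               radius_px = numeric(), radius_um = numeric())
  }
  new("GapResult", circles = tab, rMinPx = as.numeric(rMinPx),
      thresholdUm = as.numeric(thresholdUm),
      pixelSizeUm = as.numeric(pixelSizeUm), maskDim = d,
      provenance = if (is.null(prov)) list() else prov)
}

#' @rdname GapResult-class
#' @param x a [GapResult].
#' @export
setMethod("gapCircles", "GapResult", function(x) x@circles)

setMethod("show", "GapResult", function(object) {
  n <- nrow(object@circles)
  cat(sprintf("GapResult: %d circle(s) on a %dx%d mask (r_min = %g px)\n",
              n, object@maskDim[1], object@maskDim[2], object@rMinPx))
  if (n) cat(sprintf("  radii %g .. %g px; %d above %g um\n",
                     max(object@circles$radius_px),
                     min(object@circles$radius_px),
                     sum(object@circles$radius_um > object@thresholdUm),
                     object@thresholdUm))
})

#' Radius distribution above a reporting threshold
#'
#' Filters fitted circle radii to those strictly greater than `thresholdUm`
#' (microns) and summarizes the retained distribution.
#'
#' @param result a [GapResult].
#' @param thresholdUm strict lower threshold in microns (default 12).
#' @return list with `radii_um` (filtered, fit order preserved), `count`,
#'   `median_um`, `iqr_um`.
#' @export
radiusDistribution <- function(result, thresholdUm = 12) {
  stopifnot(is(result, "GapResult"))
  r <- result@circles$radius_um
  keep <- r[r > thresholdUm]
  list(radii_um = keep, count = length(keep),
       median_um = if (length(keep)) stats::median(keep) else NA_real_,
       iqr_um = if (length(keep)) stats::IQR(keep) else NA_real_)
}
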