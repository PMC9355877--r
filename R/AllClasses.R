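#' @import methods
NULL

#' Calibrated 2D microscopy image
#'
#' A single-channel pixel grid together with its physical pixel size. All
#' downstream quantifications obtain their micron units from this calibration;
#' pixels are addressed as `[row, col]` with 1-based indices and pixel centres
#' at integer coordinates. Pixels are assumed isotropic; anisotropic
#' calibrations must be resampled upstream and are rejected here.
#'
#' @slot pixels numeric matrix of intensities (arbitrary units, >= 1x1).
#' @slot pixelSizeUm positive scalar, microns per pixel (isotropic).
#' @slot channel free-text channel label (e.g. "PDPN", "DAPI").
#' @export
setClass("CalibratedImage", representation(
  pixels = "matrix",
  pixelSizeUm = "numeric",
  channel = "character"
))

setValidity("CalibratedImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L ||
      nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
    msg <- c(msg, "'pixels' must be a numeric matrix with >= 1 row and column")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive finite number")
  if (length(object@channel) != 1L)
    msg <- c(msg, "'channel' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Ordered stack of calibrated planes
#'
#' Either a spatial z-stack (`zStepUm` set) or a time-lapse
#' (`frameIntervalS` set) -- exactly one of the two intervals is non-NA.
#' All planes share shape and pixel calibration.
#'
#' @slot planes list of [CalibratedImage] objects.
#' @slot zStepUm z spacing in microns (NA for a time-lapse).
#' @slot frameIntervalS frame interval in seconds (NA for a z-stack).
#' @export
setClass("ImageStack", representation(
  planes = "list",
  zStepUm = "numeric",
  frameIntervalS = "numeric"
))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(object@planes) < 1L)
    msg <- c(msg, "stack must contain at least one plane")
  if (!all(vapply(object@planes, is, logical(1), "CalibratedImage")))
    msg <- c(msg, "all planes must be CalibratedImage objects")
  else {
    dims <- vapply(object@planes, function(p) dim(p@pixels), integer(2))
    cal <- vapply(object@planes, function(p) p@pixelSizeUm, numeric(1))
    if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)
      msg <- c(msg, "all planes must share the same shape")
    if (max(cal) - min(cal) > 1e-12)
      msg <- c(msg, "all planes must share the same pixel calibration")
  }
  zset <- !is.na(object@zStepUm)
  tset <- !is.na(object@frameIntervalS)
  if (zset == tset)
    msg <- c(msg, "exactly one of 'zStepUm' and 'frameIntervalS' must be set")
  if (zset && object@zStepUm <= 0)
    msg <- c(msg, "'zStepUm' must be positive")
  if (tset && object@frameIntervalS <= 0)
    msg <- c(msg, "'frameIntervalS' must be positive")
  if (length(msg)) msg else TRUE
})

#' Polygon or polyline region of interest in pixel coordinates
#'
#' Closed polygons delimit counting regions (e.g. a paracortex field); open
#' polylines trace hand-drawn fibers. Vertices are `(row, col)` pixel
#' coordinates.
#'
#' @slot vertices numeric matrix with columns `row`, `col`.
#' @slot closed logical; closed polygon (TRUE) or open polyline (FALSE).
#' @export
setClass("RegionROI", representation(
  vertices = "matrix",
  closed = "logical"
))

setValidity("RegionROI", function(object) {
  msg <- character()
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    msg <- c(msg, "'vertices' must be a numeric matrix with 2 columns (row, col)")
  else {
    if (object@closed && nrow(v) < 3L)
      msg <- c(msg, "a closed ROI needs >= 3 vertices")
    if (!object@closed && nrow(v) < 2L)
      msg <- c(msg, "a polyline ROI needs >= 2 vertices")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a gap analysis (maximal-circle packing)
#'
#' @slot circles data.frame with columns `rank`, `row`, `col`, `radius_px`,
#'   `radius_um` ordered by fit rank (radii non-increasing).
#' @slot rMinPx stopping radius in pixels.
#' @slot thresholdUm reporting threshold in microns (strict `>`).
#' @slot pixelSizeUm calibration used for micron radii.
#' @slot maskDim dimensions of the analysed mask.
#' @slot provenance named list recording binarization method and parameters.
#' @export
setClass("GapResult", representation(
  circles = "data.frame",
  rMinPx = "numeric",
  thresholdUm = "numeric",
  pixelSizeUm = "numeric",
  maskDim = "integer",
  provenance = "list"
))

#' Baseline-referenced recoil displacement trace
#'
#' Displacement between two network landmarks, referenced to the mean pre-cut
#' separation so pre-cut frames average to zero. `cutIndex` is the 1-based
#' index of the first post-cut frame.
#'
#' @slot timesS strictly increasing time grid in seconds.
#' @slot displacementUm baseline-referenced displacement per frame (microns).
#' @slot cutIndex integer index of the first post-cut frame.
#' @slot frameIntervalS frame interval in seconds.
#' @export
setClass("RecoilTrace", representation(
  timesS = "numeric",
  displacementUm = "numeric",
  cutIndex = "integer",
  frameIntervalS = "numeric"
))

setValidity("RecoilTrace", function(object) {
  msg <- character()
  n <- length(object@timesS)
  if (length(object@displacementUm) != n)
    msg <- c(msg, "times and displacement must have equal length")
  if (n > 1L && any(diff(object@timesS) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (object@cutIndex < 1L || object@cutIndex > n)
    msg <- c(msg, "'cutIndex' out of range")
  if (object@frameIntervalS <= 0)
    msg <- c(msg, "'frameIntervalS' must be positive")
  if (length(msg)) msg else TRUE
})

#' Trapped-bead position trace
#'
#' One-dimensional bead position along the pull axis, sampled on a regular
#' grid, with the bath temperature needed for equipartition calibration.
#'
#' @slot timesS strictly increasing sample times (seconds).
#' @slot positionNm bead position in nanometres.
#' @slot temperatureK bath temperature in kelvin (default 310.15, i.e. 37 C).
#' @export
setClass("BeadTrack", representation(
  timesS = "numeric",
  positionNm = "numeric",
  temperatureK = "numeric"
))

setValidity("BeadTrack", function(object) {
  msg <- character()
  if (length(object@positionNm) != length(object@timesS))
    msg <- c(msg, "times and positions must have equal length")
  if (length(object@timesS) > 1L && any(diff(object@timesS) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (object@temperatureK <= 0)
    msg <- c(msg, "'temperatureK' must be positive")
  if (length(msg)) msg else TRUE
})

#' Trap stiffness calibration
#'
#' @slot kPnPerNm trap stiffness in pN/nm.
#' @slot method calibration method ("equipartition").
#' @slot nSamples number of samples used.
#' @slot varianceNm2 positional variance (nm^2).
#' @slot temperatureK temperature used (K).
#' @export
setClass("TrapCalibration", representation(
  kPnPerNm = "numeric",
  method = "character",
  nSamples = "integer",
  varianceNm2 = "numeric",
  temperatureK = "numeric"
))

#' Cell-diameter swelling trace
#'
#' @slot timesMin sample times in minutes (default grid spacing 0.5 min).
#' @slot diameterUm cell diameter per frame in microns (all > 0).
#' @slot condition condition label, e.g. "ISO", "HYPO", "EXTREME".
#' @export
setClass("SwellingTrace", representation(
  timesMin = "numeric",
  diameterUm = "numeric",
  condition = "character"
))

setValidity("SwellingTrace", function(object) {
  msg <- character()
  if (length(object@diameterUm) != length(object@timesMin))
    msg <- c(msg, "times and diameters must have equal length")
  if (length(object@timesMin) > 1L && any(diff(object@timesMin) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@diameterUm)) || any(object@diameterUm <= 0))
    msg <- c(msg, "diameters must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' Linked nuclei trajectories over a time-lapse
#'
#' @slot tracks data.frame with columns `track`, `frame`, `row`, `col`;
#'   within a track frames are strictly increasing, one position per frame.
#' @slot frameIntervalH frame interval in hours.
#' @slot substrate substrate label (e.g. "2kPa", "12kPa", "30kPa", "glass").
#' @export
setClass("TrackSet", representation(
  tracks = "data.frame",
  frameIntervalH = "numeric",
  substrate = "character"
))

setValidity("TrackSet", function(object) {
  msg <- character()
  tr <- object@tracks
  need <- c("track", "frame", "row", "col")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "tracks must have columns track, frame, row, col")
  else if (nrow(tr) > 0L) {
    byTrack <- split(tr$frame, tr$track)
    if (any(vapply(byTrack, function(f) any(diff(sort(f)) == 0) ||
                     any(diff(f) <= 0), logical(1))))
      msg <- c(msg, "frames within a track must be strictly increasing")
  }
  if (object@frameIntervalH <= 0)
    msg <- c(msg, "'frameIntervalH' must be positive")
  if (length(msg)) msg else TRUE
})
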