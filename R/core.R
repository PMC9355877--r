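# Shared data model: constructors, accessors, image I/O, CSV tables.

#' Construct a calibrated image
#'
#' @param pixels numeric matrix of intensities, `[row, col]` indexed.
#' @param pixelSizeUm microns per pixel (isotropic, > 0). Anisotropic
#'   calibrations (a length-2 vector with unequal entries) are rejected.
#' @param channel optional channel label.
#' @return a [CalibratedImage].
#' @examples
#' img <- CalibratedImage(matrix(0, 64, 64), pixelSizeUm = 0.5)
#' physicalSizeUm(img)   # 32 x 32 um
#' @export
CalibratedImage <- function(pixels, pixelSizeUm, channel = "") {
  if (length(pixelSizeUm) == 2L) {
    if (abs(pixelSizeUm[1] - pixelSizeUm[2]) > 1e-9)
      stop("anisotropic pixel calibration is not supported; resample first")
    pixelSizeUm <- pixelSizeUm[1]
  }
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("CalibratedImage", pixels = pixels,
      pixelSizeUm = as.numeric(pixelSizeUm), channel = as.character(channel))
}

#' @rdname CalibratedImage-class
#' @export
setMethod("pixels", "CalibratedImage", function(x) x@pixels)

#' @rdname CalibratedImage-class
#' @export
setMethod("pixelSizeUm", "CalibratedImage", function(x) x@pixelSizeUm)

#' @rdname CalibratedImage-class
#' @export
setMethod("channelLabel", "CalibratedImage", function(x) x@channel)

#' Physical extent of a calibrated image
#'
#' @param x a [CalibratedImage].
#' @return numeric `(height_um, width_um)` = shape x pixel size.
#' @export
physicalSizeUm <- function(x) {
  stopifnot(is(x, "CalibratedImage"))
  unname(dim(x@pixels) * x@pixelSizeUm)
}

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage %dx%d px (%.3g x %.3g um) @ %g um/px%s\n",
              d[1], d[2], d[1] * object@pixelSizeUm, d[2] * object@pixelSizeUm,
              object@pixelSizeUm,
              if (nzchar(object@channel)) paste0(" [", object@channel, "]") else ""))
})

#' Construct an image stack
#'
#' @param planes list of [CalibratedImage] objects, or a 3D array
#'   `[row, col, plane]` plus `pixelSizeUm`.
#' @param pixelSizeUm calibration, required when `planes` is an array.
#' @param zStepUm z spacing in microns (spatial stack).
#' @param frameIntervalS frame interval in seconds (time-lapse). Exactly one
#'   of `zStepUm`/`frameIntervalS` must be given.
#' @param channel channel label applied when building planes from an array.
#' @return an [ImageStack].
#' @export
ImageStack <- function(planes, pixelSizeUm = NULL, zStepUm = NA_real_,
                       frameIntervalS = NA_real_, channel = "") {
  if (is.array(planes) && length(dim(planes)) == 3L) {
    stopifnot(!is.null(pixelSizeUm))
    planes <- lapply(seq_len(dim(planes)[3]), function(i)
      CalibratedImage(planes[, , i], pixelSizeUm, channel))
  }
  new("ImageStack", planes = planes, zStepUm = as.numeric(zStepUm),
      frameIntervalS = as.numeric(frameIntervalS))
}

#' @rdname ImageStack-class
#' @export
setMethod("planes", "ImageStack", function(x) x@planes)

#' @rdname ImageStack-class
#' @export
setMethod("frameIntervalS", "ImageStack", function(x) x@frameIntervalS)

#' @rdname ImageStack-class
#' @export
setMethod("zStepUm", "ImageStack", function(x) x@zStepUm)

#' @rdname ImageStack-class
#' @export
setMethod("isTimeLapse", "ImageStack", function(x) !is.na(x@frameIntervalS))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@planes[[1]]@pixels)
  kind <- if (isTimeLapse(object))
    sprintf("time-lapse, dt = %g s", object@frameIntervalS)
  else sprintf("z-stack, dz = %g um", object@zStepUm)
  cat(sprintf("ImageStack of %d plane(s) %dx%d px (%s)\n",
              length(object@planes), d[1], d[2], kind))
})

#' @rdname ImageStack-class
#' @export
setMethod("length", "ImageStack", function(x) length(x@planes))

#' Construct a region of interest
#'
#' @param vertices numeric matrix (or 2-column data.frame) of `(row, col)`
#'   pixel coordinates.
#' @param closed TRUE for a polygon, FALSE for a polyline (fiber trace).
#' @return a [RegionROI].
#' @export
RegionROI <- function(vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("row", "col")
  new("RegionROI", vertices = vertices, closed = closed)
}

#' Area of a closed ROI in square microns
#'
#' Shoelace polygon area times the squared pixel size.
#'
#' @param roi a closed [RegionROI].
#' @param pixelSizeUm microns per pixel.
#' @return area in um^2.
#' @export
roiAreaUm2 <- function(roi, pixelSizeUm) {
  stopifnot(is(roi, "RegionROI"), roi@closed, pixelSizeUm > 0)
  v <- roi@vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  areaPx <- abs(sum(v[, "row"] * v[j, "col"] - v[j, "row"] * v[, "col"])) / 2
  areaPx * pixelSizeUm^2
}

#' Read a single- or multi-page grayscale TIFF as a calibrated stack
#'
#' Calibration is supplied by the caller (configuration), not taken from TIFF
#' metadata; metadata dialects vary too much to trust silently. Integer
#' intensities are preserved as stored.
#'
#' @param path TIFF file path.
#' @param pixelSizeUm microns per pixel (> 0).
#' @param zStepUm z spacing for a spatial stack (default 1 um when neither
#'   interval is given).
#' @param frameIntervalS frame interval for a time-lapse.
#' @param channel channel label.
#' @return an [ImageStack].
#' @export
readImageStack <- function(path, pixelSizeUm, zStepUm = NULL,
                           frameIntervalS = NULL, channel = "") {
  if (!is.numeric(pixelSizeUm) || pixelSizeUm <= 0)
    stop("'pixelSizeUm' must be positive")
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (length(pages) == 0L) stop("empty TIFF: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of RGB pages
    p
  })
  if (is.null(zStepUm) && is.null(frameIntervalS)) zStepUm <- 1
  ImageStack(lapply(pages, CalibratedImage, pixelSizeUm = pixelSizeUm,
                    channel = channel),
             zStepUm = if (is.null(zStepUm)) NA_real_ else zStepUm,
             frameIntervalS = if (is.null(frameIntervalS)) NA_real_
             else frameIntervalS)
}

#' Write a stack (or single image) to a 16-bit grayscale TIFF
#'
#' Intensities are clamped to `[0, 65535]` and rounded, so integer counts up
#' to 16 bits round-trip losslessly through [readImageStack()].
#'
#' @param x an [ImageStack] or [CalibratedImage].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(x, path) {
  if (is(x, "CalibratedImage")) x <- ImageStack(list(x), zStepUm = 1)
  mats <- lapply(planes(x), function(p) {
    m <- round(pmin(pmax(p@pixels, 0), 65535))
    m / 65535
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write records to CSV with units embedded in column names
#'
#' @param records a data.frame whose column names carry units
#'   (e.g. `radius_um`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Read a CSV written by [writeRecords()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readRecords <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Maximum-intensity projection of a spatial stack
#'
#' @param stack a spatial [ImageStack] (`zStepUm` set). Passing a time-lapse
#'   signals misuse and errors.
#' @return a [CalibratedImage]: per-pixel maximum over planes.
#' @export
maxProject <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  if (isTimeLapse(stack))
    stop("maxProject expects a spatial z-stack, not a time-lapse")
  ps <- planes(stack)
  m <- Reduce(pmax, lapply(ps, pixels))
  CalibratedImage(m, pixelSizeUm(ps[[1]]), channelLabel(ps[[1]]))
}

# Rescale a matrix to [0,1] for EBImage routines that require it; constant
# images map to all-zero.
normalize01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - r[1]) / (r[2] - r[1])
}
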