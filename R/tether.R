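# Optical-tweezer tether analysis: equipartition trap calibration from a
# stationary bead trace, step detection for the tether pull, and trap force
# F_T = k * dx.

#' Construct a bead track
#'
#' @param positionNm bead positions along the pull axis (nm).
#' @param sampleIntervalS sampling interval in seconds (default 0.090).
#' @param timesS explicit sample times; overrides `sampleIntervalS`.
#' @param temperatureK bath temperature (K), default 310.15 (37 C).
#' @return a [BeadTrack].
#' @export
BeadTrack <- function(positionNm, sampleIntervalS = 0.090, timesS = NULL,
                      temperatureK = 310.15) {
  if (is.null(timesS))
    timesS <- (seq_along(positionNm) - 1) * sampleIntervalS
  new("BeadTrack", timesS = as.numeric(timesS),
      positionNm = as.numeric(positionNm),
      temperatureK = as.numeric(temperatureK))
}

#' Equipartition trap-stiffness calibration
#'
#' For a stationary trapped bead the equipartition theorem gives
#' `k = kB T / Var(x)` with `kB = 0.0138065` pN nm / K. The supplied window
#' must be tether-free; by default the whole track is used.
#'
#' @param track a [BeadTrack].
#' @param window optional index range (e.g. `1:500`) of the stationary,
#'   tether-free period.
#' @return a [TrapCalibration].
#' @export
calibrateEquipartition <- function(track, window = NULL) {
  stopifnot(is(track, "BeadTrack"))
  x <- track@positionNm
  if (!is.null(window)) x <- x[window]
  if (length(x) < 100L)
    stop("calibration needs >= 100 samples")
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0)
    stop("degenerate (constant) position trace; cannot calibrate")
  new("TrapCalibration",
      kPnPerNm = kBoltzmannPnNm * track@temperatureK / v,
      method = "equipartition", nSamples = length(x), varianceNm2 = v,
      temperatureK = track@temperatureK)
}

setMethod("show", "TrapCalibration", function(object) {
  cat(sprintf(
    "TrapCalibration (%s): k = %.4g pN/nm (Var = %.4g nm^2, n = %d, T = %g K)\n",
    object@method, object@kPnPerNm, object@varianceNm2, object@nSamples,
    object@temperatureK))
})

#' Detect baseline and tether-plateau windows in a bead trace
#'
#' Scans all candidate change points and maximizes the two-sample t-like
#' statistic (between-window mean separation over pooled within-window
#' standard error). A guard band around the detected step is excluded from
#' both windows. If the best statistic is below `minZ` no step is declared;
#' if a second significant step exists after the first, the first is used and
#' the result is flagged multi-step.
#'
#' @param track a [BeadTrack].
#' @param guardFrames frames excluded on each side of the step.
#' @param minZ significance threshold on the step statistic.
#' @return list with `baseline` and `plateau` index vectors, `changeIndex`
#'   (first plateau frame), `statistic`, `stepFound`, `multiStep`.
#' @export
detectTetherWindows <- function(track, guardFrames = 5, minZ = 8) {
  stopifnot(is(track, "BeadTrack"))
  x <- track@positionNm
  n <- length(x)
  if (n < 20L) stop("trace too short for step detection")
  bestAt <- function(x) {
    n <- length(x)
    cs <- cumsum(x); cs2 <- cumsum(x^2)
    k <- seq(5L, n - 5L)   # at least 5 frames per side
    m1 <- cs[k] / k
    m2 <- (cs[n] - cs[k]) / (n - k)
    ss1 <- cs2[k] - k * m1^2
    ss2 <- (cs2[n] - cs2[k]) - (n - k) * m2^2
    sp2 <- (ss1 + ss2) / (n - 2)
    z <- abs(m1 - m2) / sqrt(pmax(sp2, 1e-12) * (1 / k + 1 / (n - k)))
    i <- which.max(z)
    c(index = k[i], z = z[i])
  }
  # binary segmentation: collect all significant change points, earliest
  # first; the tether step is the first one
  segment <- function(from, to) {
    if (to - from + 1 < 20L) return(NULL)
    b <- bestAt(x[from:to])
    if (b["z"] < minZ) return(NULL)
    cp <- from - 1L + unname(b["index"])
    rbind(c(cp, unname(b["z"])), segment(from, cp), segment(cp + 1L, to))
  }
  cps <- segment(1L, n)
  if (is.null(cps)) {
    z0 <- bestAt(x)["z"]
    return(list(baseline = seq_len(n), plateau = integer(),
                changeIndex = NA_integer_, statistic = unname(z0),
                stepFound = FALSE, multiStep = FALSE))
  }
  ord <- order(cps[, 1])
  cp <- cps[ord[1], 1]                         # last baseline frame
  plateauEnd <- if (nrow(cps) > 1L) cps[ord[2], 1] else n
  baseline <- seq_len(max(cp - guardFrames, 1L))
  plateau <- seq(min(cp + 1L + guardFrames, plateauEnd), plateauEnd)
  list(baseline = baseline, plateau = plateau,
       changeIndex = as.integer(cp + 1L), statistic = cps[ord[1], 2],
       stepFound = TRUE, multiStep = nrow(cps) > 1L)
}

#' Trap force from calibration and windowed bead displacement
#'
#' `dx` is the absolute difference between the mean bead position in the
#' tether plateau and in the baseline; the trap force is `F_T = k dx`
#' (pN/nm x nm = pN).
#'
#' @param track a [BeadTrack].
#' @param calibration a [TrapCalibration].
#' @param baselineWindow,plateauWindow disjoint index vectors into the track.
#' @return data.frame with `delta_x_nm`, `k_pN_per_nm`, `force_pN`.
#' @export
tetherForce <- function(track, calibration, baselineWindow, plateauWindow) {
  stopifnot(is(track, "BeadTrack"), is(calibration, "TrapCalibration"))
  if (length(intersect(baselineWindow, plateauWindow)))
    stop("baseline and plateau windows must be disjoint")
  x <- track@positionNm
  if (max(baselineWindow) > length(x) || max(plateauWindow) > length(x))
    stop("window indices outside track")
  dx <- abs(mean(x[plateauWindow]) - mean(x[baselineWindow]))
  data.frame(delta_x_nm = dx, k_pN_per_nm = calibration@kPnPerNm,
             force_pN = calibration@kPnPerNm * dx)
}
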