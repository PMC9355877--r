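# Osmotic swelling: diameter-ratio kinetics d/d0, ratio at a stated
# timepoint, and area under the curve over the first 20 minutes.

#' Construct a swelling trace
#'
#' @param diameterUm per-frame cell diameters (um, > 0).
#' @param sampleIntervalMin sampling interval in minutes (default 0.5,
#'   i.e. every 30 s).
#' @param timesMin explicit sample times; overrides `sampleIntervalMin`.
#' @param condition condition label ("ISO", "HYPO", "EXTREME", ...).
#' @return a [SwellingTrace].
#' @export
SwellingTrace <- function(diameterUm, sampleIntervalMin = 0.5,
                          timesMin = NULL, condition = "HYPO") {
  if (is.null(timesMin))
    timesMin <- (seq_along(diameterUm) - 1) * sampleIntervalMin
  new("SwellingTrace", timesMin = as.numeric(timesMin),
      diameterUm = as.numeric(diameterUm), condition = condition)
}

#' Diameter-ratio series d / d0
#'
#' All diameters are divided by the initial diameter, so the series starts
#' at exactly 1.
#'
#' @param trace a [SwellingTrace].
#' @return numeric ratio series, same length as the trace.
#' @export
diameterRatio <- function(trace) {
  stopifnot(is(trace, "SwellingTrace"))
  d0 <- trace@diameterUm[1]
  if (d0 <= 0) stop("initial diameter must be positive")
  trace@diameterUm / d0
}

#' Area under the swelling curve over the first 20 minutes
#'
#' Trapezoidal integral of the ratio series over `[0, uptoMin]`. In the
#' default baseline-subtracted mode the integrand is `ratio - 1`, so an
#' isotonic (constant-ratio) control integrates to exactly 0; `baseline =
#' FALSE` integrates the raw ratio. If no sample falls exactly on the upper
#' limit the ratio there is linearly interpolated.
#'
#' @param trace a [SwellingTrace] spanning at least `uptoMin` minutes.
#' @param uptoMin upper integration limit in minutes (default 20).
#' @param baseline subtract 1 before integrating (default TRUE).
#' @return AUC in ratio x min.
#' @export
swellingAUC <- function(trace, uptoMin = 20, baseline = TRUE) {
  stopifnot(is(trace, "SwellingTrace"))
  t <- trace@timesMin
  if (max(t) < uptoMin)
    stop("trace spans ", max(t), " min; need >= ", uptoMin)
  r <- diameterRatio(trace)
  keep <- t <= uptoMin
  tt <- t[keep]; rr <- r[keep]
  if (max(tt) < uptoMin) {        # interpolate the endpoint
    rEnd <- stats::approx(t, r, xout = uptoMin)$y
    tt <- c(tt, uptoMin); rr <- c(rr, rEnd)
  }
  y <- if (baseline) rr - 1 else rr
  sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Swelling ratio at a stated timepoint
#'
#' Linear interpolation of the ratio series at `tMin` (default 15 min).
#'
#' @param trace a [SwellingTrace].
#' @param tMin query time in minutes, inside the trace span.
#' @return interpolated ratio.
#' @export
ratioAt <- function(trace, tMin = 15) {
  stopifnot(is(trace, "SwellingTrace"))
  t <- trace@timesMin
  if (tMin < min(t) || tMin > max(t))
    stop("'tMin' outside trace span")
  stats::approx(t, diameterRatio(trace), xout = tMin)$y
}

#' Summarize a swelling trace
#'
#' @param trace a [SwellingTrace].
#' @param atMin timepoint for the reported ratio (default 15).
#' @param aucUptoMin AUC upper limit (default 20).
#' @param baseline baseline-subtract the AUC integrand (default TRUE).
#' @return one-row data.frame: `condition`, `d0_um`, `ratio_at_15min`,
#'   `auc_0_20min`, `baseline_mode`.
#' @export
summarizeSwelling <- function(trace, atMin = 15, aucUptoMin = 20,
                              baseline = TRUE) {
  data.frame(condition = trace@condition, d0_um = trace@diameterUm[1],
             ratio_at_15min = ratioAt(trace, atMin),
             auc_0_20min = swellingAUC(trace, aucUptoMin, baseline),
             baseline_mode = if (baseline) "ratio_minus_1" else "raw_ratio")
}
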