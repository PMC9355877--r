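# Laser-ablation recoil: landmark-pair displacement, initial recoil velocity
# from the first post-cut frame, cohort mean curves, and an optional
# saturating-exponential fit.

#' Baseline-referenced displacement between two landmark tracks
#'
#' The recoil readout is the change in separation between two network
#' landmarks straddling the cut: `d[t] = ||a(t) - b(t)|| - baseline`, where
#' the baseline is the mean pre-cut separation (or the last pre-cut frame
#' with `baseline = "last"`), so pre-cut frames average to zero.
#'
#' @param a,b n x 2 matrices of landmark positions (same length). Units are
#'   microns unless `pixelSizeUm` converts pixel coordinates.
#' @param cutIndex 1-based index of the first post-cut frame (>= 2).
#' @param frameIntervalS frame interval in seconds (default 0.521).
#' @param pixelSizeUm set to convert pixel positions to microns (default 1,
#'   positions already in um).
#' @param baseline "mean" of all pre-cut frames (default) or "last".
#' @return a [RecoilTrace].
#' @export
displacementFromLandmarks <- function(a, b, cutIndex,
                                      frameIntervalS = 0.521,
                                      pixelSizeUm = 1,
                                      baseline = c("mean", "last")) {
  baseline <- match.arg(baseline)
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("landmark tracks must have equal length")
  n <- nrow(a)
  if (cutIndex < 2 || cutIndex > n) stop("'cutIndex' out of range")
  sep <- sqrt(rowSums((a - b)^2)) * pixelSizeUm
  pre <- seq_len(cutIndex - 1L)
  base <- if (baseline == "mean") mean(sep[pre]) else sep[cutIndex - 1L]
  new("RecoilTrace", timesS = (seq_len(n) - 1) * frameIntervalS,
      displacementUm = sep - base, cutIndex = as.integer(cutIndex),
      frameIntervalS = frameIntervalS)
}

#' Initial recoil velocity
#'
#' Displacement at the first post-cut frame divided by the frame interval --
#' the standard tension proxy for ablation assays.
#'
#' @param trace a [RecoilTrace].
#' @return velocity in um/s.
#' @export
initialRecoilVelocity <- function(trace) {
  stopifnot(is(trace, "RecoilTrace"))
  if (trace@cutIndex > length(trace@displacementUm))
    stop("trace has no post-cut frames")
  trace@displacementUm[trace@cutIndex] / trace@frameIntervalS
}

#' Fit a saturating exponential to the post-cut displacement
#'
#' Least-squares fit of `d(t') = A (1 - exp(-t'/tau))`, with `t'` the time
#' elapsed since the cut (the first post-cut frame sits at `t' =`
#' one frame interval). The fit smooths noisy traces and supports recovery
#' checks; the raw trace remains the primary measurement. A flat trace has
#' an unidentifiable tau and is returned flagged with `A = 0`.
#'
#' @param trace a [RecoilTrace] with >= 5 post-cut frames.
#' @return list with `A_um`, `tau_s`, `residual_rms_um`, `converged`,
#'   `flag` (NA or a reason).
#' @export
fitRecoil <- function(trace) {
  stopifnot(is(trace, "RecoilTrace"))
  post <- seq(trace@cutIndex, length(trace@timesS))
  if (length(post) < 5L) stop("need >= 5 post-cut frames to fit")
  tp <- trace@timesS[post] - trace@timesS[trace@cutIndex] +
    trace@frameIntervalS
  d <- trace@displacementUm[post]
  if (max(abs(d)) < 1e-12)
    return(list(A_um = 0, tau_s = NA_real_, residual_rms_um = 0,
                converged = TRUE, flag = "tau_unidentifiable"))
  start <- list(A = max(d), tau = max(tp[which(d >= 0.63 * max(d))[1]],
                                      trace@frameIntervalS))
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ A * (1 - exp(-tp / tau)), start = start,
                      lower = c(A = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A_um = NA_real_, tau_s = NA_real_,
                residual_rms_um = NA_real_, converged = FALSE,
                flag = "nonconvergence"))
  cf <- stats::coef(fit)
  list(A_um = unname(cf["A"]), tau_s = unname(cf["tau"]),
       residual_rms_um = sqrt(mean(stats::resid(fit)^2)),
       converged = TRUE, flag = NA_character_)
}

#' Pointwise mean and SEM recoil curve over a cohort of traces
#'
#' Traces are aligned at their first post-cut frame; per post-cut timepoint
#' the mean, standard error, and contributing n are reported (traces shorter
#' than the longest simply stop contributing).
#'
#' @param traces list of >= 2 [RecoilTrace] objects on a common frame
#'   interval.
#' @return data.frame with `t_post_s`, `mean_um`, `sem_um`, `n`.
#' @export
meanRecoilCurve <- function(traces) {
  if (length(traces) < 2L) stop("need >= 2 traces")
  dts <- vapply(traces, function(x) x@frameIntervalS, numeric(1))
  if (max(dts) - min(dts) > 1e-9)
    stop("traces must share a common frame interval")
  post <- lapply(traces, function(x)
    x@displacementUm[seq(x@cutIndex, length(x@displacementUm))])
  maxLen <- max(lengths(post))
  mat <- vapply(post, function(p) c(p, rep(NA_real_, maxLen - length(p))),
                numeric(maxLen))
  if (maxLen == 1L) mat <- matrix(mat, nrow = 1L)
  n <- rowSums(!is.na(mat))
  mean <- rowMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  })
  data.frame(t_post_s = seq_len(maxLen) * dts[1], mean_um = mean,
             sem_um = sem, n = n)
}
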