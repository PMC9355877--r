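# Seeded synthetic-data generators. Each generator is a pure function of its
# truth parameters (including the seed): identical inputs give identical
# outputs, and the exact ground truth is returned alongside the data so every
# downstream stage can be scored without real microscopy data.
#
# Defaults encode the acquisition conditions of the assays they emulate:
# 0.521 s recoil frames over 25 s, 90 ms bead sampling at 37 C with trap
# stiffness 0.114 pN/nm, 30 s swelling sampling, 72 h division movies.

#' Truth parameters for a synthetic fibrous-network image
#'
#' Edges of a jittered square lattice stand in for the interconnected
#' reticular network; mesh size is controlled by `spacingPx`, so the free-gap
#' scale is known by construction.
#'
#' @param sizePx image side length in pixels.
#' @param spacingPx lattice spacing (mesh size) in pixels.
#' @param jitterFrac node jitter as a fraction of spacing (0..0.45).
#' @param fiberWidthPx rendered fiber width in pixels (>= 1).
#' @param pixelSizeUm microns per pixel.
#' @param amplitude mean fiber photon count for the noise model.
#' @param readNoiseSd Gaussian read-noise SD (counts).
#' @param seed integer seed.
#' @return a `networkTruth` list.
#' @export
networkTruth <- function(sizePx = 256L, spacingPx = 24, jitterFrac = 0.2,
                         fiberWidthPx = 3, pixelSizeUm = 0.5, amplitude = 200,
                         readNoiseSd = 5, seed = 1L) {
  stopifnot(spacingPx >= 4, fiberWidthPx >= 1, jitterFrac >= 0, jitterFrac < 0.5)
  list(sizePx = as.integer(sizePx), spacingPx = spacingPx,
       jitterFrac = jitterFrac, fiberWidthPx = fiberWidthPx,
       pixelSizeUm = pixelSizeUm, amplitude = amplitude,
       readNoiseSd = readNoiseSd, seed = as.integer(seed))
}

# squared distance from pixel centres to segment p-q, vectorized over pixels
distToSegment <- function(rows, cols, p, q) {
  vr <- q[1] - p[1]; vc <- q[2] - p[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) return(sqrt((rows - p[1])^2 + (cols - p[2])^2))
  t <- ((rows - p[1]) * vr + (cols - p[2]) * vc) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((rows - (p[1] + t * vr))^2 + (cols - (p[2] + t * vc))^2)
}

#' Render a synthetic fibrous-network image with its true free-space mask
#'
#' Lattice nodes are jittered, neighbouring nodes joined by straight edges,
#' and edges dilated to the fiber width to give the ground-truth foreground.
#' The fluorescence-style image is the blurred foreground with Poisson shot
#' noise plus Gaussian read noise.
#'
#' @param truth a [networkTruth()] list.
#' @return list with `image` ([CalibratedImage]), `mask` (logical ground-truth
#'   foreground), `segments` (one edge per row: r0, c0, r1, c1), `truth`.
#' @export
makeNetworkImage <- function(truth) {
  withr::with_seed(truth$seed, {
    n <- truth$sizePx
    sp <- truth$spacingPx
    gr <- seq(1, n, by = sp)
    if (length(gr) < 2L) stop("lattice spacing too large for image size")
    nodesR <- outer(gr, rep(1, length(gr)))
    nodesC <- t(nodesR)
    jit <- sp * truth$jitterFrac
    nodesR <- nodesR + stats::runif(length(nodesR), -jit, jit)
    nodesC <- nodesC + stats::runif(length(nodesC), -jit, jit)
    nodesR <- pmin(pmax(nodesR, 1), n)
    nodesC <- pmin(pmax(nodesC, 1), n)
    k <- length(gr)
    segs <- list()
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (j < k) segs[[length(segs) + 1L]] <-
          c(nodesR[i, j], nodesC[i, j], nodesR[i, j + 1], nodesC[i, j + 1])
      if (i < k) segs[[length(segs) + 1L]] <-
          c(nodesR[i, j], nodesC[i, j], nodesR[i + 1, j], nodesC[i + 1, j])
    }
    segs <- do.call(rbind, segs)
    if (nrow(segs) < 1L) stop("network must contain at least one edge")
    if (any(segs < 0.5) || any(segs > n + 0.5))
      stop("segment endpoints outside image bounds")
    half <- truth$fiberWidthPx / 2
    fg <- matrix(FALSE, n, n)
    for (s in seq_len(nrow(segs))) {
      p <- segs[s, 1:2]; q <- segs[s, 3:4]
      r0 <- max(1L, floor(min(p[1], q[1]) - half - 1))
      r1 <- min(n, ceiling(max(p[1], q[1]) + half + 1))
      c0 <- max(1L, floor(min(p[2], q[2]) - half - 1))
      c1 <- min(n, ceiling(max(p[2], q[2]) + half + 1))
      rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
      cc <- matrix(rep(c0:c1, each = r1 - r0 + 1L), r1 - r0 + 1L)
      dd <- distToSegment(rr, cc, p, q)
      sub <- fg[r0:r1, c0:c1]
      fg[r0:r1, c0:c1] <- sub | (dd <= half)
    }
    clean <- EBImage::gblur(fg * truth$amplitude, sigma = 1)
    noisy <- matrix(stats::rpois(n * n, pmax(clean, 0)), n, n) +
      matrix(stats::rnorm(n * n, 0, truth$readNoiseSd), n, n)
    list(image = CalibratedImage(noisy, truth$pixelSizeUm, "network"),
         mask = fg, segments = segs, truth = truth)
  })
}

#' Truth parameters for a synthetic nuclei field
#'
#' @param n number of nuclei.
#' @param sizePx image side length in pixels.
#' @param radiusPx nucleus Gaussian radius (sigma) in pixels.
#' @param minSeparationPx minimum pairwise centroid separation.
#' @param exclusionMask optional logical matrix (e.g. a stromal stain mask);
#'   centroids avoid it only if `avoidMask = TRUE`.
#' @param avoidMask place nuclei only outside `exclusionMask`.
#' @param amplitude peak nucleus intensity (counts).
#' @param snr peak signal over noise SD; noise SD = amplitude / snr.
#' @param pixelSizeUm microns per pixel.
#' @param seed integer seed.
#' @return a `nucleiTruth` list.
#' @export
nucleiTruth <- function(n = 25L, sizePx = 256L, radiusPx = 4,
                        minSeparationPx = 4 * radiusPx, exclusionMask = NULL,
                        avoidMask = FALSE, amplitude = 500, snr = 10,
                        pixelSizeUm = 0.3, seed = 1L) {
  list(n = as.integer(n), sizePx = as.integer(sizePx), radiusPx = radiusPx,
       minSeparationPx = minSeparationPx, exclusionMask = exclusionMask,
       avoidMask = avoidMask, amplitude = amplitude, snr = snr,
       pixelSizeUm = pixelSizeUm, seed = as.integer(seed))
}

#' Render a synthetic nuclei image with known centroids
#'
#' Centroids are placed by dart-throwing to respect the minimum separation;
#' each nucleus is a Gaussian intensity profile; Gaussian noise of SD
#' `amplitude / snr` is added.
#'
#' @param truth a [nucleiTruth()] list.
#' @return list with `image` ([CalibratedImage]), `centroids` (n x 2 matrix,
#'   row/col), `truth`.
#' @export
makeNucleiImage <- function(truth) {
  withr::with_seed(truth$seed, {
    n <- truth$sizePx
    margin <- 3 * truth$radiusPx
    cent <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(cent) < truth$n && tries < 20000L) {
      tries <- tries + 1L
      p <- stats::runif(2, margin, n - margin)
      if (truth$avoidMask && !is.null(truth$exclusionMask) &&
          truth$exclusionMask[round(p[1]), round(p[2])]) next
      if (nrow(cent) == 0 ||
          min(sqrt((cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2)) >=
            truth$minSeparationPx)
        cent <- rbind(cent, p)
    }
    if (nrow(cent) < truth$n)
      stop("could not place nuclei at the requested separation; lower 'n'")
    img <- matrix(0, n, n)
    rows <- matrix(seq_len(n), n, n)
    cols <- t(rows)
    for (i in seq_len(nrow(cent))) {
      r0 <- cent[i, 1]; c0 <- cent[i, 2]
      w <- ceiling(4 * truth$radiusPx)
      rs <- max(1, floor(r0 - w)):min(n, ceiling(r0 + w))
      cs <- max(1, floor(c0 - w)):min(n, ceiling(c0 + w))
      img[rs, cs] <- img[rs, cs] + truth$amplitude *
        exp(-((rows[rs, cs] - r0)^2 + (cols[rs, cs] - c0)^2) /
              (2 * truth$radiusPx^2))
    }
    img <- img + matrix(stats::rnorm(n * n, 0, truth$amplitude / truth$snr), n, n)
    colnames(cent) <- c("row", "col")
    list(image = CalibratedImage(img, truth$pixelSizeUm, "nuclei"),
         centroids = cent, truth = truth)
  })
}

#' Truth parameters for a laser-ablation recoil trace
#'
#' The displacement after the cut follows a saturating exponential
#' `d(t) = A (1 - exp(-t / tau))`, the standard viscoelastic recoil form; the
#' default amplitude and timescale give an initial recoil velocity of about
#' 0.42 um/s at the 0.521 s frame interval, the steady-state regime of the
#' assay this generator emulates.
#'
#' @param amplitudeUm plateau recoil amplitude A (um, >= 0).
#' @param tauS recoil timescale tau (s, > 0).
#' @param noiseSdUm Gaussian measurement noise SD (um).
#' @param frameIntervalS frame interval (s), default 0.521.
#' @param durationS recording length (s), default 25.
#' @param cutTimeS time of the ablation cut (s).
#' @param seed integer seed.
#' @return a `recoilTruth` list.
#' @export
recoilTruth <- function(amplitudeUm = 1.372, tauS = 3, noiseSdUm = 0.05,
                        frameIntervalS = 0.521, durationS = 25,
                        cutTimeS = 2 * frameIntervalS, seed = 1L) {
  stopifnot(amplitudeUm >= 0, tauS > 0, frameIntervalS > 0, durationS > 0)
  list(amplitudeUm = amplitudeUm, tauS = tauS, noiseSdUm = noiseSdUm,
       frameIntervalS = frameIntervalS, durationS = durationS,
       cutTimeS = cutTimeS, seed = as.integer(seed))
}

#' Simulate a recoil displacement trace
#'
#' Displacement is zero for frames at or before the cut time and
#' `A (1 - exp(-(t - t_cut)/tau)) + N(0, noise)` after, sampled on the frame
#' grid.
#'
#' @param truth a [recoilTruth()] list.
#' @return a [RecoilTrace].
#' @export
makeRecoilTrace <- function(truth) {
  withr::with_seed(truth$seed, {
    times <- seq(0, truth$durationS, by = truth$frameIntervalS)
    post <- times > truth$cutTimeS
    d <- numeric(length(times))
    d[post] <- truth$amplitudeUm *
      (1 - exp(-(times[post] - truth$cutTimeS) / truth$tauS))
    if (truth$noiseSdUm > 0)
      d[post] <- d[post] + stats::rnorm(sum(post), 0, truth$noiseSdUm)
    new("RecoilTrace", timesS = times, displacementUm = d,
        cutIndex = as.integer(which(post)[1]),
        frameIntervalS = truth$frameIntervalS)
  })
}

#' Truth parameters for a trapped-bead position trace
#'
#' The bead is an Ornstein-Uhlenbeck process with stationary variance
#' `kB T / k` (equipartition); a tether pull shifts the mean by
#' `tetherStepNm` after `stepTimeS`.
#'
#' @param kPnPerNm trap stiffness (pN/nm), default 0.114.
#' @param temperatureK bath temperature (K), default 310.15.
#' @param relaxationTimeS OU relaxation time (s).
#' @param sampleIntervalS sampling interval (s), default 0.090.
#' @param durationS trace length (s).
#' @param tetherStepNm mean bead displacement during the tether plateau (nm).
#' @param stepTimeS time of tether formation (s); NA for no step.
#' @param seed integer seed.
#' @return a `beadTruth` list.
#' @export
beadTruth <- function(kPnPerNm = 0.114, temperatureK = 310.15,
                      relaxationTimeS = 0.05, sampleIntervalS = 0.090,
                      durationS = 90, tetherStepNm = 0, stepTimeS = NA,
                      seed = 1L) {
  stopifnot(kPnPerNm > 0, temperatureK > 0, relaxationTimeS > 0,
            sampleIntervalS > 0)
  list(kPnPerNm = kPnPerNm, temperatureK = temperatureK,
       relaxationTimeS = relaxationTimeS, sampleIntervalS = sampleIntervalS,
       durationS = durationS, tetherStepNm = tetherStepNm,
       stepTimeS = stepTimeS, seed = as.integer(seed))
}

#' Boltzmann constant in pN nm / K
#' @export
kBoltzmannPnNm <- 0.0138065

#' Simulate a trapped-bead position trace
#'
#' Exact discrete-time OU update (not Euler), so the stationary variance is
#' `kB T / k` at any sampling interval:
#' `x[i+1] = mu + (x[i] - mu) a + s sqrt(1 - a^2) z`, with
#' `a = exp(-dt/tau_r)` and `s^2 = kB T / k`.
#'
#' @param truth a [beadTruth()] list.
#' @return a [BeadTrack]; fewer than 100 samples is rejected (calibration on
#'   such a trace would be unreliable).
#' @export
makeBeadTrace <- function(truth) {
  times <- seq(0, truth$durationS, by = truth$sampleIntervalS)
  if (length(times) < 100L)
    stop("bead trace must contain at least 100 samples")
  withr::with_seed(truth$seed, {
    sEq <- sqrt(kBoltzmannPnNm * truth$temperatureK / truth$kPnPerNm)
    a <- exp(-truth$sampleIntervalS / truth$relaxationTimeS)
    mu <- numeric(length(times))
    if (!is.na(truth$stepTimeS))
      mu[times > truth$stepTimeS] <- truth$tetherStepNm
    x <- numeric(length(times))
    x[1] <- mu[1] + stats::rnorm(1, 0, sEq)
    z <- stats::rnorm(length(times) - 1)
    for (i in seq_along(z))
      x[i + 1] <- mu[i + 1] + (x[i] - mu[i + 1]) * a + sEq * sqrt(1 - a^2) * z[i]
    new("BeadTrack", timesS = times, positionNm = x,
        temperatureK = truth$temperatureK)
  })
}

#' Truth parameters for an osmotic-swelling diameter trace
#'
#' Ratio kinetics follow `1 + (plateau - 1)(1 - exp(-rate t))`; an isotonic
#' control has plateau 1 (no swelling), a hypotonic challenge plateau > 1.
#'
#' @param d0Um initial diameter (um, > 0).
#' @param plateauRatio asymptotic d/d0 (>= 1).
#' @param ratePerMin swelling rate constant (1/min).
#' @param noiseSdUm diameter measurement noise SD (um).
#' @param sampleIntervalMin sampling interval (min), default 0.5 (every 30 s).
#' @param durationMin trace length (min).
#' @param condition label ("ISO", "HYPO", "EXTREME").
#' @param seed integer seed.
#' @return a `swellingTruth` list.
#' @export
swellingTruth <- function(d0Um = 20, plateauRatio = 1.2, ratePerMin = 0.15,
                          noiseSdUm = 0.1, sampleIntervalMin = 0.5,
                          durationMin = 30, condition = "HYPO", seed = 1L) {
  stopifnot(d0Um > 0, plateauRatio >= 1, ratePerMin >= 0)
  list(d0Um = d0Um, plateauRatio = plateauRatio, ratePerMin = ratePerMin,
       noiseSdUm = noiseSdUm, sampleIntervalMin = sampleIntervalMin,
       durationMin = durationMin, condition = condition,
       seed = as.integer(seed))
}

#' Simulate a cell-diameter swelling trace
#'
#' @param truth a [swellingTruth()] list.
#' @return a [SwellingTrace]; the first sample is exactly `d0Um` so the ratio
#'   trace starts at 1 (the manual-ROI reference frame).
#' @export
makeSwellingTrace <- function(truth) {
  withr::with_seed(truth$seed, {
    times <- seq(0, truth$durationMin, by = truth$sampleIntervalMin)
    ratio <- 1 + (truth$plateauRatio - 1) * (1 - exp(-truth$ratePerMin * times))
    d <- truth$d0Um * ratio
    if (truth$noiseSdUm > 0) {
      noise <- stats::rnorm(length(times), 0, truth$noiseSdUm)
      noise[1] <- 0
      d <- d + noise
    }
    new("SwellingTrace", timesMin = times, diameterUm = pmax(d, 1e-6),
        condition = truth$condition)
  })
}

#' Truth parameters for a nuclei division movie
#'
#' Nuclei random-walk with step `motilityStepPx` per frame; each nucleus
#' divides with per-frame probability `1 - exp(-rate * dt)`. At a division
#' the parent detection disappears and two daughters appear on opposite sides
#' at `daughterOffsetPx` from the parent position, so the pair is separated
#' by twice the offset (kept larger than the linking search step so a
#' division reads as a track termination plus two track births).
#'
#' @param n0 starting nuclei count.
#' @param divisionRatePerH divisions per cell per hour.
#' @param frameIntervalH frame interval (h).
#' @param durationH movie length (h), default 72.
#' @param sizePx field side length (px).
#' @param motilityStepPx random-walk step SD per frame (px).
#' @param daughterOffsetPx distance of each daughter from the parent's last
#'   detected position (px); both daughters appear on opposite sides, so the
#'   pair is `2 * daughterOffsetPx` apart.
#' @param refractoryH minimum time after birth before a daughter may divide
#'   (h); emulates the cell cycle, default 10.
#' @param clearRadiusPx a cell divides only when no other cell is within
#'   this radius (px), so daughters are born clear of unrelated tracks;
#'   default `3.5 * daughterOffsetPx`, which also keeps daughters of two
#'   simultaneous divisions at least the minimum separation apart.
#' @param minSeparationPx nuclei keep at least this pairwise distance (px):
#'   moves that would bring two cells closer are rejected, emulating nuclear
#'   excluded volume and keeping track identities unambiguous (default 10).
#' @param tailGuardFrames no divisions within this many frames of the movie
#'   end, so both daughters are always observable (default 3, matching the
#'   default minimum daughter track length).
#' @param substrate substrate stiffness label.
#' @param seed integer seed.
#' @return a `divisionTruth` list.
#' @export
divisionTruth <- function(n0 = 50L, divisionRatePerH = 0.01,
                          frameIntervalH = 1, durationH = 72, sizePx = 600L,
                          motilityStepPx = 1, daughterOffsetPx = 8,
                          refractoryH = 10, tailGuardFrames = 3L,
                          clearRadiusPx = 3.5 * daughterOffsetPx,
                          minSeparationPx = 10, substrate = "glass",
                          seed = 1L) {
  stopifnot(n0 >= 1, divisionRatePerH >= 0, frameIntervalH > 0)
  list(n0 = as.integer(n0), divisionRatePerH = divisionRatePerH,
       frameIntervalH = frameIntervalH, durationH = durationH,
       sizePx = as.integer(sizePx), motilityStepPx = motilityStepPx,
       daughterOffsetPx = daughterOffsetPx, refractoryH = refractoryH,
       tailGuardFrames = as.integer(tailGuardFrames),
       clearRadiusPx = clearRadiusPx, minSeparationPx = minSeparationPx,
       substrate = substrate, seed = as.integer(seed))
}

#' Reference division rates per substrate stiffness
#'
#' Divisions per cell per hour used for the synthetic substrate-stiffness
#' cohorts (2 kPa, 12 kPa, 30 kPa polyacrylamide, glass). Rates increase
#' steeply with stiffness -- near proliferative arrest on the softest gel
#' versus roughly one division per cell per half-day equivalent on glass --
#' and are spaced so that a 72-h movie of 100 starting nuclei separates
#' neighbouring conditions well beyond counting noise.
#' @export
substrateDivisionRates <- c("2kPa" = 0.006, "12kPa" = 0.015,
                            "30kPa" = 0.032, "glass" = 0.080)

#' Simulate a nuclei time-lapse with division events
#'
#' @param truth a [divisionTruth()] list.
#' @return list with `detections` (data.frame frame/row/col), `events`
#'   (data.frame parent cell id, frame, daughter ids), `n0`, `nFrames`,
#'   `truth`. Frames are 1-based; daughters first appear at the event frame,
#'   the parent's last detection is the frame before.
#' @export
makeDivisionMovie <- function(truth) {
  withr::with_seed(truth$seed, {
    nFrames <- as.integer(floor(truth$durationH / truth$frameIntervalH)) + 1L
    pDiv <- 1 - exp(-truth$divisionRatePerH * truth$frameIntervalH)
    refrFrames <- ceiling(truth$refractoryH / truth$frameIntervalH)
    lastDivFrame <- nFrames - truth$tailGuardFrames
    margin <- 4 * truth$daughterOffsetPx
    # dart-throwing initial placement at the minimum separation
    pos <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pos) < truth$n0 && tries < 100000L) {
      tries <- tries + 1L
      p <- stats::runif(2, margin, truth$sizePx - margin)
      if (nrow(pos) == 0L ||
          min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >=
            truth$minSeparationPx)
        pos <- rbind(pos, p)
    }
    if (nrow(pos) < truth$n0)
      stop("field too crowded for the requested minimum separation")
    ids <- seq_len(truth$n0)
    bornAt <- rep(-refrFrames, truth$n0)   # starters are division-competent
    pending <- logical(truth$n0)
    nextId <- truth$n0 + 1L
    det <- list(); ev <- list()
    det[[1]] <- data.frame(frame = 1L, row = pos[, 1], col = pos[, 2],
                           cell = ids)
    for (f in 2L:nFrames) {
      # a dividing cell is replaced in place: daughters appear on opposite
      # sides of its last detected position, so a division reads as a track
      # termination plus two births, never as a small displacement
      pending <- pending | (stats::runif(nrow(pos)) < pDiv &
                              (f - bornAt) > refrFrames)
      divide <- pending & f <= lastDivFrame
      if (any(divide) && nrow(pos) > 1L) {
        # crowded cells postpone mitosis until daughters can be born clear
        # of other tracks
        dAll <- as.matrix(stats::dist(pos))
        diag(dAll) <- Inf
        divide <- divide & apply(dAll, 1, min) > truth$clearRadiusPx
      }
      if (any(divide)) {
        for (i in which(divide)) {
          theta <- stats::runif(1, 0, pi)
          off <- truth$daughterOffsetPx * c(cos(theta), sin(theta))
          d1 <- pmin(pmax(pos[i, ] + off, 1), truth$sizePx)
          d2 <- pmin(pmax(pos[i, ] - off, 1), truth$sizePx)
          ev[[length(ev) + 1L]] <- data.frame(
            parent = ids[i], frame = f,
            daughter1 = nextId, daughter2 = nextId + 1L)
          pos <- rbind(pos, d1, d2)
          ids <- c(ids, nextId, nextId + 1L)
          bornAt <- c(bornAt, f, f)
          pending <- c(pending, FALSE, FALSE)
          nextId <- nextId + 2L
        }
        keep <- !c(divide, rep(FALSE, 2 * sum(divide)))
        pos <- pos[keep, , drop = FALSE]
        ids <- ids[keep]
        bornAt <- bornAt[keep]
        pending <- pending[keep]
      }
      step <- matrix(stats::rnorm(length(pos), 0, truth$motilityStepPx),
                     ncol = 2)
      step[bornAt == f, ] <- 0   # daughters hold their birth position
      cand <- pmin(pmax(pos + step, 1), truth$sizePx)
      # excluded volume: revert moves that would bring two nuclei closer
      # than the minimum separation (the pre-move configuration satisfies it)
      if (nrow(cand) > 1L) for (it in 1:5) {
        dAll <- as.matrix(stats::dist(cand))
        diag(dAll) <- Inf
        bad <- apply(dAll, 1, min) < truth$minSeparationPx & bornAt < f
        if (!any(bad)) break
        cand[bad, ] <- pos[bad, ]
      }
      pos <- cand
      det[[f]] <- data.frame(frame = f, row = pos[, 1], col = pos[, 2],
                             cell = ids)
    }
    list(detections = do.call(rbind, det),
         events = if (length(ev)) do.call(rbind, ev)
         else data.frame(parent = integer(), frame = integer(),
                         daughter1 = integer(), daughter2 = integer()),
         n0 = truth$n0, nFrames = nFrames, truth = truth)
  })
}

#' Simulate a pair of landmark tracks around an ablation cut
#'
#' Two landmarks straddling the cut separate according to the recoil model:
#' each moves outward by half the model displacement along the separation
#' axis, with independent positional noise. Useful for exercising
#' [displacementFromLandmarks()] end to end.
#'
#' @param truth a [recoilTruth()] list; `noiseSdUm` is applied per landmark
#'   coordinate.
#' @param separationUm pre-cut landmark separation (um).
#' @return list with `a`, `b` (n x 2 matrices of um coordinates), `times_s`,
#'   `cutIndex`, `truth`.
#' @export
makeLandmarkTracks <- function(truth, separationUm = 10) {
  withr::with_seed(truth$seed, {
    times <- seq(0, truth$durationS, by = truth$frameIntervalS)
    post <- times > truth$cutTimeS
    d <- numeric(length(times))
    d[post] <- truth$amplitudeUm *
      (1 - exp(-(times[post] - truth$cutTimeS) / truth$tauS))
    half <- d / 2
    a <- cbind(rep(0, length(times)), -separationUm / 2 - half)
    b <- cbind(rep(0, length(times)), separationUm / 2 + half)
    if (truth$noiseSdUm > 0) {
      a <- a + matrix(stats::rnorm(length(a), 0, truth$noiseSdUm / 2), ncol = 2)
      b <- b + matrix(stats::rnorm(length(b), 0, truth$noiseSdUm / 2), ncol = 2)
    }
    list(a = a, b = b, times_s = times, cutIndex = as.integer(which(post)[1]),
         truth = truth)
  })
}
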