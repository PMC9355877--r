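# Proliferation tracking: link nuclei detections over a 72-h time-lapse,
# detect division events (a terminating track replaced by two nearby track
# births), and report divisions per starting cell.

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour matching between consecutive frames: the
#' globally closest (track, detection) pair within `maxDispPx` is linked
#' first, then the next among the remaining, and so on -- equivalent to
#' accepting mutually nearest pairs in order of distance. Tracks missing one
#' frame may be closed over a single-frame gap; unmatched detections start
#' new tracks. Poor linking surfaces in QC, never as an error.
#'
#' @param detections data.frame with columns `frame`, `row`, `col` covering
#'   >= 2 frames (frames need not start at 1).
#' @param maxDispPx maximum frame-to-frame displacement (px).
#' @param frameIntervalH frame interval in hours (default 1).
#' @param substrate substrate label carried into the result.
#' @param gapFrames frames a track may skip and still be continued
#'   (default 1).
#' @return a [TrackSet].
#' @export
linkDetections <- function(detections, maxDispPx, frameIntervalH = 1,
                           substrate = "", gapFrames = 1L) {
  stopifnot(all(c("frame", "row", "col") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2L) stop("need detections on >= 2 frames")
  det <- detections[order(detections$frame), , drop = FALSE]
  byFrame <- split(det[, c("row", "col")], det$frame)
  # active track state
  lastRow <- numeric(0); lastCol <- numeric(0)
  lastFrame <- integer(0); trackId <- integer(0)
  nextId <- 1L
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    p <- as.matrix(byFrame[[as.character(f)]])
    nDet <- nrow(p)
    assigned <- rep(NA_integer_, nDet)
    # consecutive-frame links take precedence; gap closure only competes
    # for the leftover detections
    for (gap in 0L:gapFrames) {
      active <- which(lastFrame == f - 1L - gap)
      free <- which(is.na(assigned))
      if (!length(active) || !length(free)) next
      dmat <- sqrt(outer(lastRow[active], p[free, 1], "-")^2 +
                     outer(lastCol[active], p[free, 2], "-")^2)
      dmat <- matrix(dmat, length(active), length(free))
      # accept candidate pairs in order of distance (greedy matching)
      cand <- which(dmat <= maxDispPx)
      if (length(cand)) {
        cand <- cand[order(dmat[cand])]
        ri <- ((cand - 1L) %% nrow(dmat)) + 1L
        ci <- ((cand - 1L) %/% nrow(dmat)) + 1L
        usedT <- logical(nrow(dmat)); usedD <- logical(ncol(dmat))
        for (k in seq_along(cand)) {
          if (usedT[ri[k]] || usedD[ci[k]]) next
          usedT[ri[k]] <- TRUE; usedD[ci[k]] <- TRUE
          assigned[free[ci[k]]] <- active[ri[k]]
        }
      }
    }
    ids <- integer(nDet)
    for (di in seq_len(nDet)) {
      if (!is.na(assigned[di])) {
        ti <- assigned[di]
        lastRow[ti] <- p[di, 1]; lastCol[ti] <- p[di, 2]; lastFrame[ti] <- f
        ids[di] <- trackId[ti]
      } else {
        lastRow <- c(lastRow, p[di, 1]); lastCol <- c(lastCol, p[di, 2])
        lastFrame <- c(lastFrame, f); trackId <- c(trackId, nextId)
        ids[di] <- nextId
        nextId <- nextId + 1L
      }
    }
    out[[fi]] <- data.frame(track = ids, frame = f, row = p[, 1],
                            col = p[, 2])
  }
  tr <- do.call(rbind, out)
  tr <- tr[order(tr$track, tr$frame), , drop = FALSE]
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, frameIntervalH = frameIntervalH,
      substrate = substrate)
}

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s), %d frame(s), dt = %g h%s\n",
              length(unique(object@tracks$track)),
              length(unique(object@tracks$frame)), object@frameIntervalH,
              if (nzchar(object@substrate))
                paste0(" [", object@substrate, "]") else ""))
})

#' Detect division events in a track set
#'
#' An event is a track that terminates at frame `f` while at least two new
#' tracks begin at `f + 1` (or `f + 2`, tolerating one dropped frame) within
#' `searchRadiusPx` of its last position, each persisting at least
#' `minDaughterLenFrames`. The two nearest qualifying births are assigned as
#' daughters; a birth not paired with any terminating parent is an entering
#' cell, never a division. Each birth is consumed by at most one event.
#'
#' @param trackSet a [TrackSet].
#' @param searchRadiusPx search radius around the parent's last position
#'   (px); roughly twice a nucleus diameter.
#' @param minDaughterLenFrames minimum daughter track length (default 3).
#' @return data.frame, one row per event: `parent`, `frame` (daughters'
#'   first frame), `daughter1`, `daughter2`.
#' @export
detectDivisions <- function(trackSet, searchRadiusPx,
                            minDaughterLenFrames = 3L) {
  stopifnot(is(trackSet, "TrackSet"))
  tr <- trackSet@tracks
  if (nrow(tr) == 0L)
    return(data.frame(parent = integer(), frame = integer(),
                      daughter1 = integer(), daughter2 = integer()))
  lastFrame <- tapply(tr$frame, tr$track, max)
  firstFrame <- tapply(tr$frame, tr$track, min)
  lens <- tapply(tr$frame, tr$track, length)
  ids <- as.integer(names(lastFrame))
  movieEnd <- max(tr$frame)
  movieStart <- min(tr$frame)
  lastPos <- tr[order(tr$track, tr$frame), ]
  lastPos <- lastPos[!duplicated(lastPos$track, fromLast = TRUE), ]
  firstPos <- tr[order(tr$track, tr$frame), ]
  firstPos <- firstPos[!duplicated(firstPos$track), ]
  enders <- ids[lastFrame < movieEnd]
  births <- ids[firstFrame > movieStart & lens >= minDaughterLenFrames]
  used <- integer(0)
  events <- list()
  for (pid in enders[order(lastFrame[as.character(enders)])]) {
    fEnd <- lastFrame[[as.character(pid)]]
    pp <- lastPos[lastPos$track == pid, ]
    cand <- births[!(births %in% used)]
    cand <- cand[firstFrame[as.character(cand)] >= fEnd + 1L &
                   firstFrame[as.character(cand)] <= fEnd + 2L]
    if (length(cand) < 2L) next
    cp <- firstPos[match(cand, firstPos$track), ]
    dd <- sqrt((cp$row - pp$row)^2 + (cp$col - pp$col)^2)
    ok <- which(dd <= searchRadiusPx)
    if (length(ok) < 2L) next
    pick <- ok[order(dd[ok])][1:2]
    daughters <- sort(cand[pick])
    used <- c(used, daughters)
    events[[length(events) + 1L]] <- data.frame(
      parent = pid, frame = min(firstFrame[as.character(daughters)]),
      daughter1 = daughters[1], daughter2 = daughters[2])
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(parent = integer(), frame = integer(),
                  daughter1 = integer(), daughter2 = integer())
}

#' Divisions per starting cell and cumulative division curve
#'
#' Event counts are normalized by the starting nucleus count `n0` (fixed at
#' the first frame; cells leaving the field do not shrink the divisor). The
#' cumulative curve counts events up to each frame, normalized by `n0`; it
#' is non-decreasing and ends at `divisions_per_cell`.
#'
#' @param events data.frame from [detectDivisions()].
#' @param n0 starting nucleus count (>= 1).
#' @param frameIntervalH frame interval in hours.
#' @param nFrames total movie frames (for the curve's time axis).
#' @return list with `summary` (one-row data.frame: `n0`, `n_events`,
#'   `divisions_per_cell`) and `curve` (data.frame `t_h`,
#'   `cum_divisions_per_cell`).
#' @export
divisionsPerCell <- function(events, n0, frameIntervalH = 1, nFrames = NULL) {
  if (n0 < 1) stop("'n0' must be >= 1")
  if (is.null(nFrames))
    nFrames <- if (nrow(events)) max(events$frame) else 1L
  cum <- vapply(seq_len(nFrames), function(f) sum(events$frame <= f),
                numeric(1)) / n0
  list(summary = data.frame(n0 = n0, n_events = nrow(events),
                            divisions_per_cell = nrow(events) / n0),
       curve = data.frame(t_h = (seq_len(nFrames) - 1) * frameIntervalH,
                          cum_divisions_per_cell = cum))
}
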