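# Independent exhaustive oracle for the greedy maximal-circle packing, and
# random-mask fixture generators. The oracle shares only the declared
# conventions (feasible radius = distance to nearest obstacle pixel centre
# incl. a virtual border ring; continuous-geometry non-overlap; smallest
# (row, col) tie-break) and computes everything by direct enumeration --
# no distance transform, no incremental update.

# distance from every pixel centre to the nearest obstacle pixel centre,
# where obstacles are mask foreground plus a virtual ring just outside the
# image; computed by brute-force minimization over obstacle pixels
bruteObstacleDist <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  # border ring: nearest virtual obstacle pixel is at row 0 / nr+1, col 0 /
  # nc+1 directly in line with the pixel
  d <- pmin(rows, cols, nr + 1 - rows, nc + 1 - cols)
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg)) {
    for (i in seq_len(nrow(fg)))
      d <- pmin(d, sqrt((rows - fg[i, 1])^2 + (cols - fg[i, 2])^2))
  }
  d
}

# exhaustive greedy packing: at each step scan all pixel centres, apply all
# previously fitted circles explicitly, take the maximum feasible radius
# with the smallest (row, col) tie-break
oracleGapCircles <- function(mask, rMinPx) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  obst <- bruteObstacleDist(mask)
  circles <- data.frame(row = numeric(), col = numeric(),
                        radius_px = numeric())
  repeat {
    feas <- obst
    for (i in seq_len(nrow(circles)))
      feas <- pmin(feas, sqrt((rows - circles$row[i])^2 +
                                (cols - circles$col[i])^2) -
                     circles$radius_px[i])
    best <- max(feas)
    if (best < rMinPx) break
    cand <- which(feas == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    circles <- rbind(circles, data.frame(row = cand[1, 1], col = cand[1, 2],
                                         radius_px = best))
  }
  circles
}

# random binary mask fixtures: scattered pixels, discs and bars, mixed
randomMask <- function(seed, maxSide = 64L) {
  withr::with_seed(seed, {
    nr <- sample(16:maxSide, 1)
    nc <- sample(16:maxSide, 1)
    m <- matrix(stats::runif(nr * nc) < stats::runif(1, 0.02, 0.15), nr, nc)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (k in seq_len(sample(0:3, 1))) {   # a few discs
      cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
      rad <- stats::runif(1, 2, 6)
      m <- m | (sqrt((rows - cr)^2 + (cols - cc)^2) <= rad)
    }
    if (stats::runif(1) < 0.5) {           # a bar
      at <- sample(nr, 1)
      m[at, sample(nc, min(nc, 10))] <- TRUE
    }
    m
  })
}

# expected division-event count for the branching process with a division
# refractory period and a no-division tail window: age-structured
# deterministic recursion, exact for the expectation by linearity.
# age[a + 1] = expected cells whose age (frames since birth) is a, capped.
expectedDivisionEvents <- function(n0, ratePerH, frameIntervalH, durationH,
                                   refractoryH, tailGuardFrames) {
  nFrames <- floor(durationH / frameIntervalH) + 1
  p <- 1 - exp(-ratePerH * frameIntervalH)
  refrFrames <- ceiling(refractoryH / frameIntervalH)
  lastDivFrame <- nFrames - tailGuardFrames
  maxAge <- nFrames + refrFrames + 2   # ages 0 .. maxAge-1
  age <- numeric(maxAge)
  age[refrFrames + 2] <- n0            # starters are division-competent
  total <- 0
  for (f in 2:nFrames) {
    # everyone ages one frame (top class absorbs)
    age <- c(0, age[1:(maxAge - 1)] + c(rep(0, maxAge - 2), age[maxAge]))
    competent <- (refrFrames + 2):maxAge    # age > refrFrames
    if (f <= lastDivFrame) {
      ev <- p * sum(age[competent])
      total <- total + ev
      age[competent] <- age[competent] * (1 - p)   # parents leave
      age[1] <- age[1] + 2 * ev                    # two newborns, age 0
    }
  }
  total
}
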