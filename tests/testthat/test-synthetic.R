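test_that("every generator is a pure function of its truth and seed", {
  expect_identical(makeNetworkImage(networkTruth(sizePx = 96, seed = 5)),
                   makeNetworkImage(networkTruth(sizePx = 96, seed = 5)))
  expect_identical(makeNucleiImage(nucleiTruth(n = 10, sizePx = 96, seed = 5)),
                   makeNucleiImage(nucleiTruth(n = 10, sizePx = 96, seed = 5)))
  expect_identical(makeRecoilTrace(recoilTruth(seed = 5)),
                   makeRecoilTrace(recoilTruth(seed = 5)))
  expect_identical(makeBeadTrace(beadTruth(durationS = 20, seed = 5)),
                   makeBeadTrace(beadTruth(durationS = 20, seed = 5)))
  expect_identical(makeSwellingTrace(swellingTruth(seed = 5)),
                   makeSwellingTrace(swellingTruth(seed = 5)))
  expect_identical(
    makeDivisionMovie(divisionTruth(n0 = 20, durationH = 24, seed = 5)),
    makeDivisionMovie(divisionTruth(n0 = 20, durationH = 24, seed = 5)))
  # different seeds differ
  expect_false(identical(
    makeRecoilTrace(recoilTruth(seed = 5)),
    makeRecoilTrace(recoilTruth(seed = 6))))
})

test_that("network foreground is exactly the fiber-width dilation of the edges", {
  net <- makeNetworkImage(networkTruth(sizePx = 128, spacingPx = 24,
                                       fiberWidthPx = 3, seed = 2))
  half <- 1.5
  idx <- which(net$mask | TRUE, arr.ind = TRUE)
  samp <- idx[sample(nrow(idx), 400), ]
  for (i in seq_len(nrow(samp))) {
    r <- samp[i, 1]; c <- samp[i, 2]
    d <- min(vapply(seq_len(nrow(net$segments)), function(s)
      min(frcmech:::distToSegment(matrix(r), matrix(c),
                                  net$segments[s, 1:2],
                                  net$segments[s, 3:4])), numeric(1)))
    expect_equal(net$mask[r, c], d <= half)
  }
  # degenerate: lattice spacing beyond the image has no edges
  expect_error(makeNetworkImage(networkTruth(sizePx = 32, spacingPx = 64)),
               "spacing")
})

test_that("nuclei fields respect the minimum separation and SNR model", {
  nf <- makeNucleiImage(nucleiTruth(n = 20, sizePx = 200, radiusPx = 4,
                                    minSeparationPx = 16, seed = 3))
  expect_equal(nrow(nf$centroids), 20L)
  d <- as.matrix(stats::dist(nf$centroids))
  diag(d) <- Inf
  expect_gte(min(d), 16)
  # zero nuclei: noise-only image
  blank <- makeNucleiImage(nucleiTruth(n = 0, sizePx = 64, amplitude = 100,
                                       snr = 10, seed = 1))
  expect_equal(nrow(blank$centroids), 0L)
  expect_lt(max(abs(pixels(blank$image))), 100)   # no nucleus peaks
})

test_that("recoil traces follow the saturating-exponential closed form", {
  # noise-free: d at the first post-cut frame is A(1 - exp(-dt/tau))
  tr <- makeRecoilTrace(recoilTruth(amplitudeUm = 2, tauS = 4, noiseSdUm = 0,
                                    cutTimeS = 0, seed = 1))
  expect_equal(tr@displacementUm[tr@cutIndex], 2 * (1 - exp(-0.521 / 4)),
               tolerance = 1e-12)
  expect_equal(tr@displacementUm[tr@cutIndex], 0.2442, tolerance = 1e-3)
  # zero amplitude: identically zero
  z <- makeRecoilTrace(recoilTruth(amplitudeUm = 0, noiseSdUm = 0, seed = 1))
  expect_true(all(z@displacementUm == 0))
  # pre-cut frames are exactly zero
  expect_true(all(tr@displacementUm[seq_len(tr@cutIndex - 1)] == 0))
})

test_that("noisy recoil end displacement is unbiased around the plateau", {
  ends <- vapply(1:100, function(s) {
    tr <- makeRecoilTrace(recoilTruth(amplitudeUm = 2, tauS = 3,
                                      noiseSdUm = 0.05, seed = s))
    utils::tail(tr@displacementUm, 1)
  }, numeric(1))
  trueEnd <- 2 * (1 - exp(-(25 - 2 * 0.521 * 2) / 3))  # >= plateau - tiny
  se <- 0.05 / sqrt(100)
  expect_lt(abs(mean(ends) - 2 * (1 - exp(-(25 - 1.042) / 3))), 3 * se + 1e-3)
})

test_that("bead traces have equipartition variance and clean steps", {
  bt <- makeBeadTrace(beadTruth(kPnPerNm = 0.114, durationS = 900, seed = 1))
  expect_equal(stats::var(bt@positionNm),
               kBoltzmannPnNm * 310.15 / 0.114, tolerance = 0.1)
  # no step: means of the two halves agree within noise
  n <- length(bt@positionNm)
  expect_lt(abs(mean(bt@positionNm[1:(n / 2)]) -
                  mean(bt@positionNm[(n / 2 + 1):n])), 1.5)
  # short traces are rejected (calibration would be unreliable)
  expect_error(makeBeadTrace(beadTruth(durationS = 5)), "100 samples")
})

test_that("isotonic swelling traces stay at ratio one", {
  iso <- makeSwellingTrace(swellingTruth(plateauRatio = 1, noiseSdUm = 0.05,
                                         condition = "ISO", seed = 2))
  expect_true(all(abs(diameterRatio(iso) - 1) < 0.02))
  expect_equal(diameterRatio(iso)[1], 1)
})

test_that("division movies plant recoverable events at the expected rate", {
  # rate zero: no events
  quiet <- makeDivisionMovie(divisionTruth(n0 = 10, divisionRatePerH = 0,
                                           durationH = 24, seed = 1))
  expect_equal(nrow(quiet$events), 0L)
  # daughters appear adjacent to the parent's last position
  mv <- makeDivisionMovie(divisionTruth(n0 = 30, divisionRatePerH = 0.02,
                                        seed = 2))
  expect_gt(nrow(mv$events), 0L)
  for (i in seq_len(min(5, nrow(mv$events)))) {
    e <- mv$events[i, ]
    pp <- mv$detections[mv$detections$cell == e$parent &
                          mv$detections$frame == e$frame - 1, ]
    d1 <- mv$detections[mv$detections$cell == e$daughter1 &
                          mv$detections$frame == e$frame, ]
    d2 <- mv$detections[mv$detections$cell == e$daughter2 &
                          mv$detections$frame == e$frame, ]
    expect_equal(sqrt((d1$row - pp$row)^2 + (d1$col - pp$col)^2), 8,
                 tolerance = 1e-6)
    expect_equal(sqrt((d2$row - pp$row)^2 + (d2$col - pp$col)^2), 8,
                 tolerance = 1e-6)
    expect_gte(sqrt((d1$row - d2$row)^2 + (d1$col - d2$col)^2), 1)
    # parent disappears at the division frame
    expect_equal(nrow(mv$detections[mv$detections$cell == e$parent &
                                      mv$detections$frame >= e$frame, ]), 0L)
  }
})

test_that("planted event counts match the branching-process expectation", {
  # single-division regime (refractory longer than the movie) in a large
  # sparse field: the spatial clearance constraint cannot bind, so the
  # age-structured expectation is exact
  counts <- vapply(1:30, function(s)
    nrow(makeDivisionMovie(divisionTruth(n0 = 50, divisionRatePerH = 0.01,
                                         sizePx = 2000L, refractoryH = 100,
                                         seed = s))$events), numeric(1))
  expected <- expectedDivisionEvents(50, 0.01, 1, 72, 100, 3)
  se <- sqrt(expected / 30)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # multi-generation regime: clearance postpones sibling re-divisions, so
  # realized counts sit below the unconstrained branching expectation but
  # above the single-division floor
  multi <- vapply(1:10, function(s)
    nrow(makeDivisionMovie(divisionTruth(n0 = 50, divisionRatePerH = 0.01,
                                         sizePx = 2000L,
                                         seed = s))$events), numeric(1))
  upper <- expectedDivisionEvents(50, 0.01, 1, 72, 10, 3)
  expect_lt(mean(multi), upper + 3 * sqrt(upper / 10))
  expect_gt(mean(multi), expected - 3 * se)
})
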