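# fixture builders: a mask with a band of "network", fibers drawn in or out
# of it, channels painted along chosen fibers

bandMask <- function(dim = c(64, 64), rows = 20:44) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[rows, ] <- TRUE
  m
}

horizontalFiber <- function(row, cols = c(5, 60)) {
  RegionROI(rbind(c(row, cols[1]), c(row, cols[2])), closed = FALSE)
}

paintFiber <- function(channel, roi, value, widthPx = 3) {
  px <- fiberPixels(roi, dim(channel), widthPx)
  channel[px] <- channel[px] + value
  channel
}

test_that("network membership follows the in-mask fraction rule", {
  mask <- bandMask()
  expect_true(fiberInNetwork(horizontalFiber(30), mask))    # fully inside
  expect_false(fiberInNetwork(horizontalFiber(5), mask))    # fully outside
  # diagonal fiber ~60% inside passes the 50% default
  diag60 <- RegionROI(rbind(c(8, 5), c(38, 60)), closed = FALSE)
  inn <- fiberInNetwork(diag60, mask)
  expect_true(attr(inn, "fraction") > 0.5 && attr(inn, "fraction") < 0.9)
  expect_true(inn)
  # raising the required fraction flips the call
  expect_false(fiberInNetwork(diag60, mask,
                              minFraction = attr(inn, "fraction") + 0.05))
})

test_that("channel positivity is background-relative", {
  mask <- bandMask()
  rois <- list(horizontalFiber(25), horizontalFiber(35))
  set.seed(4)
  bgNoise <- matrix(rnorm(64 * 64, 50, 5), 64, 64)
  # zero-signal channel: nothing positive
  sc0 <- scoreFibers(rois, mask, pmlcChannel = bgNoise)
  expect_true(all(!sc0$pmlc_positive))
  # painting one fiber at +10 SD makes exactly that fiber positive
  painted <- paintFiber(bgNoise, rois[[1]], 50)
  sc1 <- scoreFibers(rois, mask, pmlcChannel = painted)
  expect_equal(sc1$pmlc_positive, c(TRUE, FALSE))
  # uniform rescaling leaves the calls unchanged
  sc2 <- scoreFibers(rois, mask, pmlcChannel = painted * 7)
  expect_equal(sc2$pmlc_positive, sc1$pmlc_positive)
})

test_that("matrix alignment needs both intensity and overlap", {
  mask <- bandMask()
  fiber <- horizontalFiber(30)
  set.seed(5)
  chan <- matrix(rnorm(64 * 64, 30, 3), 64, 64)
  # paint only the left 40% of the fiber's span: intensity call may pass but
  # the overlap criterion fails
  left <- RegionROI(rbind(c(30, 5), c(30, 27)), closed = FALSE)
  chanPart <- paintFiber(chan, left, 60)
  scPart <- scoreFibers(list(fiber), mask, matrixChannel = chanPart)
  expect_lt(scPart$matrix_overlap, 0.5)
  expect_false(scPart$matrix_aligned)
  # full-length painting passes both
  chanFull <- paintFiber(chan, fiber, 60)
  scFull <- scoreFibers(list(fiber), mask, matrixChannel = chanFull)
  expect_gt(scFull$matrix_overlap, 0.9)
  expect_true(scFull$matrix_aligned)
})

test_that("summary percentages are over in-network fibers only", {
  scores <- data.frame(fiber = 1:15,
                       in_network = c(rep(TRUE, 12), rep(FALSE, 3)),
                       network_fraction = 1,
                       pmlc_mean = 1,
                       pmlc_positive = c(rep(TRUE, 3), rep(FALSE, 9),
                                         rep(NA, 3)),
                       matrix_mean = NA, matrix_overlap = NA,
                       matrix_aligned = NA)
  s <- summarizeFibers(scores)
  expect_equal(s$n_fibers_in_network, 12L)
  expect_equal(s$pct_pmlc_positive, 25)    # 3 of 12
  # all or none positive
  scores$pmlc_positive[1:12] <- TRUE
  expect_equal(summarizeFibers(scores)$pct_pmlc_positive, 100)
  scores$pmlc_positive[1:12] <- FALSE
  expect_equal(summarizeFibers(scores)$pct_pmlc_positive, 0)
  expect_error(summarizeFibers(scores[scores$in_network == FALSE, ]),
               "no in-network")
})

test_that("a planted positive-fiber rate is recovered and ranks two arms", {
  runImage <- function(rate, seed) {
    withr::with_seed(seed, {
      mask <- matrix(TRUE, 96, 96)
      rois <- lapply(seq(6, 87, by = 9), function(r)   # 10 fibers
        RegionROI(rbind(c(r, 8), c(r, 88)), closed = FALSE))
      chan <- matrix(rnorm(96 * 96, 40, 4), 96, 96)
      pos <- sample(length(rois), round(rate * length(rois)))
      for (i in pos) chan <- paintFiber(chan, rois[[i]], 40)
      s <- summarizeFibers(scoreFibers(rois, mask, pmlcChannel = chan))
      c(called = s$pct_pmlc_positive,
        planted = 100 * length(pos) / length(rois))
    })
  }
  # the called percentage equals the planted percentage
  one <- runImage(0.4, 1)
  expect_equal(one[["called"]], one[["planted"]])
  expect_equal(one[["called"]], 40)
  # arm with half the positive rate ranks below, across images
  armA <- rowMeans(vapply(1:6, function(s) runImage(0.6, 100 + s),
                          numeric(2)))
  armB <- rowMeans(vapply(1:6, function(s) runImage(0.3, 200 + s),
                          numeric(2)))
  expect_gt(armA[["called"]], armB[["called"]])
  expect_equal(armA[["called"]], armA[["planted"]])
  expect_equal(armB[["called"]], armB[["planted"]])
})
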