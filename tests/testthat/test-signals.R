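test_that("neuropil correction follows F_ROI - F_np + <F_np> and keeps the mean", {
  expect_equal(correctNeuropil(c(10, 12), c(3, 3)), c(10, 12))
  expect_equal(correctNeuropil(c(5, 7, 9), c(5, 7, 9)), c(7, 7, 7))
  expect_equal(correctNeuropil(c(10, 20, 30), c(2, 4, 6)), c(12, 20, 28))
  set.seed(1)
  for (i in 1:20) {
    fRoi <- rnorm(200, 100, 5)
    fNp <- rnorm(200, 40, 3)
    expect_equal(mean(correctNeuropil(fRoi, fNp)), mean(fRoi))
  }
  expect_error(correctNeuropil(1:3, 1:4), "length mismatch")
  expect_error(correctNeuropil(c(1, NA), c(1, 2)), "non-finite")
})

test_that("rolling baseline equals the brute-force trailing-percentile oracle", {
  rate <- 1.03
  w <- as.integer(round(32 * rate))
  expect_equal(rollingBaseline(rep(5, 100), rate), rep(5, 100))
  set.seed(2)
  for (i in 1:10) {
    f <- rnorm(300, 100, 10)
    expect_equal(rollingBaseline(f, rate), oracleTrailingQuantile(f, w, 0.1))
  }
  # step trace: baseline reaches the new level only once the trailing window
  # is dominated by post-step samples (oracle decides exactly when)
  f <- c(rep(0, 103), rep(10, 103))
  expect_equal(rollingBaseline(f, rate), oracleTrailingQuantile(f, w, 0.1))
  # a single impulse sits above the 10th percentile: baseline unchanged
  f <- rep(2, 200); f[100] <- 50
  expect_equal(rollingBaseline(f, rate), rep(2, 200))
  expect_error(rollingBaseline(1:10, rate, windowS = 0), "positive")
})

test_that("standardization centers on the full-trace median and scales by quiet SD", {
  rate <- 1
  set.seed(3)
  dff <- rnorm(600, 0, 0.5)
  quiet <- rep(c(TRUE, FALSE), 300)
  z <- standardizeTrace(dff, quiet, rate)
  expect_equal(z, (dff - median(dff)) / sd(dff[quiet]))
  expect_equal(sd(z[quiet]), 1)
  expect_lt(abs(median(z)), 0.2)
  # location invariance
  expect_equal(standardizeTrace(dff + 3, quiet, rate), z)
  expect_error(standardizeTrace(rep(1, 100), rep(TRUE, 100), rate),
               "zero variance")
  expect_error(standardizeTrace(dff, rep(c(TRUE, rep(FALSE, 59)), 10), rate),
               "30 s")
})

test_that("event detection applies threshold, duration and peak criteria", {
  rate <- 1.03
  expect_equal(nrow(detectEvents(rep(0, 100), rep(0, 100), rate)), 0)
  # 2-s plateau above both criteria: exactly one event spanning it
  z <- rep(0, 60); dff <- rep(0, 60)
  z[20:22] <- 1.5; dff[20:22] <- 0.08
  ev <- detectEvents(z, dff, rate)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset_frame, ev$offset_frame), c(20, 22))
  expect_equal(ev$peak_dff, 0.08)
  # too short
  z2 <- rep(0, 60); dff2 <- rep(0, 60); z2[30] <- 2; dff2[30] <- 0.2
  expect_equal(nrow(detectEvents(z2, dff2, rate)), 0)
  # long enough but peak dFF too small
  z3 <- rep(0, 60); dff3 <- rep(0, 60); z3[30:33] <- 2; dff3[30:33] <- 0.03
  expect_equal(nrow(detectEvents(z3, dff3, rate)), 0)
})

test_that("event detection matches the run-enumeration oracle on random traces", {
  rate <- 1.03
  set.seed(4)
  for (i in 1:50) {
    z <- rnorm(400, 0, 1)
    dff <- abs(z) * 0.05
    ev <- detectEvents(z, dff, rate)
    orc <- oracleEvents(z, dff, rate)
    expect_equal(nrow(ev), nrow(orc))
    if (nrow(orc)) {
      expect_equal(ev$onset_frame, orc[, 1])
      expect_equal(ev$offset_frame, orc[, 2])
    }
  }
})

test_that("event occupancy is monotone in all three detection thresholds", {
  rate <- 1.03
  set.seed(5)
  z <- rnorm(2000, 0.3, 1)
  dff <- pmax(z, 0) * 0.06
  occ <- function(...) eventOccupancy(detectEvents(z, dff, rate, ...))
  for (grid in list(
    vapply(c(0.5, 1, 1.5, 2), function(v) occ(zThresh = v), numeric(1)),
    vapply(c(1, 2, 3), function(v) occ(minDurS = v), numeric(1)),
    vapply(c(0.01, 0.05, 0.1), function(v) occ(minPeakDff = v), numeric(1))))
    expect_true(all(diff(grid) <= 1e-12))
})
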