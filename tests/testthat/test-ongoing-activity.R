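mkTrain2 <- function(pairs, n) {
  ev <- if (length(pairs))
    data.frame(onset_frame = vapply(pairs, `[`, 1, 1),
               offset_frame = vapply(pairs, `[`, 1, 2),
               peak_dff = 0.1, peak_z = 2)
  else
    data.frame(onset_frame = integer(0), offset_frame = integer(0),
               peak_dff = numeric(0), peak_z = numeric(0))
  structure(ev, occupancy = 0, n_frames = n,
            class = c("EventTrain", "data.frame"))
}

test_that("binned ongoing rate is the event fraction of stillness frames", {
  rate <- 1
  n <- 300                                  # 5 one-minute bins at 1 Hz
  still <- rep(TRUE, n)
  b0 <- binOngoingRate(mkTrain2(list(), n), still, rate)
  expect_equal(b0$rate, rep(0, 5))
  bAll <- binOngoingRate(mkTrain2(list(c(1, n)), n), still, rate)
  expect_equal(bAll$rate, rep(1, 5))
  # 12 event-seconds inside a fully-still minute -> bin rate 0.2
  b <- binOngoingRate(mkTrain2(list(c(61, 72)), n), still, rate)
  expect_equal(b$rate[2], 0.2)
  expect_equal(b$rate[c(1, 3:5)], rep(0, 4))
  # low-coverage bins are missing
  still2 <- still
  still2[121:175] <- FALSE
  b2 <- binOngoingRate(mkTrain2(list(), n), still2, rate)
  expect_true(b2$missing[3])
  expect_true(is.na(b2$rate[3]))
})

test_that("classification follows the baseline +-kSD / run-length rule", {
  mkBins <- function(rates) {
    data.frame(bin = seq_along(rates), start_min = seq_along(rates) - 1,
               rate = rates, coverage = 1, missing = is.na(rates))
  }
  set.seed(12)
  base <- pmax(0, rnorm(30, 0.15, 0.02))
  pre <- mkBins(base)
  # statistically identical post -> none
  o <- classifyOngoingChange(pre, mkBins(pmax(0, rnorm(60, 0.15, 0.02))))
  expect_equal(o$classification, "none")
  # planted step up at +25 min for 25 min -> activated with that latency
  post <- pmax(0, rnorm(60, 0.15, 0.02))
  post[26:50] <- 0.5
  o2 <- classifyOngoingChange(pre, mkBins(post))
  expect_equal(o2$classification, "activated")
  expect_equal(o2$onset_latency_min, 25)
  expect_equal(o2$duration_min, 25)
  # planted drop to zero from the wave offset -> suppressed, latency 0
  post3 <- pmax(0, rnorm(60, 0.15, 0.02))
  post3[1:25] <- 0
  o3 <- classifyOngoingChange(pre, mkBins(post3))
  expect_equal(o3$classification, "suppressed")
  expect_equal(o3$onset_latency_min, 0)
  expect_equal(o3$duration_min, 25)
  # an 8-min elevated run is too short
  post4 <- pmax(0, rnorm(60, 0.15, 0.02))
  post4[5:12] <- 0.5
  expect_equal(classifyOngoingChange(pre, mkBins(post4))$classification, "none")
  # a change starting after the onset window does not count
  post5 <- pmax(0, rnorm(60, 0.15, 0.02))
  post5[40:58] <- 0.5
  expect_equal(classifyOngoingChange(pre, mkBins(post5))$classification, "none")
  # missing bins bridge a sustained run
  post6 <- pmax(0, rnorm(60, 0.15, 0.02))
  post6[10:30] <- 0.5
  post6[c(15, 16, 17, 21)] <- NA
  o6 <- classifyOngoingChange(pre, mkBins(post6))
  expect_equal(o6$classification, "activated")
  expect_equal(o6$duration_min, 21)
  expect_error(classifyOngoingChange(mkBins(base[1:5]), mkBins(post)),
               "baseline bins")
})

test_that("classification is invariant to appending event-free excluded frames", {
  rate <- 1
  n <- 3600
  still <- rep(TRUE, n)
  ev <- mkTrain2(lapply(seq(10, 3500, by = 60), function(s) c(s, s + 4)), n)
  pre <- binOngoingRate(ev, still, rate)
  # append 10 min of non-stillness frames with no events
  n2 <- n + 600
  still2 <- c(still, rep(FALSE, 600))
  ev2 <- ev
  attr(ev2, "n_frames") <- n2
  pre2 <- binOngoingRate(ev2, still2, rate)
  expect_equal(pre2$rate[1:60], pre$rate)
  post <- pre; post$rate[] <- 0; post$missing[] <- FALSE
  o1 <- classifyOngoingChange(pre, post, minBaselineBins = 15)
  o2 <- classifyOngoingChange(pre2[1:60, ], post, minBaselineBins = 15)
  expect_equal(o1$classification, o2$classification)
})
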