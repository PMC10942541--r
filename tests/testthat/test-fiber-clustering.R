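# helper to build an EventTrain from onset/offset pairs
mkTrain <- function(pairs, n) {
  ev <- if (length(pairs))
    data.frame(onset_frame = vapply(pairs, `[`, 1, 1),
               offset_frame = vapply(pairs, `[`, 1, 2),
               peak_dff = 0.1, peak_z = 2)
  else
    data.frame(onset_frame = integer(0), offset_frame = integer(0),
               peak_dff = numeric(0), peak_z = numeric(0))
  structure(ev, occupancy = sum(ev$offset_frame - ev$onset_frame + 1) / n,
            n_frames = n, class = c("EventTrain", "data.frame"))
}

test_that("event correlation separates identical from disjoint trains", {
  n <- 200
  quiet <- rep(TRUE, n)
  same <- mkTrain(list(c(10, 14), c(50, 55), c(120, 124)), n)
  disj <- mkTrain(list(c(30, 34), c(80, 85), c(160, 164)), n)
  g <- eventCorrelation(list(same, same, disj), quiet)
  expect_equal(g$corr[1, 2], 1)
  expect_equal(g$dissimilarity[1, 2], 0)
  expect_lte(g$corr[1, 3], 0)
  expect_false(g$adjacency[1, 3])
  expect_true(all(diag(g$corr) == 1))
  expect_equal(g$dissimilarity, t(g$dissimilarity))
  # ROI with no quiet events is flagged and zero-correlated
  empty <- mkTrain(list(), n)
  g2 <- eventCorrelation(list(same, empty), quiet)
  expect_equal(g2$flagged, 2L)
  expect_equal(g2$corr[1, 2], 0)
  expect_error(eventCorrelation(list(same), quiet), "2 ROIs")
})

test_that("planted-fiber cohorts correlate more within than between fibers", {
  gen <- cachedSession("plain")
  loco <- locomotionSeries(gen$session, seed = 1)
  sig <- roiSignals(gen$session, loco)
  g <- eventCorrelation(sig$events, sig$quiet)
  fib <- gen$truth$fiber_of_roi
  same <- outer(fib, fib, "==")
  ut <- upper.tri(g$corr)
  expect_gt(mean(g$corr[same & ut]), mean(g$corr[!same & ut]) + 0.3)
})

test_that("clustering recovers planted block structure and handles degenerate cases", {
  # noiseless block-diagonal adjacency of 3 fibers x 4 ROIs
  n <- 400
  quiet <- rep(TRUE, n)
  trains <- list()
  for (f in 0:2) for (r in 1:4)
    trains[[f * 4 + r]] <- mkTrain(lapply(0:4, function(k)
      c(20 + f * 120 + k * 20, 24 + f * 120 + k * 20)), n)
  g <- eventCorrelation(trains, quiet)
  fm <- clusterFibers(g)
  expect_equal(ari(as.integer(fm), rep(0:2, each = 4)), 1)
  # all-zero dissimilarity: one cluster
  g0 <- g
  g0$dissimilarity <- matrix(0, 12, 12)
  expect_equal(length(unique(clusterFibers(g0))), 1L)
  # single ROI: one singleton cluster
  g1 <- list(dissimilarity = matrix(0, 1, 1))
  expect_equal(as.integer(clusterFibers(g1)), 0L)
})

test_that("clustering is invariant to ROI ordering", {
  gen <- cachedSession("plain")
  loco <- locomotionSeries(gen$session, seed = 1)
  sig <- roiSignals(gen$session, loco)
  g <- eventCorrelation(sig$events, sig$quiet)
  fm <- clusterFibers(g)
  set.seed(10)
  perm <- sample(length(fm))
  gP <- eventCorrelation(sig$events[perm], sig$quiet)
  fmP <- clusterFibers(gP)
  expect_equal(ari(as.integer(fm)[perm], as.integer(fmP)), 1)
})

test_that("clustering recovers planted fibers at default noise", {
  gen <- cachedSession("plain")
  loco <- locomotionSeries(gen$session, seed = 1)
  sig <- roiSignals(gen$session, loco)
  g <- eventCorrelation(sig$events, sig$quiet)
  fm <- clusterFibers(g)
  expect_gte(ari(as.integer(fm), gen$truth$fiber_of_roi), 0.9)
})

test_that("fiber traces average member standardized traces", {
  z <- rbind(sin(1:50), sin(1:50), cos(1:50))
  expect_equal(fiberTrace(z, 1), z[1, ])
  expect_equal(fiberTrace(z, c(1, 2)), z[1, ])
  anti <- rbind(sin(1:200), -sin(1:200))
  flat <- fiberTrace(anti, c(1, 2))
  expect_lt(sd(flat), sd(anti[1, ]))
  expect_error(fiberTrace(z, integer(0)), "empty")
  expect_error(fiberTrace(z, 9), "out of range")
})
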