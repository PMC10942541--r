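test_that("wave-window detection finds analytic threshold crossings", {
  rate <- 1.03
  n <- 600
  trigger <- 200L
  t <- (seq_len(n) - 1) / rate
  t0 <- 230 / rate
  base <- 500
  amp <- 1.2
  # logistic rise, plateau, exponential return
  L <- 1 / (1 + exp(-(t - t0) / 1))
  dec <- exp(-pmax(0, t - t0 - 15) / 10)
  f <- base * (1 + amp * L * dec)
  expect_error(detectWaveWindow(rep(base, n), trigger, rate), "no wave")
  win <- detectWaveWindow(f, trigger, rate)
  # closed-form crossings of 0.1 * peak (F_pre = base exactly: flat history)
  dffTrue <- (f - base) / base
  thr <- win$threshold
  pk <- which.max(dffTrue)
  onsetTrue <- max(which(dffTrue[1:pk] <= thr)) + 1L
  offTrue <- pk + min(which(dffTrue[pk:n] <= thr)) - 2L
  expect_equal(win$onset_frame, onsetTrue)
  expect_equal(win$offset_frame, offTrue)
  # amplitude scale invariance (relative threshold)
  win10 <- detectWaveWindow(base + (f - base) * 10, trigger, rate)
  expect_equal(win10$onset_frame, win$onset_frame)
  expect_equal(win10$offset_frame, win$offset_frame)
})

test_that("per-bin logistic fits recover noiseless onsets within one frame", {
  gen <- cachedSession("wave")
  s <- gen$session
  win <- detectWaveWindow(fovTrace(s), csdTriggerFrame(s), frameRate(s))
  fits <- fitBinOnsets(s, win)
  truth <- gen$truth$wave$bin_onset_s
  inc <- fits$included
  expect_gt(mean(inc), 0.9)
  errs <- abs(fits$t_onset[inc] -
                truth[cbind(fits$row[inc], fits$col[inc])])
  expect_lt(max(errs), 1 / frameRate(s))
  # tau exclusion rule is applied exactly on the fitted values
  expect_true(all(fits$tau[inc] >= 0 & fits$tau[inc] <= 2))
  expect_true(all(fits$r2[inc] >= 0.5))
})

test_that("bins flagged by the ROI-exclusion mask are skipped", {
  gen <- cachedSession("wave")
  s <- gen$session
  win <- detectWaveWindow(fovTrace(s), csdTriggerFrame(s), frameRate(s))
  d <- dim(backgroundGrid(s))
  mask <- matrix(FALSE, d[1], d[2])
  mask[1:2, ] <- TRUE
  fits <- fitBinOnsets(s, win, roiExclusionMask = mask)
  expect_true(all(!fits$included[fits$row <= 2]))
  expect_true(all(is.na(fits$t_onset[fits$row <= 2])))
})

test_that("speed and direction are recovered and rotate with the planted wave", {
  gen <- cachedSession("wave")
  s <- gen$session
  win <- detectWaveWindow(fovTrace(s), csdTriggerFrame(s), frameRate(s))
  est <- estimateSpeedDirection(fitBinOnsets(s, win))
  expect_equal(est$speed_mm_per_min, 3.8, tolerance = 0.02)
  expect_lt(abs(est$direction_deg - 90), 2)
  # rotated wave: direction rotates, speed unchanged
  cfg <- simConfig(seed = 78L, durationPreMin = 6, durationPostMin = 8,
                   nFibers = 2L, fracDeformCoupled = 0, fracLocoCoupled = 0,
                   fracUnmasked = 0, fracLost = 0, activatedFraction = 0,
                   suppressedFraction = 0, waveDirectionDeg = 0)
  gen2 <- generateSession(cfg)
  win2 <- detectWaveWindow(fovTrace(gen2$session),
                           csdTriggerFrame(gen2$session),
                           frameRate(gen2$session))
  est2 <- estimateSpeedDirection(fitBinOnsets(gen2$session, win2))
  expect_equal(est2$speed_mm_per_min, 3.8, tolerance = 0.02)
  expect_lt(min(abs(est2$direction_deg - c(0, 360))), 2)
  # simultaneous onsets: no propagation
  flat <- fitBinOnsets(s, win)
  flat$t_onset[] <- 100
  flat$included[] <- TRUE
  expect_error(estimateSpeedDirection(flat), "no propagation")
})

test_that("fiber activation pace matches planted sequential onsets", {
  gen <- cachedSession("wave")
  s <- gen$session
  tr <- gen$truth
  win <- detectWaveWindow(fovTrace(s), csdTriggerFrame(s), frameRate(s))
  spans <- tapply(tr$roi_arc_dist_um, tr$fiber_of_roi, function(x) diff(range(x)))
  f <- as.integer(names(which(spans > 200)))[1]
  idx <- which(tr$fiber_of_roi == f)
  o <- order(tr$roi_arc_dist_um[idx])
  idx <- idx[o]
  traces <- roiTraces(s)[idx, , drop = FALSE]
  arc <- tr$roi_arc_dist_um[idx]
  p <- fiberActivationPace(traces, arc, win, frameRate(s))
  # planted pace along the fiber from true ROI onsets
  truePace <- unname(coef(lm(tr$wave$roi_onset_s[idx] ~ arc))[2]) * 1000
  expect_equal(p$pace_s_per_mm, truePace, tolerance = 0.05 * max(1, abs(truePace)))
  # reversed order: pace flips sign, magnitude preserved
  pRev <- fiberActivationPace(traces[rev(seq_len(nrow(traces))), ],
                              max(arc) - rev(arc), win, frameRate(s))
  expect_equal(pRev$pace_s_per_mm, -p$pace_s_per_mm, tolerance = 0.05)
  # simultaneous activation (locomotion-like): pace ~ 0
  n <- ncol(traces)
  tS <- (seq_len(n) - 1) / frameRate(s)
  onset0 <- (win$onset_frame - 1) / frameRate(s)
  sim <- matrix(rep(1000 * (1 + 1 / (1 + exp(-(tS - onset0) / 1))), 3),
                nrow = 3, byrow = TRUE)
  pSim <- fiberActivationPace(sim, c(0, 150, 300), win, frameRate(s))
  expect_lt(abs(pSim$pace_s_per_mm), 0.5)
  expect_error(fiberActivationPace(sim, c(0, 50, 100), win, frameRate(s)),
               "span")
})
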