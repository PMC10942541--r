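test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- simConfig(seed = 5L, durationPreMin = 6, durationPostMin = 6,
                   nFibers = 3L, activatedFraction = 0, suppressedFraction = 0)
  g1 <- generateSession(cfg)
  g2 <- generateSession(cfg)
  expect_identical(roiTraces(g1$session), roiTraces(g2$session))
  expect_identical(backgroundGrid(g1$session), backgroundGrid(g2$session))
  expect_identical(wheelPosition(g1$session), wheelPosition(g2$session))
  expect_identical(g1$truth$fibers, g2$truth$fibers)
})

test_that("config validation rejects infeasible settings", {
  expect_error(simConfig(activatedFraction = 1.2), "fractions")
  expect_error(simConfig(activatedFraction = 0.6, suppressedFraction = 0.6),
               "exceed 1")
  expect_error(simConfig(waveSpeedMmPerMin = -1), "positive")
  expect_error(simConfig(roisPerFiber = c(4L, 2L)), "roisPerFiber")
  # wave must cross the FOV within the post window
  expect_error(generateSession(simConfig(seed = 1, durationPostMin = 0.5,
                                         durationPreMin = 5)),
               "infeasible")
})

test_that("zero planted fractions give all-none ground-truth classes", {
  gen <- cachedSession("plain")
  expect_true(all(gen$truth$fibers$ongoing_class == "none"))
  expect_true(all(gen$truth$glm_truth_pre == 0))
})

test_that("planted wave onsets lie exactly on the plane distance / speed", {
  gen <- cachedSession("wave")
  w <- gen$truth$wave
  centers <- binCenters(gen$session)
  u <- c(cos(w$direction_deg * pi / 180), sin(w$direction_deg * pi / 180))
  proj <- as.matrix(centers[, c("x_um", "y_um")]) %*% u
  onset <- w$bin_onset_s[cbind(centers$row, centers$col)]
  fitl <- lm(onset ~ proj)
  speedUmS <- 1 / coef(fitl)[2]
  expect_equal(unname(speedUmS) * 60 / 1000, w$speed_mm_per_min,
               tolerance = 1e-9)
  expect_equal(max(abs(resid(fitl))), 0, tolerance = 1e-9)
})

test_that("stillness event occupancy matches the planted 6.9% condition", {
  gen <- cachedSession("plain")                 # all fibers at baseline class
  loco <- locomotionSeries(gen$session, seed = 1)
  sig <- roiSignals(gen$session, loco)
  occ <- vapply(seq_len(nRois(gen$session)), function(i)
    mean(eventIndicator(sig$events[[i]], nFrames(gen$session))[sig$quiet]),
    numeric(1))
  # CI from the Poisson event-count variance (frames within an event are
  # dependent, so a per-frame binomial CI would be far too tight): per fiber
  # SE ~ sqrt(lambda T) * dur / T; averaging over nFibers independent fibers
  cfg <- gen$truth$config
  quietS <- sum(sig$quiet) / frameRate(gen$session)
  lam <- 0.069 / 2.5                            # approximate rate, dur ~2.5 s
  sePerFiber <- sqrt(lam * quietS) * 2.5 / quietS
  se <- sePerFiber / sqrt(cfg$nFibers)
  expect_lt(abs(mean(occ) - 0.069), 3 * se + 0.01)
})

test_that("planted bout statistics match the configured distributions", {
  gen <- cachedSession("plain")
  bouts <- gen$truth$locomotion$bouts
  cfg <- gen$truth$config
  # dwell times are geometric (memoryless) with mean meanBoutDurS; past the
  # 2-s threshold the excess duration is again geometric, compared via KS
  # against the exponential approximation at a generous alpha
  ks <- suppressWarnings(ks.test(bouts$duration_s - 2, "pexp",
                                 1 / cfg$meanBoutDurS))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(bouts$duration_s >= 2))
  rate <- nrow(bouts) / (nFrames(gen$session) / frameRate(gen$session) / 60)
  expect_lt(abs(rate - cfg$boutRatePerMin), 0.25)
})

test_that("the fixture suite is written, re-readable and seeded", {
  d <- withr::local_tempdir()
  paths <- makeFixtureSuite(d)
  expect_gte(length(paths), 4)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.exists(file.path(d, paste0(names(paths), "_truth.json")))))
  s <- readSession(paths[["pure_noise"]])
  expect_true(is.na(csdTriggerFrame(s)))
  tr <- jsonlite::read_json(file.path(d, "pure_noise_truth.json"),
                            simplifyVector = TRUE)
  expect_true(all(unlist(tr$glm_truth_pre) == 0))
  # regenerating a fixture config reproduces the identical session
  g2 <- generateSession(fixtureConfigs()$pure_noise)
  expect_identical(roiTraces(g2$session), roiTraces(readSession(paths[["pure_noise"]])))
})
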