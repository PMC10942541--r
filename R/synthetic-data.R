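# Synthetic recording sessions with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# GCaMP6s-like transients on Poisson event trains, ROIs grouped into fibers
# sharing a latent trace, locomotion bouts with coupled deformation series,
# a planar CSD calcium wave, and post-CSD changes (delayed activation,
# immediate suppression, deformation-coefficient gain, unmasking).

#' Simulation configuration
#'
#' Builds a validated configuration for [generateSession()]. Defaults encode
#' the study conditions: 60 min baseline + 120 min post-CSD at 1.03
#' volumes/s, 15.5 Hz wheel sampling, 626 x 423 um FOV, a 3.8 mm/min
#' anterior-to-posterior calcium wave, baseline fluorescence events
#' occupying 6.9% of stillness time, ~10% of afferents with delayed (25 min)
#' prolonged activation and ~20% with immediate suppression, locomotion bout
#' rate reduced to 60% post-CSD, and a x2 post-CSD gain on deformation
#' coefficients in sensitized afferents.
#'
#' @param seed Integer seed fixing all randomness.
#' @param durationPreMin,durationPostMin Baseline and post-CSD durations.
#' @param frameRateHz,wheelRateHz,fovSizeUm,pixelSizeUm,binSizePx Acquisition
#'   constants.
#' @param nFibers Number of afferent fibers.
#' @param roisPerFiber Integer range (min, max) of ROIs per fiber.
#' @param targetOccupancy Baseline stillness event occupancy (default 0.069).
#' @param eventAmpDff Typical event amplitude in dFF units (default 0.2,
#'   lognormal jitter `eventAmpSdLog`).
#' @param eventAmpSdLog Lognormal sigma of event amplitudes (default 0.3).
#' @param gcampRiseS,gcampDecayS GCaMP6s kernel time constants (s).
#' @param quietDffSd Quiet-wakefulness dFF noise SD (default 0.02).
#' @param roiNoiseSd,fiberNoiseSd Independent per-ROI and shared per-fiber
#'   noise SDs, in units of `quietDffSd`.
#' @param boutRatePerMin,meanBoutDurS Locomotion bout statistics.
#' @param runSpeedMean,runSpeedSd Within-bout speed distribution (cm/s).
#' @param velSmoothS Velocity smoothing window (s).
#' @param stillSpeedSd Stillness speed jitter (cm/s).
#' @param deformGain Gains (scale um, shear, zshift um per cm/s of filtered
#'   velocity).
#' @param deformNoiseSd Additive noise SDs for (scale, shear, zshift).
#' @param deformFilterTauS Causal velocity-filter time constant (s).
#' @param couplingBeta Planted coupling coefficient (z units per predictor
#'   SD).
#' @param couplingDelayFrames Delay (frames) of the planted coupling.
#' @param fracDeformCoupled,fracLocoCoupled Fractions of fibers coupled to
#'   deformation / locomotion state at baseline.
#' @param fracSensitized Fraction of deformation-coupled fibers whose
#'   deformation coefficients gain `sensitizedGain` post-CSD (default 0.6,
#'   placing about half of the fibers that are well fit in both epochs in
#'   the sensitized class).
#' @param sensitizedGain Post-CSD multiplicative coefficient gain (default 2).
#' @param fracUnmasked Fraction of fibers silent at baseline that become
#'   deformation-coupled post-CSD.
#' @param fracLost Fraction of fibers coupled at baseline that lose coupling
#'   post-CSD.
#' @param includeCsd Logical; FALSE produces a no-CSD session.
#' @param waveSpeedMmPerMin,waveDirectionDeg Planar wave speed and image-
#'   coordinate bearing (90 deg = anterior to posterior).
#' @param waveAmplitudeDff,waveTauS,wavePlateauS,waveReturnTauS Wave shape:
#'   logistic rise (amplitude, tau), plateau, exponential return.
#' @param waveLagS Lag between trigger and wave entry into the FOV (s).
#' @param waveNoiseFrac Background-grid noise SD as a fraction of the wave
#'   amplitude.
#' @param activatedFraction,suppressedFraction Fractions of fibers with
#'   prolonged post-CSD activation / suppression.
#' @param activationDelayMin,effectDurationMin Onset latency and duration of
#'   the planted ongoing-activity changes (min).
#' @param activatedOccupancy Occupancy during planted activation.
#' @param suppressedBaselineOccupancy Baseline occupancy of fibers destined
#'   for suppression (suppression is only observable against an elevated
#'   baseline; see the methods vignette).
#' @param suppressedEventAmpDff,suppressedEventAmpSdLog Event amplitude and
#'   lognormal spread of those fibers; sustaining an elevated occupancy
#'   against the quiet-epoch SD inflation requires large transients of
#'   near-uniform amplitude (see the methods vignette).
#' @param suppressedRegularity Gamma shape of those fibers' inter-event
#'   intervals (quasi-rhythmic tonic firing; higher = more regular). A
#'   suppression is only detectable under the baseline-SD rule when the
#'   baseline bin-to-bin variance is low.
#' @param postQuietMin Locomotion-free period right after the trigger (min).
#' @param postBoutRateFactor Post-CSD bout-rate multiplier (default 0.6).
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      durationPreMin = 60, durationPostMin = 120,
                      frameRateHz = 1.03, wheelRateHz = 15.5,
                      fovSizeUm = c(626, 423), pixelSizeUm = 626 / 512,
                      binSizePx = 40L,
                      nFibers = 12L, roisPerFiber = c(3L, 8L),
                      targetOccupancy = 0.069,
                      eventAmpDff = 0.2, eventAmpSdLog = 0.3,
                      gcampRiseS = 0.2, gcampDecayS = 1.5,
                      quietDffSd = 0.02, roiNoiseSd = 1, fiberNoiseSd = 0.35,
                      boutRatePerMin = 0.4, meanBoutDurS = 10,
                      runSpeedMean = 8, runSpeedSd = 2,
                      velSmoothS = 1, stillSpeedSd = 0.05,
                      deformGain = c(scale = 0.6, shear = 8e-4, zshift = 0.5),
                      deformNoiseSd = c(scale = 1.0, shear = 1.3e-3,
                                        zshift = 0.8),
                      deformFilterTauS = 0.5,
                      couplingBeta = 1.0, couplingDelayFrames = 0L,
                      fracDeformCoupled = 0.25, fracLocoCoupled = 0.10,
                      fracSensitized = 0.6, sensitizedGain = 2,
                      fracUnmasked = 0.10, fracLost = 0.05,
                      includeCsd = TRUE,
                      waveSpeedMmPerMin = 3.8, waveDirectionDeg = 90,
                      waveAmplitudeDff = 1.5, waveTauS = 1,
                      wavePlateauS = 15, waveReturnTauS = 10,
                      waveLagS = 2, waveNoiseFrac = 0,
                      activatedFraction = 0.10, suppressedFraction = 0.20,
                      activationDelayMin = 25, effectDurationMin = 25,
                      activatedOccupancy = 0.5,
                      suppressedBaselineOccupancy = 0.2,
                      suppressedEventAmpDff = 0.8,
                      suppressedEventAmpSdLog = 0.05,
                      suppressedRegularity = 8,
                      postQuietMin = 3, postBoutRateFactor = 0.6) {
  cfg <- as.list(environment())
  fracs <- c(cfg$fracDeformCoupled, cfg$fracLocoCoupled, cfg$fracSensitized,
             cfg$fracUnmasked, cfg$fracLost, cfg$activatedFraction,
             cfg$suppressedFraction, cfg$waveNoiseFrac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$activatedFraction + cfg$suppressedFraction > 1)
    stop("activated + suppressed fractions exceed 1", call. = FALSE)
  pos <- c(cfg$durationPreMin, cfg$frameRateHz, cfg$wheelRateHz,
           cfg$pixelSizeUm, cfg$gcampRiseS, cfg$gcampDecayS, cfg$quietDffSd,
           cfg$waveSpeedMmPerMin, cfg$waveTauS, cfg$waveReturnTauS,
           cfg$targetOccupancy)
  if (any(pos <= 0)) stop("rates, durations and speeds must be positive", call. = FALSE)
  if (cfg$roisPerFiber[1] < 1 || cfg$roisPerFiber[2] < cfg$roisPerFiber[1])
    stop("invalid roisPerFiber range", call. = FALSE)
  structure(cfg, class = "SimConfig")
}

# GCaMP kernel sampled at dt, peak-normalized.
#' @noRd
.gcampKernel <- function(riseS, decayS, dt, lenS = 20) {
  t <- seq(0, lenS, by = dt)
  k <- exp(-t / decayS) - exp(-t / riseS)
  k / max(k)
}

# Event-rate calibration: find the Poisson rate whose detected-event
# occupancy equals `target`. The standardization SD is inflated above the
# unit noise by the events themselves (Campbell's theorem: var = rate *
# E[amp^2] * integral of the squared kernel) and by any planted coupling
# drive (`extraVar`), which raises the effective detection threshold; the
# inflation is an explicit function of the rate, so the occupancy-rate curve
# is evaluated on a grid and inverted. When `sdFixed` is given (events added
# to an epoch that does not feed the standardization, e.g. post-CSD
# activation standardized by baseline statistics) the SD is held at that
# value instead.
#' @noRd
.calibrateEventRate <- function(target, cfg, extraVar = 0, sdFixed = NULL,
                                ampDff = cfg$eventAmpDff,
                                ampSdLog = cfg$eventAmpSdLog) {
  fr <- cfg$frameRateHz
  dtFine <- 0.01
  kFine <- .gcampKernel(cfg$gcampRiseS, cfg$gcampDecayS, dtFine)
  tFine <- seq(0, 20, by = dtFine)
  k2int <- sum(kFine^2) * dtFine
  ampZ0 <- ampDff / cfg$quietDffSd
  qs <- qlnorm(seq(0.02, 0.98, length.out = 25),
               meanlog = log(ampZ0), sdlog = ampSdLog)
  eA2 <- mean(qs^2)
  phases <- seq(0, 1 - 1e-9, length.out = 8) / fr
  noiseSd <- sqrt(cfg$roiNoiseSd^2 + cfg$fiberNoiseSd^2)
  # Expected detected frames per event at standardization SD s, accounting
  # for frame noise: with independent frame noise a frame lies inside a
  # detected (>= 2-frame) run iff it is suprathreshold and at least one
  # neighbor is, so E[frames] = sum p_t (1 - (1-p_{t-1})(1-p_{t+1})).
  eFrames <- function(s) {
    mean(outer(qs, phases, function(a, ph) {
      vapply(seq_along(a), function(i) {
        if (a[i] * cfg$quietDffSd < 0.05) return(0)
        tt <- seq(ph[i], 20, by = 1 / fr)
        kk <- approx(tFine, kFine, tt, rule = 2)$y
        p <- pnorm((a[i] * kk - s) / noiseSd)
        pl <- c(pnorm(-s / noiseSd), p[-length(p)])
        pr <- c(p[-1], pnorm(-s / noiseSd))
        sum(p * (1 - (1 - pl) * (1 - pr)))
      }, numeric(1))
    }))
  }
  sOf <- function(lam) {
    if (!is.null(sdFixed)) sdFixed
    else sqrt(noiseSd^2 + extraVar + lam * eA2 * k2int)
  }
  # Boolean-coverage occupancy of overlapping events
  occOf <- function(lam) 1 - exp(-lam * eFrames(sOf(lam)) / fr)
  lams <- exp(seq(log(5e-4), log(2), length.out = 60))
  occs <- vapply(lams, occOf, numeric(1))
  if (max(occs) < target)
    stop(sprintf(
      "occupancy %.2f unattainable: amplitude too small relative to the SD inflation (max %.2f)",
      target, max(occs)), call. = FALSE)
  i <- which(occs >= target)[1]
  lam <- if (i == 1) lams[1] else
    approx(occs[(i - 1):i], lams[(i - 1):i], xout = target)$y
  list(rate_hz = lam, sd_inflation = sOf(lam),
       expected_dur_s = eFrames(sOf(lam)) / fr)
}

#' Generate a synthetic recording session with ground truth
#'
#' Deterministic given the configuration seed. See [simConfig()] for the
#' generative model.
#'
#' @param config A `SimConfig` from [simConfig()].
#' @return List with `session` (a [RecordingSession-class]) and `truth`
#'   (a `GroundTruth` list: fiber assignments, per-fiber coupling
#'   coefficients pre/post, ongoing-activity classes with onset/duration,
#'   wave speed/direction/per-bin onsets, locomotion state and bout table,
#'   deformation series, and the configuration).
#' @export
generateSession <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))
  fr <- cfg$frameRateHz
  nPre <- .frames(cfg$durationPreMin * 60, fr)
  nPost <- if (cfg$includeCsd) .frames(cfg$durationPostMin * 60, fr) else 0L
  n <- nPre + nPost
  trigger <- if (cfg$includeCsd) nPre + 1L else NA_integer_
  tS <- (seq_len(n) - 1) / fr

  # ---- locomotion state, velocity, wheel ---------------------------------
  pEnter <- cfg$boutRatePerMin / 60 / fr
  pExit <- 1 / (cfg$meanBoutDurS * fr)
  state <- logical(n)
  quietUntil <- if (cfg$includeCsd) trigger + .frames(cfg$postQuietMin * 60, fr) else 0L
  for (i in 2:n) {
    pe <- pEnter * if (cfg$includeCsd && i > trigger) cfg$postBoutRateFactor else 1
    if (cfg$includeCsd && i >= trigger && i <= quietUntil) {
      state[i] <- FALSE
    } else if (state[i - 1]) {
      state[i] <- runif(1) > pExit
    } else {
      state[i] <- runif(1) < pe
    }
  }
  target <- ifelse(state, pmax(0.5, rnorm(n, cfg$runSpeedMean, cfg$runSpeedSd)),
                   0) + rnorm(n, 0, cfg$stillSpeedSd)
  velocity <- .movingAverage(target, .frames(cfg$velSmoothS, fr))
  nWheel <- as.integer(round(n / fr * cfg$wheelRateHz))
  tWheel <- (seq_len(nWheel)) / cfg$wheelRateHz
  vWheel <- approx(tS + 0.5 / fr, velocity, xout = tWheel, rule = 2)$y
  wheelPos <- cumsum(vWheel) / cfg$wheelRateHz

  # ---- deformation series and affines ------------------------------------
  filt <- .expFilter(velocity, cfg$deformFilterTauS, fr)
  defScale <- cfg$deformGain[["scale"]] * filt +
    rnorm(n, 0, cfg$deformNoiseSd[["scale"]])
  # shear is an anisotropy magnitude (singular-value split), hence >= 0
  defShear <- abs(cfg$deformGain[["shear"]] * filt +
                    rnorm(n, 0, cfg$deformNoiseSd[["shear"]]))
  defZ <- cfg$deformGain[["zshift"]] * filt +
    rnorm(n, 0, cfg$deformNoiseSd[["zshift"]])
  rRef <- sqrt(sum((cfg$fovSizeUm / 2)^2))
  m <- defScale / rRef
  h <- defShear
  s1 <- h + sqrt(h^2 + (1 + m)^2)
  s2 <- s1 - 2 * h
  affLin <- array(0, dim = c(2, 2, n))
  th1 <- runif(n, -0.05, 0.05)
  th2 <- runif(n, -0.05, 0.05)
  for (i in seq_len(n)) {
    R1 <- matrix(c(cos(th1[i]), sin(th1[i]), -sin(th1[i]), cos(th1[i])), 2)
    R2 <- matrix(c(cos(th2[i]), sin(th2[i]), -sin(th2[i]), cos(th2[i])), 2)
    affLin[, , i] <- R1 %*% diag(c(s1[i], s2[i])) %*% R2
  }
  affTr <- matrix(rnorm(2 * n, 0, 0.5), 2, n)

  # ---- fiber geometry -----------------------------------------------------
  nFib <- cfg$nFibers
  nroiFib <- sample(seq(cfg$roisPerFiber[1], cfg$roisPerFiber[2]), nFib,
                    replace = TRUE)
  nRoi <- sum(nroiFib)
  fiberOf <- rep(seq_len(nFib) - 1L, nroiFib)
  cent <- matrix(NA_real_, nRoi, 2)
  arcDist <- numeric(nRoi)
  idx0 <- cumsum(c(0, nroiFib))
  for (f in seq_len(nFib)) {
    len <- runif(1, 250, 400)
    ang <- runif(1, 0, 2 * pi)
    c0 <- c(runif(1, 0.2, 0.8) * cfg$fovSizeUm[1],
            runif(1, 0.2, 0.8) * cfg$fovSizeUm[2])
    dists <- sort(runif(nroiFib[f], 0, len))
    dists <- dists - mean(dists)
    for (j in seq_len(nroiFib[f])) {
      p <- c0 + dists[j] * c(cos(ang), sin(ang))
      p <- pmin(pmax(p, 5), cfg$fovSizeUm - 5)
      cent[idx0[f] + j, ] <- p
      arcDist[idx0[f] + j] <- dists[j] - dists[1]
    }
  }

  # ---- fiber roles ---------------------------------------------------------
  fams <- .FAMILIES
  takeN <- function(frac) round(frac * nFib)
  perm <- sample(nFib)
  nDef <- takeN(cfg$fracDeformCoupled)
  nLoc <- takeN(cfg$fracLocoCoupled)
  role <- rep("none", nFib)
  role[perm[seq_len(nDef)]] <- "deformation"
  if (nLoc > 0) role[perm[nDef + seq_len(nLoc)]] <- "locomotion"
  coupledIdx <- perm[seq_len(nDef + nLoc)]
  freeIdx <- setdiff(seq_len(nFib), coupledIdx)
  pickFrom <- function(pool, k) {        # sample() safe for length-1 pools
    k <- min(k, length(pool))
    if (k <= 0) integer(0) else pool[sample.int(length(pool), k)]
  }
  sensIdx <- if (nDef > 0) perm[seq_len(max(0, round(cfg$fracSensitized * nDef)))] else integer(0)
  lostIdx <- pickFrom(setdiff(coupledIdx, sensIdx), takeN(cfg$fracLost))
  unmaskedIdx <- pickFrom(freeIdx, takeN(cfg$fracUnmasked))

  betaPre <- matrix(0, nFib, length(fams), dimnames = list(NULL, fams))
  for (f in seq_len(nFib)) {
    if (role[f] == "deformation")
      betaPre[f, c("scale", "shear", "zshift")] <- cfg$couplingBeta
    if (role[f] == "locomotion")
      betaPre[f, "locomotion_state"] <- cfg$couplingBeta
  }
  betaPost <- betaPre
  if (cfg$includeCsd) {
    for (f in sensIdx)
      betaPost[f, c("scale", "shear", "zshift")] <-
        betaPre[f, c("scale", "shear", "zshift")] * cfg$sensitizedGain
    betaPost[lostIdx, ] <- 0
    for (f in unmaskedIdx)
      betaPost[f, c("scale", "shear", "zshift")] <- cfg$couplingBeta
  }

  # ---- ongoing-activity classes -------------------------------------------
  ongoing <- rep("none", nFib)
  if (cfg$includeCsd) {
    nAct <- takeN(cfg$activatedFraction)
    nSup <- takeN(cfg$suppressedFraction)
    pool <- sample(nFib)
    ongoing[pool[seq_len(nAct)]] <- "activated"
    if (nSup > 0) ongoing[pool[nAct + seq_len(nSup)]] <- "suppressed"
  }

  # ---- predictors standardized over the baseline epoch --------------------
  preRows <- seq_len(if (cfg$includeCsd) nPre else n)
  stdPre <- function(x) {
    s0 <- sd(x[preRows])
    if (!is.finite(s0) || s0 == 0) return(numeric(length(x)))
    (x - mean(x[preRows])) / s0
  }
  xStd <- cbind(locomotion_state = stdPre(as.numeric(state)),
                velocity = stdPre(velocity),
                scale = stdPre(defScale), shear = stdPre(defShear),
                zshift = stdPre(defZ))
  dly <- cfg$couplingDelayFrames
  lagged <- function(x, d) if (d == 0) x else c(rep(x[1], d), x[seq_len(n - d)])
  xLag <- apply(xStd, 2, lagged, d = dly)

  # ---- wave geometry -------------------------------------------------------
  fovPx <- cfg$fovSizeUm / cfg$pixelSizeUm
  nbx <- max(1L, floor(fovPx[1] / cfg$binSizePx))
  nby <- max(1L, floor(fovPx[2] / cfg$binSizePx))
  waveTruth <- NULL
  waveDffAt <- function(onsetS) {
    w <- numeric(n)
    if (!cfg$includeCsd) return(w)
    rel <- tS - onsetS
    L <- 1 / (1 + exp(-rel / cfg$waveTauS))
    dec <- exp(-pmax(0, rel - cfg$wavePlateauS) / cfg$waveReturnTauS)
    cfg$waveAmplitudeDff * L * dec
  }
  if (cfg$includeCsd) {
    speedUmS <- cfg$waveSpeedMmPerMin * 1000 / 60
    u <- c(cos(cfg$waveDirectionDeg * pi / 180),
           sin(cfg$waveDirectionDeg * pi / 180))
    corners <- rbind(c(0, 0), c(cfg$fovSizeUm[1], 0), c(0, cfg$fovSizeUm[2]),
                     cfg$fovSizeUm)
    proj0 <- min(corners %*% u)
    projMax <- max(corners %*% u)
    crossS <- (projMax - proj0) / speedUmS
    trigS <- (trigger - 1) / fr
    if (trigS + cfg$waveLagS + crossS + 60 > n / fr)
      stop("infeasible config: wave does not cross the FOV within the post-CSD window",
           call. = FALSE)
    onsetOf <- function(p) trigS + cfg$waveLagS + (sum(p * u) - proj0) / speedUmS
    stepUm <- cfg$binSizePx * cfg$pixelSizeUm
    binOnset <- matrix(NA_real_, nby, nbx)
    for (r in seq_len(nby)) for (cc in seq_len(nbx))
      binOnset[r, cc] <- onsetOf(c((cc - 0.5) * stepUm, (r - 0.5) * stepUm))
    roiOnset <- apply(cent, 1, onsetOf)
    waveTruth <- list(speed_mm_per_min = cfg$waveSpeedMmPerMin,
                      direction_deg = cfg$waveDirectionDeg,
                      bin_onset_s = binOnset, roi_onset_s = roiOnset,
                      global_onset_s = min(binOnset),
                      trigger_s = trigS)
  }

  # ---- background grid -----------------------------------------------------
  bgBase <- 500
  bg <- array(0, dim = c(nby, nbx, n))
  noiseSd <- cfg$waveNoiseFrac * bgBase * cfg$waveAmplitudeDff
  for (r in seq_len(nby)) for (cc in seq_len(nbx)) {
    w <- if (cfg$includeCsd) waveDffAt(waveTruth$bin_onset_s[r, cc]) else numeric(n)
    bg[r, cc, ] <- bgBase * (1 + w) +
      if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
  }

  # ---- stillness mask (truth) for calibration -----------------------------
  boutsTruth <- extractBouts(state, fr, velocity = velocity, minDurS = 2)
  stillTruth <- stillnessEpochs(state, boutsTruth, fr)
  quietPre <- stillTruth & seq_len(n) %in% preRows

  # ---- per-fiber event trains and traces ----------------------------------
  kFrame <- .gcampKernel(cfg$gcampRiseS, cfg$gcampDecayS, 1 / fr)
  trigS <- if (cfg$includeCsd) (trigger - 1) / fr else NA_real_
  waveEndS <- if (cfg$includeCsd) max(waveTruth$bin_onset_s) + cfg$wavePlateauS else NA_real_
  fiberZ <- matrix(0, nFib, n)
  eventTimes <- vector("list", nFib)
  baselineOcc <- ifelse(ongoing == "suppressed",
                        cfg$suppressedBaselineOccupancy, cfg$targetOccupancy)
  calCache <- list()
  for (f in seq_len(nFib)) {
    drive <- as.numeric(xLag %*% betaPre[f, ])
    if (cfg$includeCsd && any(betaPost[f, ] != betaPre[f, ])) {
      drivePost <- as.numeric(xLag %*% betaPost[f, ])
      drive[-preRows] <- drivePost[-preRows]
    }
    dvar <- if (sum(quietPre) > 1) var(drive[quietPre]) else 0
    sup <- ongoing[f] == "suppressed"
    ampF <- if (sup) cfg$suppressedEventAmpDff else cfg$eventAmpDff
    sdlF <- if (sup) cfg$suppressedEventAmpSdLog else cfg$eventAmpSdLog
    key <- sprintf("%.4f|%.4f|%.3f", baselineOcc[f], round(dvar, 4), ampF)
    if (is.null(calCache[[key]]))
      calCache[[key]] <- .calibrateEventRate(baselineOcc[f], cfg,
                                             extraVar = dvar, ampDff = ampF,
                                             ampSdLog = sdlF)
    cal <- calCache[[key]]
    lam <- cal$rate_hz
    totS <- n / fr
    if (sup && cfg$suppressedRegularity > 1) {
      # quasi-regular renewal train: gamma inter-event intervals
      kap <- cfg$suppressedRegularity
      iv <- rgamma(ceiling(lam * totS * 1.5) + 20, shape = kap,
                   rate = kap * lam)
      evT <- cumsum(iv)
      evT <- evT[evT < totS]
    } else {
      nEv <- rpois(1, lam * totS)
      evT <- sort(runif(nEv, 0, totS))
    }
    if (cfg$includeCsd) {
      if (ongoing[f] == "suppressed") {
        supLo <- waveEndS
        supHi <- supLo + cfg$effectDurationMin * 60
        evT <- evT[evT < supLo | evT > supHi]
      } else if (ongoing[f] == "activated") {
        actLo <- trigS + cfg$activationDelayMin * 60
        actHi <- actLo + cfg$effectDurationMin * 60
        keyA <- sprintf("A%.4f|%.4f", cfg$activatedOccupancy, round(dvar, 4))
        if (is.null(calCache[[keyA]]))
          calCache[[keyA]] <- .calibrateEventRate(cfg$activatedOccupancy, cfg,
                                                  sdFixed = cal$sd_inflation,
                                                  ampDff = ampF,
                                                  ampSdLog = sdlF)
        lamA <- calCache[[keyA]]$rate_hz
        nExtra <- rpois(1, max(0, lamA - lam) * (actHi - actLo))
        evT <- sort(c(evT, runif(nExtra, actLo, actHi)))
      }
    }
    eventTimes[[f]] <- evT
    imp <- numeric(n)
    if (length(evT)) {
      fidx <- pmin(n, floor(evT * fr) + 1L)
      amps <- rlnorm(length(evT), log(ampF / cfg$quietDffSd), sdlF)
      for (j in seq_along(fidx)) imp[fidx[j]] <- imp[fidx[j]] + amps[j]
    }
    ev <- as.numeric(stats::filter(imp, kFrame, sides = 1))
    ev[is.na(ev)] <- 0
    fiberZ[f, ] <- ev + drive + rnorm(n, 0, cfg$fiberNoiseSd)
  }

  # ---- assemble ROI and neuropil traces -----------------------------------
  roiTr <- matrix(0, nRoi, n)
  npTr <- matrix(0, nRoi, n)
  f0Base <- runif(nRoi, 800, 1200)
  npBase <- runif(nRoi, 500, 700)
  for (i in seq_len(nRoi)) {
    f <- fiberOf[i] + 1L
    w <- if (cfg$includeCsd) waveDffAt(waveTruth$roi_onset_s[i]) else numeric(n)
    dff <- cfg$quietDffSd * (fiberZ[f, ] + rnorm(n, 0, cfg$roiNoiseSd)) + w
    npTr[i, ] <- npBase[i] * (1 + 0.3 * w) + rnorm(n, 0, 2)
    roiTr[i, ] <- f0Base[i] * (1 + dff) + (npTr[i, ] - mean(npTr[i, ]))
  }

  session <- RecordingSession(
    sessionId = sprintf("synthetic-%d", cfg$seed),
    roiTraces = roiTr, neuropilTraces = npTr, roiCentroidsUm = cent,
    backgroundGrid = bg, wheelPosition = wheelPos,
    affineLinear = affLin, affineTranslation = affTr, zShiftUm = defZ,
    csdTriggerFrame = trigger, frameRateHz = fr,
    wheelRateHz = cfg$wheelRateHz, fovSizeUm = cfg$fovSizeUm,
    pixelSizeUm = cfg$pixelSizeUm, binSizePx = cfg$binSizePx)

  # planted coefficients on the scale the pipeline reports: each ROI trace is
  # standardized by its quiet-epoch SD, so the measured coefficient is the
  # planted one divided by that SD (fiber signal + independent ROI noise)
  sigMeas <- vapply(seq_len(nFib), function(f)
    sqrt(var(fiberZ[f, quietPre]) + cfg$roiNoiseSd^2), numeric(1))
  betaPreMeas <- betaPre / sigMeas
  betaPostMeas <- betaPost / sigMeas

  sensCat <- rep("never_fit", nFib)
  sensCat[coupledIdx] <- "unchanged"
  sensCat[sensIdx] <- "sensitized_both_fit"
  sensCat[lostIdx] <- "desensitized_lost"
  sensCat[unmaskedIdx] <- "sensitized_unmasked"
  fibers <- data.frame(
    fiber = seq_len(nFib) - 1L, n_rois = nroiFib, role = role,
    ongoing_class = ongoing,
    ongoing_latency_min = ifelse(ongoing == "activated",
                                 cfg$activationDelayMin,
                                 ifelse(ongoing == "suppressed", 0, NA)),
    ongoing_duration_min = ifelse(ongoing == "none", NA, cfg$effectDurationMin),
    baseline_occupancy = baselineOcc,
    sensitization = if (cfg$includeCsd) sensCat else NA_character_)

  truth <- structure(list(
    fiber_of_roi = fiberOf, roi_arc_dist_um = arcDist,
    fibers = fibers, glm_truth_pre = betaPre, glm_truth_post = betaPost,
    glm_truth_pre_measured = betaPreMeas,
    glm_truth_post_measured = betaPostMeas,
    quiet_sd_inflation = sigMeas,
    coupling_delay_frames = dly,
    wave = waveTruth,
    locomotion = list(state = state, velocity = velocity, bouts = boutsTruth,
                      stillness_mask = stillTruth),
    deformation = list(scale = defScale, shear = defShear, zshift = defZ),
    event_times = eventTimes,
    config = cfg), class = "GroundTruth")
  list(session = session, truth = truth)
}

#' Write the standard fixture suite
#'
#' Generates and writes four named, seeded fixtures used throughout the test
#' suite: a noiseless planar wave, a pure-noise cohort (all coupling
#' coefficients zero, no CSD), a sensitization cohort, and an
#' ongoing-activity cohort. Ground truth is serialized alongside as JSON.
#'
#' @param outDir Output directory (created if needed).
#' @return Named character vector of session file paths.
#' @export
makeFixtureSuite <- function(outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cfgs <- fixtureConfigs()
  out <- character(0)
  for (nm in names(cfgs)) {
    gen <- generateSession(cfgs[[nm]])
    p <- file.path(outDir, paste0(nm, ".h5"))
    writeSession(gen$session, p)
    tr <- gen$truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr[c("fiber_of_roi", "fibers", "glm_truth_pre",
                              "glm_truth_post")],
                         file.path(outDir, paste0(nm, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    out[nm] <- p
  }
  out
}

#' Configurations of the standard fixtures
#'
#' @return Named list of `SimConfig` objects (`noiseless_wave`,
#'   `pure_noise`, `sensitization_cohort`, `ongoing_cohort`).
#' @export
fixtureConfigs <- function() {
  list(
    noiseless_wave = simConfig(seed = 101L, durationPreMin = 10,
                               durationPostMin = 10, nFibers = 4L,
                               fracDeformCoupled = 0, fracLocoCoupled = 0,
                               fracUnmasked = 0, fracLost = 0,
                               activatedFraction = 0, suppressedFraction = 0,
                               waveNoiseFrac = 0),
    pure_noise = simConfig(seed = 102L, durationPreMin = 30,
                           durationPostMin = 0, includeCsd = FALSE,
                           nFibers = 8L, fracDeformCoupled = 0,
                           fracLocoCoupled = 0, fracUnmasked = 0,
                           fracLost = 0, activatedFraction = 0,
                           suppressedFraction = 0),
    sensitization_cohort = simConfig(seed = 103L, durationPreMin = 40,
                                     durationPostMin = 50, nFibers = 20L,
                                     roisPerFiber = c(2L, 4L),
                                     activatedFraction = 0,
                                     suppressedFraction = 0),
    ongoing_cohort = simConfig(seed = 104L, durationPreMin = 40,
                               durationPostMin = 65, nFibers = 20L,
                               roisPerFiber = c(2L, 4L),
                               fracDeformCoupled = 0, fracLocoCoupled = 0,
                               fracUnmasked = 0, fracLost = 0))
  }
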