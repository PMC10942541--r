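# Independent brute-force oracles and shared synthetic fixtures.

# -- oracles (deliberately simple scans, independent of the implementation) --

# Event detection by explicit forward scan.
oracleEvents <- function(z, dff, rate, zThresh = 1, minDur = 1, minPeak = 0.05) {
  n <- length(z)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (z[i] > zThresh) {
      j <- i
      while (j < n && z[j + 1L] > zThresh) j <- j + 1L
      if ((j - i + 1L) / rate >= minDur && max(dff[i:j]) >= minPeak)
        out <- rbind(out, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Trailing-window percentile by direct quantile calls.
oracleTrailingQuantile <- function(f, w, p) {
  vapply(seq_along(f), function(i)
    as.numeric(quantile(f[max(1, i - w + 1):i], p, type = 7)), numeric(1))
}

# Maximal TRUE-runs by explicit scan.
oracleRuns <- function(state) {
  n <- length(state)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (state[i]) {
      j <- i
      while (j < n && state[j + 1L]) j <- j + 1L
      out <- rbind(out, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Benjamini-Hochberg step-up by the textbook formula.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Adjusted Rand index (mclust is the independent reference where available;
# fall back to the closed form otherwise).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# -- shared fixtures (memoized across test files) ---------------------------

.fixtureCache <- new.env(parent = emptyenv())

cachedSession <- function(name) {
  if (!is.null(.fixtureCache[[name]])) return(.fixtureCache[[name]])
  gen <- switch(name,
    plain = generateSession(simConfig(
      seed = 11L, durationPreMin = 40, durationPostMin = 0, includeCsd = FALSE,
      nFibers = 6L, fracDeformCoupled = 0, fracLocoCoupled = 0,
      fracUnmasked = 0, fracLost = 0, activatedFraction = 0,
      suppressedFraction = 0)),
    wave = generateSession(simConfig(
      seed = 77L, durationPreMin = 6, durationPostMin = 8, nFibers = 4L,
      roisPerFiber = c(6L, 8L), fracDeformCoupled = 0, fracLocoCoupled = 0,
      fracUnmasked = 0, fracLost = 0, activatedFraction = 0,
      suppressedFraction = 0)),
    stop("unknown fixture ", name))
  .fixtureCache[[name]] <- gen
  gen
}

# Majority-vote map from detected fiber labels to planted fiber ids.
mapFibersToTruth <- function(found, truthOfRoi) {
  vapply(sort(unique(found)), function(f) {
    tt <- truthOfRoi[found == f]
    as.integer(names(sort(table(tt), decreasing = TRUE))[1])
  }, integer(1))
}

# Standardized z/dff matrices plus per-ROI event trains for a session.
roiSignals <- function(session, loco) {
  n <- nFrames(session)
  rate <- frameRate(session)
  trigger <- csdTriggerFrame(session)
  pre <- if (is.na(trigger)) rep(TRUE, n) else seq_len(n) < trigger
  quiet <- loco$stillness_mask & pre
  z <- dff <- matrix(0, nRois(session), n)
  events <- vector("list", nRois(session))
  for (i in seq_len(nRois(session))) {
    st <- standardizedTrace(roiTraces(session)[i, ],
                            neuropilTraces(session)[i, ], quiet, rate)
    z[i, ] <- st$z
    dff[i, ] <- st$dff
    events[[i]] <- detectEvents(st$z, st$dff, rate)
  }
  list(z = z, dff = dff, events = events, quiet = quiet)
}
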