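# Locomotion: wheel-derived velocity, HMM state segmentation, bouts,
# stillness epochs.

#' Instantaneous velocity from wheel position
#'
#' First-differences the wheel encoder series (sampled at `wheelRateHz`),
#' scales by the sampling rate, and block-averages the resulting velocity
#' onto the imaging frame grid (frame k covers [k/frameRateHz,
#' (k+1)/frameRateHz)). Frames receiving no wheel sample (possible only at
#' the very end of a recording) repeat the preceding value.
#'
#' @param wheelPos Wheel position series (encoder units).
#' @param wheelRateHz Wheel sampling rate (Hz).
#' @param frameRateHz Imaging frame rate (Hz).
#' @param nFrames Number of imaging frames to produce.
#' @return Velocity series at the frame rate (encoder units / s).
#' @export
wheelToVelocity <- function(wheelPos, wheelRateHz, frameRateHz, nFrames) {
  if (length(wheelPos) < 2) stop("need at least 2 wheel samples", call. = FALSE)
  v <- diff(wheelPos) * wheelRateHz          # at times j / wheelRateHz, j >= 1
  tj <- seq_along(v) / wheelRateHz
  bin <- pmin(nFrames, floor(tj * frameRateHz) + 1L)
  out <- as.numeric(tapply(v, factor(bin, levels = seq_len(nFrames)), mean))
  # carry last defined value into any empty trailing frames
  for (i in seq_len(nFrames))
    if (is.na(out[i])) out[i] <- if (i == 1L) 0 else out[i - 1L]
  out
}

# One EM run for a 2-state Gaussian HMM on a 1-D series.
#' @noRd
.hmmEm <- function(x, mu, sigma, trans, init, maxIter = 60, tol = 1e-6) {
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    fb <- hmm_forward_backward(x, mu, sigma, trans, init)
    g <- fb$gamma
    nk <- colSums(g)
    mu <- as.numeric(crossprod(g, x)) / nk
    for (k in 1:2) {
      v <- sum(g[, k] * (x - mu[k])^2) / nk[k]
      sigma[k] <- sqrt(max(v, 1e-10))
    }
    trans <- fb$xi / rowSums(fb$xi)
    trans[!is.finite(trans)] <- 0.5
    init <- g[1, ] / sum(g[1, ])
    if (abs(fb$loglik - ll0) < tol * abs(ll0 + 1)) {
      ll0 <- fb$loglik
      break
    }
    ll0 <- fb$loglik
  }
  list(mu = mu, sigma = sigma, trans = trans, init = init, loglik = ll0)
}

#' Two-state hidden-Markov locomotion segmentation
#'
#' Fits a two-state Gaussian-emission HMM to the speed (absolute velocity)
#' series by EM with multiple random restarts, keeps the highest-likelihood
#' fit, and returns the Viterbi state path. The state with the higher
#' emission mean is labeled "locomoting", so the labeling is invariant to
#' state-index permutation.
#'
#' @param velocity Velocity series at the frame rate.
#' @param seed Integer seed controlling the random restarts.
#' @param nRestarts Number of EM restarts (default 20).
#' @return Logical series, TRUE where locomoting.
#' @export
fitLocomotionHmm <- function(velocity, seed = 1L, nRestarts = 20L) {
  x <- abs(as.numeric(velocity))
  if (length(x) < 60)
    stop("velocity series too short for HMM segmentation", call. = FALSE)
  if (sd(x) == 0) {
    warning("degenerate velocity series; returning all-still")
    return(logical(length(x)))
  }
  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  qs <- quantile(x, c(0.25, 0.9))
  for (r in seq_len(nRestarts)) {
    mu0 <- sort(abs(c(qs[1] * runif(1, 0.5, 1.5), qs[2] * runif(1, 0.5, 1.5))))
    if (diff(mu0) < 1e-8) mu0[2] <- mu0[2] + sd(x)
    sigma0 <- rep(max(sd(x) / 2, 1e-6), 2)
    p <- runif(2, 0.9, 0.999)
    trans0 <- matrix(c(p[1], 1 - p[1], 1 - p[2], p[2]), 2, byrow = TRUE)
    fit <- tryCatch(.hmmEm(x, mu0, sigma0, trans0, c(0.5, 0.5)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("HMM fitting failed", call. = FALSE)
  path <- hmm_viterbi(x, best$mu, best$sigma, best$trans, best$init)
  runState <- which.max(best$mu) - 1L
  path == runState
}

# Save/restore the global RNG state so seeded internals do not perturb the
# caller's stream.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract locomotion bouts
#'
#' Maximal runs of the locomotion state lasting at least `minDurS` seconds
#' (default 2 s).
#'
#' @param state Logical locomotion-state series at the frame rate.
#' @param frameRateHz Frame rate.
#' @param velocity Optional velocity series for per-bout peak velocity.
#' @param minDurS Minimum bout duration in seconds.
#' @return data.frame with columns `start_frame`, `end_frame` (1-based,
#'   inclusive), `start_s`, `end_s`, `duration_s`, `peak_velocity` (NA when
#'   no velocity given).
#' @export
extractBouts <- function(state, frameRateHz, velocity = NULL, minDurS = 2) {
  runs <- .trueRuns(state)
  dur <- (runs$end - runs$start + 1) / frameRateHz
  keep <- dur >= minDurS
  runs <- runs[keep, , drop = FALSE]
  dur <- dur[keep]
  pk <- rep(NA_real_, nrow(runs))
  if (!is.null(velocity))
    for (i in seq_len(nrow(runs)))
      pk[i] <- max(abs(velocity[runs$start[i]:runs$end[i]]))
  data.frame(start_frame = runs$start, end_frame = runs$end,
             start_s = (runs$start - 1) / frameRateHz,
             end_s = runs$end / frameRateHz,
             duration_s = dur, peak_velocity = pk)
}

#' Bout rate over an analysis window
#'
#' @param bouts Bout table from [extractBouts()].
#' @param windowMin Window duration in minutes.
#' @return Bouts per minute.
#' @export
boutRate <- function(bouts, windowMin) nrow(bouts) / windowMin

#' Stillness epochs
#'
#' Marks frames that are not in the locomotion state and at least `marginS`
#' seconds away from every bout boundary (30-s margins before and after each
#' bout are excluded to avoid residual locomotion-evoked activity).
#'
#' @param state Logical locomotion-state series.
#' @param bouts Bout table from [extractBouts()].
#' @param frameRateHz Frame rate.
#' @param marginS Exclusion margin in seconds (default 30).
#' @return Logical stillness mask.
#' @export
stillnessEpochs <- function(state, bouts, frameRateHz, marginS = 30) {
  mask <- !state
  m <- .frames(marginS, frameRateHz)
  for (i in seq_len(nrow(bouts))) {
    lo <- max(1L, bouts$start_frame[i] - m)
    hi <- min(length(state), bouts$end_frame[i] + m)
    mask[lo:hi] <- FALSE
  }
  mask
}

#' Full locomotion analysis for a session
#'
#' Derives velocity from the wheel series, segments the locomotion state with
#' the two-state HMM, extracts bouts and the stillness mask.
#'
#' @param session A [RecordingSession-class].
#' @param seed Seed for the HMM restarts.
#' @param minDurS,marginS Bout and stillness parameters.
#' @return A `LocomotionSeries` list with `velocity`, `state`, `bouts`,
#'   `stillness_mask`.
#' @export
locomotionSeries <- function(session, seed = 1L, minDurS = 2, marginS = 30) {
  v <- wheelToVelocity(wheelPosition(session), wheelRate(session),
                       frameRate(session), nFrames(session))
  st <- fitLocomotionHmm(v, seed = seed)
  bouts <- extractBouts(st, frameRate(session), velocity = v, minDurS = minDurS)
  structure(list(velocity = v, state = st, bouts = bouts,
                 stillness_mask = stillnessEpochs(st, bouts, frameRate(session),
                                                  marginS)),
            class = "LocomotionSeries")
}
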