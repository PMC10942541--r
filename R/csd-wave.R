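# CSD-associated calcium wave: FOV-level detection, per-bin logistic onset
# mapping, speed/direction estimation, per-fiber activation pace.

#' Field-of-view mean background fluorescence
#'
#' @param session A [RecordingSession-class].
#' @return Series of the mean over all background-grid bins.
#' @export
fovTrace <- function(session) {
  g <- backgroundGrid(session)
  apply(g, 3, mean)
}

#' Detect the CSD calcium-wave window in the FOV trace
#'
#' Within the first `searchMin` minutes after the trigger: smooths the time
#' derivative of F_FOV with a `smoothS`-second moving average and takes the
#' initial period t_initial between the derivative's maximum and the
#' following minimum; computes the pre-wave baseline F_pre as the 10th
#' percentile of F_FOV over the 30 s before t_initial; normalizes
#' dFF = (F_FOV - F_pre)/F_pre; sets the threshold at 0.1 x the dFF maximum
#' over t_initial; and walks outward from the peak to the threshold
#' crossings, which define the wave onset and offset. The threshold is
#' relative, so the result is invariant to uniform scaling of fluorescence.
#'
#' @param fFov FOV-mean fluorescence series.
#' @param triggerFrame 1-based frame of CSD induction.
#' @param frameRateHz Frame rate.
#' @param searchMin Post-trigger search window in minutes (default 5).
#' @param smoothS Derivative smoothing window in seconds (default 1).
#' @return A `WaveWindow` list: `t_initial` (frames of derivative max/min),
#'   `f_pre`, `threshold`, `onset_frame`, `offset_frame`, `onset_s`,
#'   `offset_s`, `peak_dff`.
#' @export
detectWaveWindow <- function(fFov, triggerFrame, frameRateHz,
                             searchMin = 5, smoothS = 1) {
  n <- length(fFov)
  last <- min(n, triggerFrame + .frames(searchMin * 60, frameRateHz))
  if ((last - triggerFrame) / frameRateHz < 60)
    stop("need at least 1 min of frames after the trigger", call. = FALSE)
  win <- triggerFrame:last
  f <- fFov[win]
  d <- c(0, diff(f)) * frameRateHz
  d <- .movingAverage(d, .frames(smoothS, frameRateHz))
  iMax <- which.max(d)
  iMin <- iMax + which.min(d[iMax:length(d)]) - 1L
  preLo <- max(1L, win[iMax] - .frames(30, frameRateHz))
  preIdx <- preLo:max(preLo, win[iMax] - 1L)
  fPre <- as.numeric(quantile(fFov[preIdx], 0.10))
  if (fPre <= 0) stop("non-positive pre-wave baseline", call. = FALSE)
  dff <- (fFov - fPre) / fPre
  thr <- 0.1 * max(dff[win[iMax]:win[iMin]])
  if (thr <= 0 || max(dff[win]) < max(thr, 1e-3))
    stop("no wave detected: no supra-threshold excursion", call. = FALSE)
  iPk <- win[iMax] + which.max(dff[win[iMax]:win[iMin]]) - 1L
  onset <- iPk
  while (onset > 1L && dff[onset - 1L] > thr) onset <- onset - 1L
  offset <- iPk
  while (offset < n && dff[offset + 1L] > thr) offset <- offset + 1L
  structure(list(t_initial = c(win[iMax], win[iMin]), f_pre = fPre,
                 threshold = thr, onset_frame = onset, offset_frame = offset,
                 onset_s = (onset - 1) / frameRateHz,
                 offset_s = (offset - 1) / frameRateHz,
                 peak_dff = dff[iPk]),
            class = "WaveWindow")
}

# Logistic fit of one peri-wave trace: A/(1+exp(-(t-t0)/tau)) + K.
# Grid search over (t0, tau) with A, K solved by linear least squares, then
# Levenberg-Marquardt refinement from the best grid point.
#' @noRd
.fitLogistic <- function(t, y, tauGrid = c(0.5, 1, 2)) {
  best <- NULL
  n <- length(t)
  sy <- sum(y)
  for (t0 in seq(min(t), max(t), by = 1)) {
    for (tau in tauGrid) {
      L <- 1 / (1 + exp(-(t - t0) / tau))
      # closed-form least squares for y ~ K + A * L
      sL <- sum(L); sLL <- sum(L * L); sLy <- sum(L * y)
      det <- n * sLL - sL * sL
      if (abs(det) < 1e-12) next
      A <- (n * sLy - sL * sy) / det
      K <- (sy - A * sL) / n
      sse <- sum((y - K - A * L)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(t0 = t0, tau = tau, A = A, K = K, sse = sse)
    }
  }
  if (is.null(best) || !is.finite(best$A)) return(NULL)
  refined <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + exp(-(t - t0) / tau)) + K,
                      start = list(A = unname(best$A), t0 = best$t0,
                                   tau = best$tau, K = unname(best$K)),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  sst <- sum((y - mean(y))^2)
  if (!is.null(refined)) {
    p <- coef(refined)
    sse <- sum(resid(refined)^2)
    list(A = unname(p["A"]), t_onset = unname(p["t0"]), tau = unname(p["tau"]),
         K = unname(p["K"]), r2 = if (sst > 0) 1 - sse / sst else 0)
  } else {
    list(A = unname(best$A), t_onset = best$t0, tau = best$tau,
         K = unname(best$K), r2 = if (sst > 0) 1 - best$sse / sst else 0)
  }
}

#' Fit per-bin logistic onsets of the CSD wave
#'
#' For every background-grid bin, gathers the peri-wave data from
#' `periS[1]` to `periS[2]` seconds relative to the wave onset (default -6 to
#' +14 s) and fits a logistic A/(1+exp(-(t-t_onset)/tau))+K by nonlinear
#' least squares with multi-start initialization. Fits with R^2 < 0.5,
#' tau > 2 s, or tau < 0 s are excluded. Bins flagged in `roiExclusionMask`
#' (bins overlapping or neighboring ROIs) are skipped.
#'
#' @param session A [RecordingSession-class].
#' @param window A `WaveWindow` from [detectWaveWindow()].
#' @param roiExclusionMask Optional logical matrix [nBinsY x nBinsX]; TRUE
#'   bins are not fitted.
#' @param periS Peri-onset window in seconds (default c(-6, 14)).
#' @return A `BinOnsetFit` data.frame with one row per fitted bin: `row`,
#'   `col`, `x_um`, `y_um`, `A`, `t_onset` (s, absolute), `tau`, `K`, `r2`,
#'   `included`.
#' @export
fitBinOnsets <- function(session, window, roiExclusionMask = NULL,
                         periS = c(-6, 14)) {
  g <- backgroundGrid(session)
  rate <- frameRate(session)
  centers <- binCenters(session)
  lo <- max(1L, window$onset_frame + as.integer(round(periS[1] * rate)))
  hi <- min(dim(g)[3], window$onset_frame + as.integer(round(periS[2] * rate)))
  t <- ((lo:hi) - 1) / rate
  out <- centers
  out$A <- out$t_onset <- out$tau <- out$K <- out$r2 <- NA_real_
  out$included <- FALSE
  for (i in seq_len(nrow(centers))) {
    r <- centers$row[i]; cc <- centers$col[i]
    if (!is.null(roiExclusionMask) && roiExclusionMask[r, cc]) next
    y <- g[r, cc, lo:hi]
    if (sd(y) == 0) next
    fit <- .fitLogistic(t, y)
    if (is.null(fit)) next
    out$A[i] <- fit$A; out$t_onset[i] <- fit$t_onset; out$tau[i] <- fit$tau
    out$K[i] <- fit$K; out$r2[i] <- fit$r2
    out$included[i] <- is.finite(fit$r2) && fit$r2 >= 0.5 &&
      fit$tau >= 0 && fit$tau <= 2
  }
  if (!any(out$included))
    stop("insufficient wave coverage: all bins excluded", call. = FALSE)
  structure(out, class = c("BinOnsetFit", "data.frame"))
}

#' Estimate wave speed and direction from per-bin onsets
#'
#' The wavefront contour is the level set of the (bilinearly interpolated)
#' onset map at the median included onset time; the contour is fitted to a
#' line by total least squares and the propagation direction is the vector
#' orthogonal to that line, oriented toward increasing onset times. Speed is
#' the inverse slope of the regression of onset time on the projection of
#' bin centers onto the propagation direction, reported in mm/min.
#' Directions are image-coordinate bearings in degrees
#' (atan2(dy, dx); +y is posterior, so 90 deg means anterior-to-posterior).
#'
#' @param fits A `BinOnsetFit` from [fitBinOnsets()].
#' @param minBins Minimum number of included bins (default 6).
#' @return A `WaveEstimate` list: `speed_mm_per_min`, `direction_deg`,
#'   `n_bins_included`, `onset_map`.
#' @export
estimateSpeedDirection <- function(fits, minBins = 6) {
  inc <- fits[fits$included, , drop = FALSE]
  if (nrow(inc) < minBins)
    stop(sprintf("only %d included bins; need at least %d", nrow(inc), minBins),
         call. = FALSE)
  if (sd(inc$t_onset) < 1e-6)
    stop("no propagation: onset times are simultaneous", call. = FALSE)
  med <- median(inc$t_onset)
  # contour points: crossings of the median level on grid edges
  pts <- NULL
  onsetAt <- function(r, cc) {
    i <- which(fits$row == r & fits$col == cc)
    if (length(i) != 1 || !fits$included[i]) NA_real_ else fits$t_onset[i]
  }
  for (i in seq_len(nrow(inc))) {
    r <- inc$row[i]; cc <- inc$col[i]; o1 <- inc$t_onset[i]
    for (dd in list(c(0L, 1L), c(1L, 0L))) {
      o2 <- onsetAt(r + dd[1], cc + dd[2])
      if (is.na(o2) || o1 == o2) next
      u <- (med - o1) / (o2 - o1)
      if (u < 0 || u > 1) next
      j <- which(inc$row == r + dd[1] & inc$col == cc + dd[2])
      pts <- rbind(pts, c(inc$x_um[i] + u * (inc$x_um[j] - inc$x_um[i]),
                          inc$y_um[i] + u * (inc$y_um[j] - inc$y_um[i])))
    }
  }
  if (is.null(pts) || nrow(pts) < 2)
    stop("direction undefined: wavefront contour could not be traced",
         call. = FALSE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 2]                     # orthogonal to the fitted line
  # orient toward increasing onset and measure speed along that axis
  proj <- cbind(inc$x_um, inc$y_um) %*% normal
  fitLm <- lm(inc$t_onset ~ proj)
  slope <- unname(coef(fitLm)[2])         # s / um
  if (!is.finite(slope) || slope == 0)
    stop("no propagation along the wavefront normal", call. = FALSE)
  if (slope < 0) { normal <- -normal; slope <- -slope }
  structure(list(
    speed_mm_per_min = (1 / slope) * 60 / 1000,
    direction_deg = (atan2(normal[2], normal[1]) * 180 / pi) %% 360,
    n_bins_included = nrow(inc),
    onset_map = fits),
    class = "WaveEstimate")
}

#' Activation pace along a single afferent fiber
#'
#' Fits each ROI's peri-wave trace to the logistic onset model and regresses
#' onset time on arc distance along the fiber. Reported as pace (s/mm, the
#' inverse of speed), which stays finite when activation is simultaneous, as
#' during locomotion bouts.
#'
#' @param traces Matrix [nRois x nFrames] of the fiber's ROI traces, ordered
#'   along the fiber.
#' @param arcDistUm Arc distance of each ROI along the fiber (um).
#' @param window A `WaveWindow` (or any list with `onset_frame`) centering
#'   the peri-event window.
#' @param frameRateHz Frame rate.
#' @param periS Peri-onset window (default c(-6, 14) s).
#' @param minSpanUm Minimum fiber length (default 200 um).
#' @return List with `pace_s_per_mm` and an `onsets` data.frame
#'   (`arc_dist_um`, `onset_s`, `r2`, `used`).
#' @export
fiberActivationPace <- function(traces, arcDistUm, window, frameRateHz,
                                periS = c(-6, 14), minSpanUm = 200) {
  stopifnot(nrow(traces) == length(arcDistUm))
  if (diff(range(arcDistUm)) <= minSpanUm)
    stop(sprintf("fiber span %.0f um; need > %.0f um", diff(range(arcDistUm)),
                 minSpanUm), call. = FALSE)
  if (nrow(traces) < 3) stop("need at least 3 ROIs", call. = FALSE)
  lo <- max(1L, window$onset_frame + as.integer(round(periS[1] * frameRateHz)))
  hi <- min(ncol(traces), window$onset_frame + as.integer(round(periS[2] * frameRateHz)))
  t <- ((lo:hi) - 1) / frameRateHz
  onset <- r2 <- rep(NA_real_, nrow(traces))
  for (i in seq_len(nrow(traces))) {
    y <- traces[i, lo:hi]
    if (sd(y) == 0) next
    fit <- .fitLogistic(t, y)
    if (is.null(fit)) next
    onset[i] <- fit$t_onset; r2[i] <- fit$r2
  }
  used <- is.finite(onset) & is.finite(r2) & r2 >= 0.5
  if (sum(used) < 3) stop("fewer than 3 usable ROI fits", call. = FALSE)
  slope <- coef(lm(onset[used] ~ arcDistUm[used]))[2]   # s / um
  list(pace_s_per_mm = unname(slope) * 1000,
       onsets = data.frame(arc_dist_um = arcDistUm, onset_s = onset, r2 = r2,
                           used = used))
}
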