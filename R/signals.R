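# Fluorescence signal conditioning and event detection.

#' Neuropil correction
#'
#' Subtracts the background-mask (neuropil) signal from the raw ROI signal
#' and adds back the neuropil mean over the whole recording, so the corrected
#' trace F = F_ROI - F_np + <F_np> keeps the original mean level:
#' mean(F) = mean(F_ROI).
#'
#' @param fRoi Raw ROI fluorescence series.
#' @param fNp Neuropil-mask fluorescence series of the same length.
#' @return Corrected fluorescence series.
#' @export
correctNeuropil <- function(fRoi, fNp) {
  if (length(fRoi) != length(fNp))
    stop(sprintf("length mismatch: fRoi has %d samples, fNp has %d",
                 length(fRoi), length(fNp)), call. = FALSE)
  .assertFinite(fRoi, "fRoi"); .assertFinite(fNp, "fNp")
  fRoi - fNp + mean(fNp)
}

#' Rolling trailing-percentile baseline
#'
#' Baseline F0 at each frame is the given percentile of the trace over the
#' trailing window (t - windowS, t]. Frames earlier than one full window use
#' the partial history available, so the baseline is defined from the first
#' frame on. Percentiles interpolate linearly between order statistics
#' (R quantile type 7).
#'
#' @param f Fluorescence series.
#' @param frameRateHz Sampling rate (frames/s).
#' @param windowS Trailing window length in seconds (default 32).
#' @param percentile Percentile in (0, 100) (default 10).
#' @return Baseline series of the same length as `f`.
#' @export
rollingBaseline <- function(f, frameRateHz, windowS = 32, percentile = 10) {
  if (windowS <= 0) stop("windowS must be positive", call. = FALSE)
  w <- as.integer(round(windowS * frameRateHz))
  if (w < 2) stop("window must span at least 2 samples at this rate", call. = FALSE)
  rolling_trailing_quantile(as.numeric(f), w, percentile / 100)
}

#' Normalized fluorescence change
#'
#' dFF = (F - F0) / F0 against a rolling baseline.
#'
#' @inheritParams rollingBaseline
#' @return List with `f0` and `dff` series.
#' @export
deltaFOverF <- function(f, frameRateHz, windowS = 32, percentile = 10) {
  f0 <- rollingBaseline(f, frameRateHz, windowS, percentile)
  if (any(f0 <= 0))
    stop("baseline F0 is non-positive; dFF undefined", call. = FALSE)
  list(f0 = f0, dff = (f - f0) / f0)
}

#' Standardize a dFF trace against quiet-wakefulness variability
#'
#' z = (dff - median(dff)) / SD(dff over quiet samples). The median is taken
#' over the full trace; the SD only over the quiet mask (stillness outside
#' locomotion bouts and their 30-s margins), so event-rich epochs do not
#' inflate the noise estimate.
#'
#' @param dff dFF series.
#' @param quietMask Logical series marking quiet-wakefulness samples.
#' @param frameRateHz Sampling rate, used to require at least 30 s of quiet.
#' @return Standardized (z) series.
#' @export
standardizeTrace <- function(dff, quietMask, frameRateHz) {
  if (length(dff) != length(quietMask))
    stop("dff and quietMask lengths differ", call. = FALSE)
  if (sum(quietMask) < 30 * frameRateHz)
    stop("quietMask must cover at least 30 s of samples", call. = FALSE)
  s <- sd(dff[quietMask])
  if (!is.finite(s) || s == 0)
    stop("zero variance over quiet samples; cannot standardize", call. = FALSE)
  (dff - median(dff)) / s
}

#' Detect fluorescence events
#'
#' An event is a maximal run of frames where the standardized signal strictly
#' exceeds `zThresh` (default 1), lasting at least `minDurS` seconds (default
#' 1 s) and reaching a peak dFF of at least `minPeakDff` (default 0.05).
#' Runs failing either the duration or the peak criterion are discarded.
#'
#' @param z Standardized series.
#' @param dff dFF series aligned with `z`.
#' @param frameRateHz Sampling rate.
#' @param zThresh Threshold on z (default 1, strict inequality).
#' @param minDurS Minimum event duration in seconds (default 1).
#' @param minPeakDff Minimum peak dFF (default 0.05).
#' @return An `EventTrain`: data.frame with columns `onset_frame`,
#'   `offset_frame` (1-based, inclusive), `peak_dff`, `peak_z`, carrying an
#'   `occupancy` attribute (fraction of frames inside events).
#' @export
detectEvents <- function(z, dff, frameRateHz, zThresh = 1, minDurS = 1,
                         minPeakDff = 0.05) {
  if (length(z) != length(dff))
    stop("z and dff lengths differ", call. = FALSE)
  runs <- .trueRuns(z > zThresh)
  keep <- logical(nrow(runs))
  pk_dff <- pk_z <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    pk_dff[i] <- max(dff[idx])
    pk_z[i] <- max(z[idx])
    keep[i] <- (length(idx) / frameRateHz >= minDurS) && (pk_dff[i] >= minPeakDff)
  }
  ev <- data.frame(onset_frame = runs$start[keep],
                   offset_frame = runs$end[keep],
                   peak_dff = pk_dff[keep], peak_z = pk_z[keep])
  occ <- if (nrow(ev)) sum(ev$offset_frame - ev$onset_frame + 1) / length(z) else 0
  structure(ev, occupancy = occ, n_frames = length(z), class = c("EventTrain", "data.frame"))
}

#' Event occupancy
#'
#' @param events An `EventTrain` from [detectEvents()].
#' @return Fraction of frames inside events.
#' @export
eventOccupancy <- function(events) attr(events, "occupancy")

#' Binary event-indicator series
#'
#' @param events An `EventTrain`.
#' @param nFrames Length of the underlying trace (defaults to the length the
#'   train was detected on).
#' @return Logical vector, TRUE inside events.
#' @export
eventIndicator <- function(events, nFrames = attr(events, "n_frames")) {
  ind <- logical(nFrames)
  for (i in seq_len(nrow(events)))
    ind[events$onset_frame[i]:events$offset_frame[i]] <- TRUE
  ind
}

#' Full signal conditioning for one ROI
#'
#' Applies neuropil correction, rolling baselining, dFF normalization and
#' quiet-referenced standardization in one call.
#'
#' @param fRoi,fNp Raw ROI and neuropil series.
#' @param quietMask Logical quiet-wakefulness mask.
#' @param frameRateHz Sampling rate.
#' @param windowS,percentile Baseline parameters (see [rollingBaseline()]).
#' @return A `StandardizedTrace` list with elements `f_corrected`, `f0`,
#'   `dff`, `z`, `quiet_mask`.
#' @export
standardizedTrace <- function(fRoi, fNp, quietMask, frameRateHz,
                              windowS = 32, percentile = 10) {
  f <- correctNeuropil(fRoi, fNp)
  b <- deltaFOverF(f, frameRateHz, windowS, percentile)
  z <- standardizeTrace(b$dff, quietMask, frameRateHz)
  structure(list(f_corrected = f, f0 = b$f0, dff = b$dff, z = z,
                 quiet_mask = quietMask),
            class = "StandardizedTrace")
}
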