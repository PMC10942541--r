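# Ongoing activity during stillness in 1-min bins and classification of
# post-CSD activation/suppression.

#' Ongoing-activity rate in 1-min bins
#'
#' For each bin, the fraction of stillness frames that fall inside detected
#' fluorescence events. Bins whose stillness coverage is below `minCoverage`
#' (default 50%) are marked missing (rate NA), since too little usable time
#' makes the estimate unreliable.
#'
#' @param events An `EventTrain` from [detectEvents()].
#' @param stillnessMask Logical stillness mask over frames.
#' @param frameRateHz Frame rate.
#' @param binMin Bin width in minutes (default 1).
#' @param minCoverage Minimum stillness fraction per bin (default 0.5).
#' @return data.frame with `bin`, `start_min`, `rate`, `coverage`,
#'   `missing`.
#' @export
binOngoingRate <- function(events, stillnessMask, frameRateHz, binMin = 1,
                           minCoverage = 0.5) {
  n <- length(stillnessMask)
  ind <- eventIndicator(events, n)
  binFrames <- .frames(binMin * 60, frameRateHz)
  nBins <- floor(n / binFrames)
  out <- data.frame(bin = seq_len(nBins))
  out$start_min <- (out$bin - 1) * binMin
  out$rate <- out$coverage <- NA_real_
  for (b in seq_len(nBins)) {
    idx <- ((b - 1) * binFrames + 1):(b * binFrames)
    still <- stillnessMask[idx]
    out$coverage[b] <- mean(still)
    if (sum(still) > 0)
      out$rate[b] <- sum(ind[idx][still]) / sum(still)
  }
  out$missing <- out$coverage < minCoverage | !is.finite(out$rate)
  out$rate[out$missing] <- NA_real_
  out
}

# Find qualifying runs in a logical vector with NA (missing) bins. Missing
# bins carry no evidence either way, so they never break a run: a run is
# delimited by non-missing bins that fail the criterion, and starts/ends on
# qualifying bins. Returns start index, span (bins, bridged gaps included)
# and the number of qualifying bins inside.
#' @noRd
.qualifyingRuns <- function(flag) {
  n <- length(flag)
  runs <- NULL
  i <- 1L
  while (i <= n) {
    if (isTRUE(flag[i])) {
      start <- i
      last <- i
      j <- i + 1L
      nq <- 1L
      while (j <= n) {
        if (isTRUE(flag[j])) {
          last <- j; nq <- nq + 1L
        } else if (!is.na(flag[j])) break
        j <- j + 1L
      }
      runs <- rbind(runs, data.frame(start = start, len = last - start + 1L,
                                     n_qualifying = nq))
      i <- last
    }
    i <- i + 1L
  }
  runs
}

#' Classify post-CSD change in ongoing activity
#'
#' Baseline mean and SD are taken over the usable pre-CSD bins. A post-CSD
#' bin is "elevated" when its rate exceeds mean + kSd x SD and "reduced" when
#' below max(0, mean - kSd x SD). An afferent is classified activated
#' (suppressed) when an elevated (reduced) run lasting more than `runMin`
#' minutes begins within `onsetWindowMin` minutes of the wave offset; its
#' latency is the run start relative to the wave offset and its duration the
#' run length (span). Missing bins (low stillness coverage) carry no evidence
#' and never break a run; a run is delimited by non-missing bins failing the
#' criterion and must contain at least `runMin/2` qualifying bins, so
#' locomotion gaps cannot truncate a sustained change nor stitch isolated
#' fluctuations together.
#'
#' @param preBins,postBins Binned-rate tables from [binOngoingRate()];
#'   `postBins` starts at the wave offset.
#' @param kSd Baseline-SD multiplier (default 2).
#' @param runMin Minimum run length in minutes, exclusive (default 10).
#' @param onsetWindowMin Onset window after the wave offset (default 30).
#' @param minBaselineBins Minimum usable baseline bins (default 15).
#' @return An `OngoingActivityProfile` list: `classification` ("activated",
#'   "suppressed" or "none"), `onset_latency_min`, `duration_min`,
#'   `baseline_mean`, `baseline_sd`, plus the two bin tables.
#' @export
classifyOngoingChange <- function(preBins, postBins, kSd = 2, runMin = 10,
                                  onsetWindowMin = 30, minBaselineBins = 15) {
  base <- preBins$rate[!preBins$missing]
  if (length(base) < minBaselineBins)
    stop(sprintf("only %d usable baseline bins; need %d", length(base),
                 minBaselineBins), call. = FALSE)
  m <- mean(base); s <- sd(base)
  binMin <- if (nrow(postBins) > 1) diff(postBins$start_min[1:2]) else 1
  up <- ifelse(postBins$missing, NA, postBins$rate > m + kSd * s)
  dn <- ifelse(postBins$missing, NA, postBins$rate < max(0, m - kSd * s))
  pick <- function(flag) {
    runs <- .qualifyingRuns(flag)
    if (is.null(runs)) return(NULL)
    runs$latency <- (runs$start - 1) * binMin
    runs$duration <- runs$len * binMin
    runs <- runs[runs$duration > runMin & runs$latency <= onsetWindowMin &
                   runs$n_qualifying >= ceiling(runMin / 2), , drop = FALSE]
    if (!nrow(runs)) NULL else runs[which.max(runs$duration), ]
  }
  actRun <- pick(up)
  supRun <- pick(dn)
  cls <- "none"; lat <- NA_real_; dur <- NA_real_
  best <- NULL
  if (!is.null(actRun)) { cls <- "activated"; best <- actRun }
  if (!is.null(supRun) && (is.null(best) || supRun$duration > best$duration)) {
    cls <- "suppressed"; best <- supRun
  }
  if (!is.null(best)) { lat <- best$latency; dur <- best$duration }
  structure(list(classification = cls, onset_latency_min = lat,
                 duration_min = dur, baseline_mean = m, baseline_sd = s,
                 pre_bins = preBins, post_bins = postBins),
            class = "OngoingActivityProfile")
}
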