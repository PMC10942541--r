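# Internal helpers shared across modules.

#' @noRd
.assertFinite <- function(x, name) {
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(TRUE)
}

# Maximal runs of TRUE in a logical vector; returns a data.frame with
# 1-based start/end indices (zero rows when there is no TRUE run).
#' @noRd
.trueRuns <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

# Causal exponential filter with unit DC gain, time constant tau (seconds).
#' @noRd
.expFilter <- function(x, tauS, rateHz) {
  a <- exp(-1 / (tauS * rateHz))
  y <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    acc <- a * acc + (1 - a) * x[i]
    y[i] <- acc
  }
  y
}

# Centered moving average with window w samples; the window shrinks at the
# edges so the output has no NA and the same length as the input.
#' @noRd
.movingAverage <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor((w - 1) / 2)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + (w - 1L - half))
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' @noRd
.frames <- function(seconds, rateHz) max(1L, as.integer(round(seconds * rateHz)))
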