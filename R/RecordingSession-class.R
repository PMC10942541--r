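#' RecordingSession: container for one imaging session
#'
#' Holds every per-session time series consumed by the analysis pipeline:
#' raw ROI fluorescence and the matching neuropil (background-mask) traces,
#' ROI centroid coordinates, the spatially binned background-fluorescence
#' movie, the wheel-position series, per-frame affine registration parameters
#' and Z-shifts, the CSD trigger frame (if a CSD was induced), and the
#' acquisition constants (volume rate, wheel sampling rate, field-of-view
#' size, pixel size).
#'
#' Conventions: frame \code{k} (0-based) is timestamped \code{k / frameRateHz}
#' seconds from acquisition start; wheel samples analogously at
#' \code{wheelRateHz}. Image coordinates are in micrometers with the origin at
#' the top-left corner of the field of view, x increasing laterally and y
#' increasing posteriorly (anterior maps to -y).
#'
#' @slot sessionId character identifier.
#' @slot frameRateHz volumes per second (default acquisition 1.03).
#' @slot wheelRateHz wheel encoder sampling rate in Hz (default 15.5).
#' @slot fovSizeUm numeric length-2, field-of-view width and height in um.
#' @slot pixelSizeUm micrometers per pixel.
#' @slot roiTraces numeric matrix [nRois x nFrames], raw ROI fluorescence.
#' @slot neuropilTraces numeric matrix [nRois x nFrames], background-mask
#'   fluorescence for each ROI.
#' @slot roiCentroidsUm numeric matrix [nRois x 2], planar ROI centroids (um).
#' @slot backgroundGrid numeric array [nBinsY x nBinsX x nFrames], mean
#'   background fluorescence in square spatial bins of \code{binSizePx} pixels.
#' @slot binSizePx side of a spatial bin in pixels (default 40).
#' @slot wheelPosition numeric, wheel encoder position at \code{wheelRateHz}.
#' @slot csdTriggerFrame integer frame of CSD induction, or NA if none.
#' @slot affineLinear numeric array [2 x 2 x nFrames], linear part of the
#'   per-frame affine registration correction (pixel units).
#' @slot affineTranslation numeric matrix [2 x nFrames], affine translation.
#' @slot zShiftUm numeric, per-frame Z-shift in um (positive toward skull).
#'
#' @seealso [readSession()], [writeSession()], [generateSession()]
#' @export
setClass("RecordingSession",
  representation(
    sessionId = "character",
    frameRateHz = "numeric",
    wheelRateHz = "numeric",
    fovSizeUm = "numeric",
    pixelSizeUm = "numeric",
    roiTraces = "matrix",
    neuropilTraces = "matrix",
    roiCentroidsUm = "matrix",
    backgroundGrid = "array",
    binSizePx = "integer",
    wheelPosition = "numeric",
    csdTriggerFrame = "integer",
    affineLinear = "array",
    affineTranslation = "matrix",
    zShiftUm = "numeric"
  )
)

setValidity("RecordingSession", function(object) {
  msg <- character(0)
  nf <- ncol(object@roiTraces)
  nr <- nrow(object@roiTraces)
  if (length(object@frameRateHz) != 1 || object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be a single positive number")
  if (length(object@wheelRateHz) != 1 || object@wheelRateHz <= 0)
    msg <- c(msg, "wheelRateHz must be a single positive number")
  if (length(object@fovSizeUm) != 2 || any(object@fovSizeUm <= 0))
    msg <- c(msg, "fovSizeUm must be two positive numbers (width, height)")
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!all(is.finite(object@roiTraces)))
    msg <- c(msg, "roiTraces contains non-finite values")
  if (!all(is.finite(object@neuropilTraces)))
    msg <- c(msg, "neuropilTraces contains non-finite values")
  if (!identical(dim(object@neuropilTraces), dim(object@roiTraces)))
    msg <- c(msg, sprintf(
      "neuropilTraces dimensions (%s) must match roiTraces (%s)",
      paste(dim(object@neuropilTraces), collapse = "x"),
      paste(dim(object@roiTraces), collapse = "x")))
  if (nrow(object@roiCentroidsUm) != nr || ncol(object@roiCentroidsUm) != 2)
    msg <- c(msg, "roiCentroidsUm must be an [nRois x 2] matrix")
  d <- dim(object@backgroundGrid)
  if (length(d) != 3) {
    msg <- c(msg, "backgroundGrid must be a 3-D array [nBinsY x nBinsX x nFrames]")
  } else {
    if (d[3] != nf)
      msg <- c(msg, sprintf("backgroundGrid has %d frames but roiTraces has %d", d[3], nf))
    fovPx <- object@fovSizeUm / object@pixelSizeUm
    expX <- max(1L, floor(fovPx[1] / object@binSizePx))
    expY <- max(1L, floor(fovPx[2] / object@binSizePx))
    if (d[1] != expY || d[2] != expX)
      msg <- c(msg, sprintf(
        "backgroundGrid is %dx%d bins but FOV/binSizePx implies %dx%d",
        d[1], d[2], expY, expX))
    if (!all(is.finite(object@backgroundGrid)))
      msg <- c(msg, "backgroundGrid contains non-finite values")
  }
  if (!all(is.finite(object@wheelPosition)))
    msg <- c(msg, "wheelPosition contains non-finite values")
  # durations must agree after rate conversion (within one frame period)
  durF <- nf / object@frameRateHz
  durW <- length(object@wheelPosition) / object@wheelRateHz
  if (abs(durF - durW) > 1 / object@frameRateHz + 1e-9)
    msg <- c(msg, sprintf(
      "wheel series duration (%.2f s) inconsistent with frame series (%.2f s)",
      durW, durF))
  if (!is.na(object@csdTriggerFrame) &&
      (object@csdTriggerFrame < 1L || object@csdTriggerFrame > nf))
    msg <- c(msg, "csdTriggerFrame outside the recorded frame range")
  if (!identical(dim(object@affineLinear), c(2L, 2L, as.integer(nf))))
    msg <- c(msg, "affineLinear must be a [2 x 2 x nFrames] array")
  else if (!all(is.finite(object@affineLinear)))
    msg <- c(msg, "affineLinear contains non-finite values")
  if (!identical(dim(object@affineTranslation), c(2L, as.integer(nf))))
    msg <- c(msg, "affineTranslation must be a [2 x nFrames] matrix")
  if (length(object@zShiftUm) != nf)
    msg <- c(msg, sprintf("zShiftUm has length %d but there are %d frames",
                          length(object@zShiftUm), nf))
  else if (!all(is.finite(object@zShiftUm)))
    msg <- c(msg, "zShiftUm contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a RecordingSession
#'
#' @param sessionId character identifier.
#' @param roiTraces,neuropilTraces numeric matrices [nRois x nFrames].
#' @param roiCentroidsUm numeric matrix [nRois x 2] in um.
#' @param backgroundGrid numeric array [nBinsY x nBinsX x nFrames].
#' @param wheelPosition wheel encoder series at `wheelRateHz`.
#' @param affineLinear array [2 x 2 x nFrames]; defaults to identity matrices.
#' @param affineTranslation matrix [2 x nFrames]; defaults to zeros.
#' @param zShiftUm per-frame Z-shift (um); defaults to zeros.
#' @param csdTriggerFrame 1-based frame of CSD induction or NA.
#' @param frameRateHz,wheelRateHz,fovSizeUm,pixelSizeUm,binSizePx acquisition
#'   constants; defaults match the study conditions (1.03 volumes/s, 15.5 Hz
#'   wheel sampling, 626 x 423 um FOV, 40-pixel bins).
#' @return A validated [RecordingSession-class] object.
#' @export
RecordingSession <- function(sessionId, roiTraces, neuropilTraces,
                             roiCentroidsUm, backgroundGrid, wheelPosition,
                             affineLinear = NULL, affineTranslation = NULL,
                             zShiftUm = NULL, csdTriggerFrame = NA_integer_,
                             frameRateHz = 1.03, wheelRateHz = 15.5,
                             fovSizeUm = c(626, 423),
                             pixelSizeUm = 626 / 512, binSizePx = 40L) {
  nf <- ncol(roiTraces)
  if (is.null(affineLinear))
    affineLinear <- array(rep(c(1, 0, 0, 1), nf), dim = c(2, 2, nf))
  if (is.null(affineTranslation))
    affineTranslation <- matrix(0, 2, nf)
  if (is.null(zShiftUm)) zShiftUm <- numeric(nf)
  new("RecordingSession",
      sessionId = as.character(sessionId),
      frameRateHz = as.numeric(frameRateHz),
      wheelRateHz = as.numeric(wheelRateHz),
      fovSizeUm = as.numeric(fovSizeUm),
      pixelSizeUm = as.numeric(pixelSizeUm),
      roiTraces = roiTraces,
      neuropilTraces = neuropilTraces,
      roiCentroidsUm = roiCentroidsUm,
      backgroundGrid = backgroundGrid,
      binSizePx = as.integer(binSizePx),
      wheelPosition = as.numeric(wheelPosition),
      csdTriggerFrame = as.integer(csdTriggerFrame),
      affineLinear = affineLinear,
      affineTranslation = affineTranslation,
      zShiftUm = as.numeric(zShiftUm))
}

setMethod("show", "RecordingSession", function(object) {
  nf <- ncol(object@roiTraces)
  cat("RecordingSession '", object@sessionId, "'\n", sep = "")
  cat(sprintf("  %d ROIs x %d frames (%.1f min at %.2f volumes/s)\n",
              nrow(object@roiTraces), nf, nf / object@frameRateHz / 60,
              object@frameRateHz))
  cat(sprintf("  FOV %.0f x %.0f um, background grid %d x %d bins (%d px)\n",
              object@fovSizeUm[1], object@fovSizeUm[2],
              dim(object@backgroundGrid)[1], dim(object@backgroundGrid)[2],
              object@binSizePx))
  if (is.na(object@csdTriggerFrame)) {
    cat("  no CSD trigger recorded\n")
  } else {
    cat(sprintf("  CSD trigger at frame %d (%.1f min)\n",
                object@csdTriggerFrame,
                (object@csdTriggerFrame - 1) / object@frameRateHz / 60))
  }
})

# ---- accessors -------------------------------------------------------------

#' Accessors for RecordingSession
#'
#' Read-only accessors for the slots of a [RecordingSession-class].
#' @param session A [RecordingSession-class] object.
#' @return The corresponding slot value.
#' @name session-accessors
NULL

#' @rdname session-accessors
#' @export
sessionId <- function(session) session@sessionId
#' @rdname session-accessors
#' @export
frameRate <- function(session) session@frameRateHz
#' @rdname session-accessors
#' @export
wheelRate <- function(session) session@wheelRateHz
#' @rdname session-accessors
#' @export
nFrames <- function(session) ncol(session@roiTraces)
#' @rdname session-accessors
#' @export
nRois <- function(session) nrow(session@roiTraces)
#' @rdname session-accessors
#' @export
roiTraces <- function(session) session@roiTraces
#' @rdname session-accessors
#' @export
neuropilTraces <- function(session) session@neuropilTraces
#' @rdname session-accessors
#' @export
roiCentroids <- function(session) session@roiCentroidsUm
#' @rdname session-accessors
#' @export
backgroundGrid <- function(session) session@backgroundGrid
#' @rdname session-accessors
#' @export
wheelPosition <- function(session) session@wheelPosition
#' @rdname session-accessors
#' @export
csdTriggerFrame <- function(session) session@csdTriggerFrame
#' @rdname session-accessors
#' @export
affineLinear <- function(session) session@affineLinear
#' @rdname session-accessors
#' @export
affineTranslation <- function(session) session@affineTranslation
#' @rdname session-accessors
#' @export
zShift <- function(session) session@zShiftUm
#' @rdname session-accessors
#' @export
fovSize <- function(session) session@fovSizeUm
#' @rdname session-accessors
#' @export
pixelSize <- function(session) session@pixelSizeUm
#' @rdname session-accessors
#' @export
binSize <- function(session) session@binSizePx

#' Spatial-bin centers of the background grid
#'
#' @param session A [RecordingSession-class].
#' @return A data.frame with columns `row`, `col`, `x_um`, `y_um` giving the
#'   center of every background-grid bin in image coordinates.
#' @export
binCenters <- function(session) {
  d <- dim(session@backgroundGrid)
  stepUm <- session@binSizePx * session@pixelSizeUm
  g <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  g$x_um <- (g$col - 0.5) * stepUm
  g$y_um <- (g$row - 0.5) * stepUm
  g
}
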