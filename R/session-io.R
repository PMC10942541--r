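# HDF5 container for RecordingSession objects.
#
# Layout (schema 1.0):
#   /traces/roi, /traces/neuropil, /traces/roi_centroids_um
#   /background/grid, /background/bin_size_px
#   /behavior/wheel_position
#   /registration/affine_linear, /registration/affine_translation,
#   /registration/zshift_um
#   /meta/{session_id, frame_rate_hz, wheel_rate_hz, fov_size_um,
#          pixel_size_um, csd_trigger_frame (absent if none), schema_version}

.SCHEMA_VERSION <- "1.0"

#' Write a RecordingSession to an HDF5 container
#'
#' All arrays are stored uncompressed in a fixed group layout so that two
#' writes of the same session produce identical dataset payloads.
#'
#' @param session A validated [RecordingSession-class].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "RecordingSession"))
  validObject(session)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (g in c("traces", "background", "behavior", "registration", "meta"))
    rhdf5::h5createGroup(path, g)
  w <- function(obj, name) rhdf5::h5write(obj, path, name)
  w(session@roiTraces, "traces/roi")
  w(session@neuropilTraces, "traces/neuropil")
  w(session@roiCentroidsUm, "traces/roi_centroids_um")
  w(session@backgroundGrid, "background/grid")
  w(session@binSizePx, "background/bin_size_px")
  w(session@wheelPosition, "behavior/wheel_position")
  w(session@affineLinear, "registration/affine_linear")
  w(session@affineTranslation, "registration/affine_translation")
  w(session@zShiftUm, "registration/zshift_um")
  w(session@sessionId, "meta/session_id")
  w(session@frameRateHz, "meta/frame_rate_hz")
  w(session@wheelRateHz, "meta/wheel_rate_hz")
  w(session@fovSizeUm, "meta/fov_size_um")
  w(session@pixelSizeUm, "meta/pixel_size_um")
  if (!is.na(session@csdTriggerFrame))
    w(session@csdTriggerFrame, "meta/csd_trigger_frame")
  w(.SCHEMA_VERSION, "meta/schema_version")
  invisible(path)
}

#' Read a RecordingSession from an HDF5 container
#'
#' The loaded object is passed through the full class validity check, so a
#' file whose arrays are inconsistent (mismatched lengths, non-finite values)
#' is rejected with a descriptive error rather than silently returned.
#'
#' @param path Path to a file written by [writeSession()].
#' @return A validated [RecordingSession-class].
#' @export
readSession <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (!rhdf5::H5Fis_hdf5(path))
    stop("not an HDF5 session container: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  present <- rhdf5::h5ls(path)
  have <- file.path(present$group, present$name)
  need <- c("/traces/roi", "/traces/neuropil", "/traces/roi_centroids_um",
            "/background/grid", "/background/bin_size_px",
            "/behavior/wheel_position", "/registration/affine_linear",
            "/registration/affine_translation", "/registration/zshift_um",
            "/meta/session_id", "/meta/frame_rate_hz", "/meta/wheel_rate_hz",
            "/meta/fov_size_um", "/meta/pixel_size_um", "/meta/schema_version")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("session container is missing datasets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  r <- function(name) rhdf5::h5read(path, name)
  trig <- if ("/meta/csd_trigger_frame" %in% have)
    as.integer(r("meta/csd_trigger_frame")) else NA_integer_
  RecordingSession(
    sessionId = as.character(r("meta/session_id")),
    roiTraces = as.matrix(r("traces/roi")),
    neuropilTraces = as.matrix(r("traces/neuropil")),
    roiCentroidsUm = as.matrix(r("traces/roi_centroids_um")),
    backgroundGrid = r("background/grid"),
    wheelPosition = as.numeric(r("behavior/wheel_position")),
    affineLinear = r("registration/affine_linear"),
    affineTranslation = as.matrix(r("registration/affine_translation")),
    zShiftUm = as.numeric(r("registration/zshift_um")),
    csdTriggerFrame = trig,
    frameRateHz = as.numeric(r("meta/frame_rate_hz")),
    wheelRateHz = as.numeric(r("meta/wheel_rate_hz")),
    fovSizeUm = as.numeric(r("meta/fov_size_um")),
    pixelSizeUm = as.numeric(r("meta/pixel_size_um")),
    binSizePx = as.integer(r("background/bin_size_px")))
}

#' Export session traces as CSV
#'
#' Writes the ROI and neuropil trace matrices (one row per ROI, one column
#' per frame) to plain CSV files for inspection outside R.
#'
#' @param session A [RecordingSession-class].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
exportTracesCsv <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "roi_traces.csv")
  p2 <- file.path(dir, "neuropil_traces.csv")
  write.csv(session@roiTraces, p1, row.names = FALSE)
  write.csv(session@neuropilTraces, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
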