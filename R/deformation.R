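# Meningeal deformation series from per-frame affine registration parameters.

#' Scale and shear from affine registration matrices
#'
#' Decomposes the 2x2 linear part A of each frame's affine correction via its
#' singular values s1 >= s2 (a rotation-invariant split): isotropic stretch
#' sqrt(s1*s2) - 1 captures expansion (+) / compression (-), and the
#' anisotropic part (s1 - s2)/2 captures shearing. Scale is converted to
#' micrometers as the displacement of a field-of-view corner under pure
#' isotropic stretch, i.e. multiplied by half the FOV diagonal; shear is
#' returned both dimensionless and in the same um reference.
#'
#' Singular matrices are flagged invalid and linearly interpolated from
#' neighboring frames.
#'
#' @param affineLinear Array [2 x 2 x nFrames] of linear affine parts.
#' @param fovSizeUm Field-of-view width and height in um.
#' @return A data.frame with columns `scale_um`, `shear`, `shear_um`,
#'   `valid`.
#' @export
decomposeAffine <- function(affineLinear, fovSizeUm) {
  stopifnot(length(dim(affineLinear)) == 3, all(dim(affineLinear)[1:2] == 2))
  n <- dim(affineLinear)[3]
  rRef <- sqrt(sum((fovSizeUm / 2)^2))
  iso <- shear <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    A <- affineLinear[, , i]
    if (!all(is.finite(A)) || abs(det(A)) < 1e-12) {
      valid[i] <- FALSE
      next
    }
    s <- svd(A, nu = 0, nv = 0)$d        # s[1] >= s[2] >= 0
    iso[i] <- sqrt(s[1] * s[2]) - 1
    shear[i] <- (s[1] - s[2]) / 2
  }
  if (!all(valid)) {
    if (!any(valid)) stop("all affine matrices are singular", call. = FALSE)
    idx <- which(valid)
    iso <- approx(idx, iso[idx], xout = seq_len(n), rule = 2)$y
    shear <- approx(idx, shear[idx], xout = seq_len(n), rule = 2)$y
  }
  data.frame(scale_um = iso * rRef, shear = shear, shear_um = shear * rRef,
             valid = valid)
}

#' Z-shift in micrometers
#'
#' Converts per-frame plane shifts (in imaging planes) to micrometers.
#' Positive values indicate meningeal movement toward the skull.
#'
#' @param zCorrections Per-frame plane shifts (planes, signed).
#' @param planeSpacingUm Spacing between imaging planes in um.
#' @return Z-shift series in um.
#' @export
zshiftUm <- function(zCorrections, planeSpacingUm) {
  if (planeSpacingUm <= 0) stop("planeSpacingUm must be positive", call. = FALSE)
  as.numeric(zCorrections) * planeSpacingUm
}

#' Deformation series for a session
#'
#' @param session A [RecordingSession-class].
#' @return A `DeformationSeries` list with `scale` (um), `shear`
#'   (dimensionless), `shear_um`, and `zshift` (um) series at the frame rate.
#' @export
deformationSeries <- function(session) {
  d <- decomposeAffine(affineLinear(session), fovSize(session))
  structure(list(scale = d$scale_um, shear = d$shear, shear_um = d$shear_um,
                 zshift = zShift(session)),
            class = "DeformationSeries")
}
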