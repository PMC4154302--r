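# Orientation and scale calibration.
#
# Reconstructions come out at arbitrary orientation; the gait frame is
# defined by (1) rotating an identified vertical direction onto +Z, then
# (2) rotating about +Z until the direction of locomotion lies along +X.
# The coordinate system is right-handed, so +Y then points to the left-hand
# side of an animal travelling along +X. Scale comes either from a known
# in-scene length or from the tape-measured camera separations.

#' Minimal rotation taking a direction to +Z
#'
#' @param v non-zero 3-vector (the identified vertical, e.g. a fitted pole
#'   direction).
#' @return \code{similarity_transform} (rotation only) with
#'   \eqn{R \hat v = (0,0,1)}. Antiparallel input (\code{v} along -Z) maps
#'   to the declared convention of a 180-degree rotation about +X.
#' @export
rotation_to_vertical <- function(v) {
  vhat <- unit(as.numeric(v))
  z <- c(0, 0, 1)
  c_ <- sum(vhat * z)
  if (c_ > 1 - 1e-15) return(similarity_transform())
  if (c_ < -1 + 1e-15)
    return(similarity_transform(R = diag(c(1, -1, -1))))  # 180 deg about +X
  axis <- c(vhat[2L] * z[3L] - vhat[3L] * z[2L],
            vhat[3L] * z[1L] - vhat[1L] * z[3L],
            vhat[1L] * z[2L] - vhat[2L] * z[1L])
  similarity_transform(R = rotation_about_axis(axis, acos(c_)))
}

#' Rotation about +Z taking a horizontal direction to +X
#'
#' @param d 3-vector whose horizontal component (d_x, d_y) is non-zero.
#' @return \code{similarity_transform} (rotation only) rotating about +Z by
#'   \code{-atan2(d_y, d_x)}: the rotated \code{d} has zero Y component and
#'   positive X component; Z components are untouched.
#' @export
rotation_about_z_to_x <- function(d) {
  d <- as.numeric(d)
  if (sqrt(d[1L]^2 + d[2L]^2) < 1e-12)
    cg_stop("degenerate_input_error",
            "direction is purely vertical; no horizontal component to align")
  a <- -atan2(d[2L], d[1L])
  ca <- cos(a); sa <- sin(a)
  similarity_transform(R = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L))
}

#' Orient a cloud into the gait frame
#'
#' Fits a line to \code{vertical_sel}, rotates that direction onto +Z, then
#' fits a line to \code{travel} (evaluated after the first rotation) and
#' rotates about +Z until it lies along +X. Line fits are sign-ambiguous
#' and a static travel feature (a rope, a wall edge) carries no motion
#' direction, so optional \code{up_hint} / \code{forward_hint} vectors (in
#' the original cloud coordinates) resolve the two signs; without hints the
#' \code{\link{fit_line}} selection-order convention decides.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param vertical_sel \code{\link{selection}} covering a vertical feature.
#' @param travel \code{\link{selection}} covering a feature along the
#'   direction of locomotion, or a 3-vector giving that direction directly.
#' @param up_hint optional 3-vector roughly along the scene's up direction.
#' @param forward_hint optional 3-vector roughly along the direction of
#'   motion.
#' @return \code{similarity_transform} (rotation only, s = 1, t = 0)
#'   composing both rotations.
#' @export
orient_cloud <- function(cloud, vertical_sel, travel,
                         up_hint = NULL, forward_hint = NULL) {
  vdir <- fit_line(cloud, vertical_sel)$direction
  if (!is.null(up_hint) && sum(vdir * up_hint) < 0) vdir <- -vdir
  T1 <- rotation_to_vertical(vdir)

  tdir <- if (inherits(travel, "selection")) {
    fit_line(apply_transform(cloud, T1), travel)$direction
  } else {
    as.numeric(T1$R %*% as.numeric(travel))
  }
  if (!is.null(forward_hint)) {
    fh <- as.numeric(T1$R %*% as.numeric(forward_hint))
    if (tdir[1L] * fh[1L] + tdir[2L] * fh[2L] < 0) tdir <- -tdir
  }
  T2 <- rotation_about_z_to_x(tdir)
  compose_transform(T2, T1)
}

#' Scale factor from a known in-scene length
#'
#' The easiest calibration: measure a known distance within the point cloud
#' and take the ratio. The clouds are undistorted, so a single uniform
#' scale factor is all that is required.
#'
#' @param p1,p2 endpoints of the measured feature, in cloud units.
#' @param true_length its physical length in metres.
#' @return scale factor s (metres per cloud unit).
#' @export
scale_from_known_distance <- function(p1, p2, true_length) {
  d <- vnorm(as.numeric(p1) - as.numeric(p2))
  if (d < 1e-15) cg_stop("degenerate_input_error", "calibration points coincide")
  if (!is_number(true_length) || true_length <= 0)
    cg_stop("invalid_input_error", "true_length must be > 0")
  true_length / d
}

#' Scale factor from camera separations
#'
#' Bundle adjustment outputs the camera poses, so the in-cloud separations
#' of adjacent cameras can be compared with their tape-measured physical
#' spacings: s = mean(physical separations) / mean(cloud separations).
#' The ratio of means matches calibrating with the mean camera separation;
#' unregistered cameras are excluded before pairing.
#'
#' @param cams a \code{bundler_cameras} object from
#'   \code{\link{read_bundler}}.
#' @param physical_separations metres, one entry per adjacent pair of
#'   registered cameras, in camera order.
#' @return scale factor s (metres per cloud unit).
#' @export
scale_from_camera_separation <- function(cams, physical_separations) {
  seps <- camera_separations(cams)
  physical_separations <- as.numeric(physical_separations)
  if (length(physical_separations) != length(seps))
    cg_stop("input_error",
            "%d physical separations supplied for %d adjacent camera pairs",
            length(physical_separations), length(seps))
  if (any(physical_separations <= 0))
    cg_stop("input_error", "physical separations must be > 0")
  mean(physical_separations) / mean(seps)
}
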