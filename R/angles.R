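# Projected segment angles and travel-direction realignment.
#
# A limb segment between two markers is characterised by projecting its
# vector into the three coordinate planes X = 0, Y = 0 and Z = 0 and
# measuring the in-plane angle. Sign conventions (the atan2 argument order
# below) are declared here once: with u = b - a,
#   theta_X = atan2(u_y, u_z)  -- front view, deviation from vertical,
#                                 positive toward +Y;
#   theta_Y = atan2(u_x, u_z)  -- sagittal view, deviation from vertical,
#                                 positive toward +X;
#   theta_Z = atan2(u_y, u_x)  -- plan view, measured from +X toward +Y.
# Angles are reported in degrees in (-180, 180]; a projection is flagged
# undefined when the in-plane component is negligible relative to |u|.

#' Projected segment angles between two markers
#'
#' @param marker_a,marker_b \code{\link{marker_series}} for the segment's
#'   proximal and distal ends; the segment vector is \code{b - a} per
#'   common valid frame.
#' @param degrees report degrees (default) or radians.
#' @return object of class \code{segment_angles}: list with \code{frames},
#'   \code{theta_x}, \code{theta_y}, \code{theta_z} and logical
#'   \code{valid_x/y/z} flags (FALSE where the projection is undefined or a
#'   marker is missing).
#' @export
projected_segment_angles <- function(marker_a, marker_b, degrees = TRUE) {
  common <- intersect(marker_a$frames[marker_a$valid],
                      marker_b$frames[marker_b$valid])
  if (length(common) == 0L)
    cg_stop("empty_overlap_error", "markers share no common valid frames")
  frames <- sort(unique(c(marker_a$frames, marker_b$frames)))
  ia <- match(frames, marker_a$frames)
  ib <- match(frames, marker_b$frames)
  both <- frames %in% common
  u <- matrix(NA_real_, length(frames), 3L)
  u[both, ] <- marker_b$positions[ib[both], , drop = FALSE] -
    marker_a$positions[ia[both], , drop = FALSE]

  nu <- sqrt(rowSums(u^2))
  tol <- 1e-9 * nu
  in_x <- sqrt(u[, 2L]^2 + u[, 3L]^2)   # projection into X = 0
  in_y <- sqrt(u[, 1L]^2 + u[, 3L]^2)   # projection into Y = 0
  in_z <- sqrt(u[, 1L]^2 + u[, 2L]^2)   # projection into Z = 0
  k <- if (degrees) 180 / pi else 1
  structure(list(
    frames = frames,
    theta_x = k * atan2(u[, 2L], u[, 3L]),
    theta_y = k * atan2(u[, 1L], u[, 3L]),
    theta_z = k * atan2(u[, 2L], u[, 1L]),
    valid_x = both & is.finite(in_x) & in_x >= tol,
    valid_y = both & is.finite(in_y) & in_y >= tol,
    valid_z = both & is.finite(in_z) & in_z >= tol,
    degrees = degrees),
    class = "segment_angles")
}

#' @export
print.segment_angles <- function(x, ...) {
  cat(sprintf("<segment_angles> %d frames (%s); defined: X %d, Y %d, Z %d\n",
              length(x$frames), if (x$degrees) "degrees" else "radians",
              sum(x$valid_x), sum(x$valid_y), sum(x$valid_z)))
  invisible(x)
}

#' Realign marker series to the direction of travel
#'
#' When the scene's +X axis was set from a convenient static feature rather
#' than the subject's path, the analysis frame is recovered by fitting a
#' line (total least squares) to the sequential (x, y) positions of a
#' reference marker -- the head -- and rotating all measurements about the
#' +Z axis until that fitted line is parallel to +X with motion toward +X.
#' Z values are unchanged.
#'
#' @param series_set list of \code{\link{marker_series}} to rotate.
#' @param reference \code{\link{marker_series}} whose ground track defines
#'   the travel direction (>= 2 valid frames, horizontal displacement above
#'   \code{tol}).
#' @param tol minimum horizontal displacement (default 1e-9).
#' @return list(series = rotated series set, rotation = the
#'   \code{\link{similarity_transform}} applied, angle = rotation about +Z
#'   in radians).
#' @export
align_to_travel_direction <- function(series_set, reference, tol = 1e-9) {
  ok <- reference$valid
  if (sum(ok) < 2L)
    cg_stop("degenerate_input_error", "reference needs at least 2 valid frames")
  xy <- reference$positions[ok, 1:2, drop = FALSE]
  span <- xy[nrow(xy), ] - xy[1L, ]
  if (sqrt(sum(span^2)) <= tol)
    cg_stop("degenerate_input_error", "reference marker is stationary in the horizontal plane")
  ctr <- colMeans(xy)
  X <- sweep(xy, 2L, ctr)
  e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  dir <- e$vectors[, 1L]
  if (sum(dir * span) < 0) dir <- -dir   # motion toward +X
  T <- rotation_about_z_to_x(c(dir, 0))
  rotated <- lapply(series_set, apply_transform, T = T)
  list(series = rotated, rotation = T, angle = -atan2(dir[2L], dir[1L]))
}
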