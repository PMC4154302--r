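#' Construct a point cloud
#'
#' A point cloud is the per-frame unit of a photogrammetric reconstruction:
#' an unordered set of 3D surface points, optionally carrying per-point RGB
#' colour and unit normals (dense multi-view stereo tools such as PMVS emit
#' both). Coordinates are in arbitrary reconstruction units until a
#' similarity transform carries them into the metre-scaled gait frame.
#'
#' @param points numeric n x 3 matrix of coordinates (or a length-3 vector
#'   for a single point).
#' @param colours optional integer n x 3 matrix of RGB values in 0--255.
#' @param normals optional numeric n x 3 matrix of unit (or zero) normals.
#' @param units one of \code{"uncalibrated"} or \code{"metres"}.
#' @param frame_index non-negative integer frame number within a sequence.
#' @return an object of class \code{point_cloud}.
#' @export
point_cloud <- function(points, colours = NULL, normals = NULL,
                        units = c("uncalibrated", "metres"),
                        frame_index = 0L) {
  units <- match.arg(units)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) cg_stop("invalid_cloud_error", "points must be n x 3")
  if (nrow(points) < 1L) cg_stop("invalid_cloud_error", "a point cloud needs at least one point")
  if (!all(is.finite(points))) cg_stop("invalid_cloud_error", "non-finite coordinates in point cloud")
  if (!is.null(colours)) {
    colours <- as.matrix(colours)
    storage.mode(colours) <- "integer"
    if (!identical(dim(colours), dim(points)))
      cg_stop("invalid_cloud_error", "colours must match point count")
    if (any(colours < 0L | colours > 255L))
      cg_stop("invalid_cloud_error", "colours must lie in 0..255")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!identical(dim(normals), dim(points)))
      cg_stop("invalid_cloud_error", "normals must match point count")
    len <- sqrt(rowSums(normals^2))
    # PMVS occasionally emits all-zero normals for unoriented patches.
    if (any(len > 1e-9 & abs(len - 1) > 1e-3))
      cg_stop("invalid_cloud_error", "normals must be unit length or zero")
  }
  structure(
    list(points = points, colours = colours, normals = normals,
         units = units, frame_index = as.integer(frame_index)),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (%s)%s%s, frame %d\n",
              nrow(x$points), x$units,
              if (!is.null(x$colours)) ", colours" else "",
              if (!is.null(x$normals)) ", normals" else "",
              x$frame_index))
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$points)

#' Exact rational frame rate
#'
#' Video frame rates in the NTSC family are rationals (30000/1001,
#' 60000/1001); storing numerator and denominator exactly avoids timestamp
#' drift over long clips. The presets \code{"30p"} and \code{"60p"} name
#' those two rates.
#'
#' @param num numerator (frames) or a preset name.
#' @param den denominator (seconds).
#' @return object of class \code{frame_rate} with fields \code{num},
#'   \code{den} and convenience \code{fps}.
#' @examples
#' frame_rate("60p")            # 60000/1001
#' frame_rate(50)               # exactly 50 fps
#' @export
frame_rate <- function(num, den = 1L) {
  if (is.character(num)) {
    num <- switch(num,
      "30p" = { den <- 1001L; 30000L },
      "60p" = { den <- 1001L; 60000L },
      cg_stop("invalid_frame_rate_error", "unknown frame-rate preset '%s'", num)
    )
  }
  num <- as.integer(num); den <- as.integer(den)
  if (is.na(num) || is.na(den) || num <= 0L || den <= 0L)
    cg_stop("invalid_frame_rate_error", "frame rate numerator and denominator must be positive integers")
  structure(list(num = num, den = den, fps = num / den), class = "frame_rate")
}

#' @export
print.frame_rate <- function(x, ...) {
  cat(sprintf("<frame_rate> %d/%d (%.6f fps)\n", x$num, x$den, x$fps))
  invisible(x)
}

# Seconds per frame as an exact double ratio den/num.
frame_dt <- function(rate) rate$den / rate$num

frame_times <- function(rate, frame_indices, start_frame = 0L) {
  (as.numeric(frame_indices) + as.numeric(start_frame)) * rate$den / rate$num
}

#' Construct a cloud sequence
#'
#' An ordered, frame-rate-aware sequence of point clouds. Frame indices may
#' have gaps (frames where reconstruction failed); gaps are recorded, never
#' silently renumbered.
#'
#' @param frames list of \code{point_cloud} objects with strictly increasing
#'   \code{frame_index}.
#' @param rate a \code{\link{frame_rate}}.
#' @param start_frame integer offset added to frame indices when computing
#'   timestamps.
#' @return object of class \code{cloud_sequence}; \code{$missing} lists frame
#'   numbers absent from the covered range.
#' @export
cloud_sequence <- function(frames, rate, start_frame = 0L) {
  if (!inherits(rate, "frame_rate")) cg_stop("invalid_frame_rate_error", "rate must be a frame_rate")
  if (length(frames) < 1L) cg_stop("empty_sequence_error", "a cloud sequence needs at least one frame")
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (any(diff(idx) <= 0L))
    cg_stop("invalid_sequence_error", "frame indices must be strictly increasing")
  covered <- seq.int(idx[1L], idx[length(idx)])
  structure(
    list(frames = frames, frame_rate = rate,
         start_frame = as.integer(start_frame),
         frame_indices = idx,
         missing = setdiff(covered, idx)),
    class = "cloud_sequence"
  )
}

#' @export
print.cloud_sequence <- function(x, ...) {
  cat(sprintf("<cloud_sequence> %d frames [%d..%d], %d/%d fps, %d missing\n",
              length(x$frames), x$frame_indices[1L],
              x$frame_indices[length(x$frame_indices)],
              x$frame_rate$num, x$frame_rate$den, length(x$missing)))
  invisible(x)
}

#' @export
length.cloud_sequence <- function(x) length(x$frames)

#' Timestamps of a cloud sequence
#'
#' @param seq a \code{cloud_sequence}.
#' @return numeric vector of seconds, one per stored frame, computed from the
#'   exact rational frame rate: \code{t_i = (start_frame + index_i) * den/num}.
#' @export
sequence_times <- function(seq) {
  frame_times(seq$frame_rate, seq$frame_indices, seq$start_frame)
}
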