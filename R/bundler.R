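# Bundler bundle.out camera calibration files (v0.3 layout).
#
# Structure-from-motion outputs the pose of every camera; the optical
# centres derived from those poses give the in-cloud camera separations
# used for scale calibration. Layout: optional "# Bundle file v0.3" comment,
# then <num_cameras num_points>, then per camera: <f k1 k2>, three rows of
# the world-to-camera rotation R, one row of the translation t. A camera
# with f = 0 is unregistered (bundle adjustment failed to place it).

#' Read a Bundler bundle.out file
#'
#' Parses camera intrinsics (focal length in pixels, two radial distortion
#' coefficients) and extrinsics (R, t), and derives each optical centre
#' \eqn{c = -R^T t}, the point satisfying \eqn{R c + t = 0}. Cameras with
#' \code{f = 0} are flagged unregistered and excluded from calibration
#' computations. A rotation that is not orthonormal to 1e-6 raises a
#' warning and flags the pose suspect.
#'
#' @param path path to a \code{bundle.out} file.
#' @return object of class \code{bundler_cameras}: list with
#'   \code{cameras} (each a \code{camera_pose} with fields \code{focal},
#'   \code{k1}, \code{k2}, \code{R}, \code{t}, \code{centre},
#'   \code{registered}, \code{suspect}) and \code{n_points} (sparse point
#'   count declared in the header).
#' @export
read_bundler <- function(path) {
  if (!file.exists(path)) cg_stop("io_error", "Bundler file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  tok <- scan(text = lines, what = numeric(), quiet = TRUE)
  if (length(tok) < 2L)
    cg_stop("bundler_parse_error", "%s: missing camera/point counts", path)
  n_cam <- as.integer(tok[1L]); n_pts <- as.integer(tok[2L])
  need <- 2L + 15L * n_cam
  if (length(tok) < need)
    cg_stop("bundler_parse_error",
            "%s: truncated at camera %d (expected %d values, found %d)",
            path, (length(tok) - 2L) %/% 15L + 1L, need, length(tok))
  cameras <- vector("list", n_cam)
  for (i in seq_len(n_cam)) {
    v <- tok[2L + (i - 1L) * 15L + seq_len(15L)]
    R <- matrix(v[4:12], nrow = 3L, byrow = TRUE)
    t <- v[13:15]
    registered <- v[1L] != 0
    suspect <- FALSE
    centre <- c(NA_real_, NA_real_, NA_real_)
    if (registered) {
      orth_err <- max(abs(crossprod(R) - diag(3)))
      if (orth_err > 1e-6 || det(R) <= 0) {
        cg_warn("bundler_suspect_pose_warning",
                "camera %d: rotation not orthonormal (max deviation %.2e); pose flagged suspect",
                i, orth_err)
        suspect <- TRUE
      }
      centre <- as.numeric(-crossprod(R, t))
    }
    cameras[[i]] <- structure(
      list(focal = v[1L], k1 = v[2L], k2 = v[3L], R = R, t = t,
           centre = centre, registered = registered, suspect = suspect),
      class = "camera_pose")
  }
  structure(list(cameras = cameras, n_points = n_pts),
            class = "bundler_cameras")
}

#' @export
print.bundler_cameras <- function(x, ...) {
  reg <- sum(vapply(x$cameras, `[[`, TRUE, "registered"))
  cat(sprintf("<bundler_cameras> %d cameras (%d registered), %d sparse points\n",
              length(x$cameras), reg, x$n_points))
  invisible(x)
}

#' Camera optical centres
#'
#' @param cams a \code{bundler_cameras} object (or list of camera poses).
#' @param registered_only drop unregistered (f = 0) cameras (default TRUE).
#' @return numeric n x 3 matrix of optical centres, in cloud units,
#'   in camera order.
#' @export
camera_centres <- function(cams, registered_only = TRUE) {
  poses <- if (inherits(cams, "bundler_cameras")) cams$cameras else cams
  if (registered_only)
    poses <- Filter(function(p) p$registered, poses)
  if (length(poses) == 0L)
    return(matrix(numeric(), ncol = 3L))
  do.call(rbind, lapply(poses, `[[`, "centre"))
}

#' Adjacent camera separations in cloud units
#'
#' Distances between optical centres of consecutive registered cameras, the
#' in-cloud counterpart of the tape-measured physical spacings.
#'
#' @inheritParams camera_centres
#' @return numeric vector of length (registered cameras - 1).
#' @export
camera_separations <- function(cams) {
  ctr <- camera_centres(cams, registered_only = TRUE)
  if (nrow(ctr) < 2L)
    cg_stop("insufficient_cameras_error",
            "need at least 2 registered cameras, have %d", nrow(ctr))
  sqrt(rowSums((ctr[-1L, , drop = FALSE] - ctr[-nrow(ctr), , drop = FALSE])^2))
}

# Writer used by the synthetic rig generator: exact v0.3 layout, full
# double precision so centre recovery is limited only by arithmetic.
write_bundler <- function(cameras, path, n_points = 0L) {
  lines <- c("# Bundle file v0.3",
             sprintf("%d %d", length(cameras), n_points))
  for (cam in cameras) {
    lines <- c(lines,
               paste(fmt_full(c(cam$focal, cam$k1, cam$k2)), collapse = " "),
               paste(fmt_full(cam$R[1L, ]), collapse = " "),
               paste(fmt_full(cam$R[2L, ]), collapse = " "),
               paste(fmt_full(cam$R[3L, ]), collapse = " "),
               paste(fmt_full(cam$t), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
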