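# Similarity transforms: rotation + translation + uniform scale.
#
# Photogrammetric reconstructions come out at arbitrary orientation and
# scale; because the clouds are undistorted, a single similarity transform
# x -> s R x + t is all that is needed to carry them into the oriented,
# metre-scaled gait frame.

#' Construct a similarity transform
#'
#' Application rule: \eqn{x \mapsto s R x + t}.
#'
#' @param R 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (target units).
#' @param s uniform scale factor > 0 (target units per source unit).
#' @return object of class \code{similarity_transform}.
#' @export
similarity_transform <- function(R = diag(3), t = c(0, 0, 0), s = 1) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(3L, 3L)))
    cg_stop("invalid_transform_error", "R must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    cg_stop("invalid_transform_error", "R must be a proper rotation (orthonormal, det +1)")
  if (!is_number(s) || s <= 0)
    cg_stop("invalid_transform_error", "scale s must be a positive number")
  t <- as.numeric(t)
  if (length(t) != 3L || !all(is.finite(t)))
    cg_stop("invalid_transform_error", "t must be a finite 3-vector")
  structure(list(R = R, t = t, s = s), class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- rotation_angle(x$R) * 180 / pi
  cat(sprintf("<similarity_transform> rotation %.3f deg, |t| = %.4g, s = %.9g\n",
              ang, vnorm(x$t), x$s))
  invisible(x)
}

#' Compose two similarity transforms
#'
#' \code{compose_transform(T2, T1)} applies \code{T1} first, then \code{T2}
#' (matrix-composition order).
#'
#' @param T2,T1 \code{similarity_transform} objects.
#' @return their composition as a \code{similarity_transform}.
#' @export
compose_transform <- function(T2, T1) {
  similarity_transform(R = T2$R %*% T1$R,
                       t = as.numeric(T2$s * T2$R %*% T1$t + T2$t),
                       s = T2$s * T1$s)
}

#' Invert a similarity transform
#'
#' @param T a \code{similarity_transform}.
#' @return the transform U with \code{apply_transform(apply_transform(x, T), U) = x}.
#' @export
invert_transform <- function(T) {
  Rt <- t(T$R)
  similarity_transform(R = Rt, t = as.numeric(-(1 / T$s) * Rt %*% T$t),
                       s = 1 / T$s)
}

#' Apply a similarity transform
#'
#' Maps every point \eqn{x \mapsto s R x + t}. Normals are rotated only
#' (unit length is scale-invariant); colours are untouched.
#'
#' @param x a \code{point_cloud}, \code{cloud_sequence}, n x 3 matrix, or
#'   length-3 vector.
#' @param T a \code{similarity_transform}.
#' @param units optional units flag to stamp on transformed clouds (e.g.
#'   \code{"metres"} once \code{s} is calibrated).
#' @return transformed copy of \code{x}.
#' @export
apply_transform <- function(x, T, units = NULL) {
  if (!inherits(T, "similarity_transform"))
    cg_stop("invalid_transform_error", "T must be a similarity_transform")
  if (inherits(x, "cloud_sequence")) {
    x$frames <- lapply(x$frames, apply_transform, T = T, units = units)
    return(x)
  }
  if (inherits(x, "point_cloud")) {
    x$points <- x$points %*% (T$s * t(T$R)) +
      matrix(T$t, nrow(x$points), 3L, byrow = TRUE)
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(T$R)
    if (!is.null(units)) x$units <- units
    return(x)
  }
  if (inherits(x, "marker_series")) {
    ok <- x$valid
    x$positions[ok, ] <- x$positions[ok, , drop = FALSE] %*% (T$s * t(T$R)) +
      matrix(T$t, sum(ok), 3L, byrow = TRUE)
    if (!is.null(units)) x$units <- units
    return(x)
  }
  if (is.null(dim(x))) {
    if (length(x) != 3L) cg_stop("invalid_input_error", "expected a 3-vector")
    return(as.numeric(T$s * T$R %*% x + T$t))
  }
  x %*% (T$s * t(T$R)) + matrix(T$t, nrow(x), 3L, byrow = TRUE)
}

#' Serialise / restore a similarity transform as JSON
#'
#' Row-major rotation, translation and scale at full precision.
#'
#' @param T a \code{similarity_transform}.
#' @param path output (input) path.
#' @return \code{write_transform}: \code{path} invisibly;
#'   \code{read_transform}: the transform.
#' @export
write_transform <- function(T, path) {
  jsonlite::write_json(
    list(R = matrix(T$R, 3L, 3L), t = T$t, s = T$s),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(R = json_matrix(obj$R), t = obj$t, s = obj$s)
}

# jsonlite simplifies row-major nested arrays straight into a matrix;
# reconstruct one when simplification returned nested lists instead.
json_matrix <- function(x, ncol = 3L) {
  if (is.matrix(x)) {
    m <- unname(x)
    storage.mode(m) <- "double"
    m
  } else {
    matrix(unlist(x), ncol = ncol, byrow = TRUE)
  }
}
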