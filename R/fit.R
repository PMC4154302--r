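# Declarative point selections and primitive fitting.
#
# The interactive mouse selection of the original digitising workflow is
# replaced by declarative regions (explicit indices, a sphere, or an
# axis-aligned box) so that measurement sessions are scriptable and
# reproducible. Lines and planes are total-least-squares fits via the
# principal axes of the centred selection.

#' Define a point selection
#'
#' Exactly one of \code{indices}, \code{sphere}, \code{box} must be given.
#'
#' @param indices integer vector of 1-based point indices.
#' @param sphere list(centre = 3-vector, radius > 0).
#' @param box 2 x 3 matrix: rows are the lower and upper corners.
#' @return object of class \code{selection}.
#' @export
selection <- function(indices = NULL, sphere = NULL, box = NULL) {
  given <- !vapply(list(indices, sphere, box), is.null, logical(1))
  if (sum(given) != 1L)
    cg_stop("selection_error", "give exactly one of indices, sphere, box")
  if (!is.null(sphere)) {
    if (!is_number(sphere$radius) || sphere$radius <= 0)
      cg_stop("selection_error", "sphere radius must be > 0")
    sphere$centre <- as.numeric(sphere$centre)
  }
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (!identical(dim(box), c(2L, 3L)) || any(box[1L, ] > box[2L, ]))
      cg_stop("selection_error", "box must be 2 x 3 with lower <= upper")
  }
  structure(list(indices = indices, sphere = sphere, box = box),
            class = "selection")
}

#' Resolve a selection against a cloud
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param sel a \code{\link{selection}}.
#' @return integer vector of selected point indices (possibly empty).
#' @export
resolve_selection <- function(cloud, sel) {
  if (!inherits(sel, "selection")) cg_stop("selection_error", "sel must be a selection")
  p <- cloud$points
  if (!is.null(sel$indices)) {
    idx <- as.integer(sel$indices)
    if (any(idx < 1L | idx > nrow(p)))
      cg_stop("selection_error", "selection indices out of cloud bounds")
    return(idx)
  }
  if (!is.null(sel$sphere)) {
    d2 <- (p[, 1L] - sel$sphere$centre[1L])^2 +
          (p[, 2L] - sel$sphere$centre[2L])^2 +
          (p[, 3L] - sel$sphere$centre[3L])^2
    return(which(d2 <= sel$sphere$radius^2))
  }
  which(p[, 1L] >= sel$box[1L, 1L] & p[, 1L] <= sel$box[2L, 1L] &
        p[, 2L] >= sel$box[1L, 2L] & p[, 2L] <= sel$box[2L, 2L] &
        p[, 3L] >= sel$box[1L, 3L] & p[, 3L] <= sel$box[2L, 3L])
}

.selected_points <- function(cloud, sel, min_n, op) {
  idx <- resolve_selection(cloud, sel)
  if (length(idx) < min_n)
    cg_stop("selection_error", "%s needs at least %d selected points, have %d",
            op, min_n, length(idx))
  cloud$points[idx, , drop = FALSE]
}

# Principal axes of a centred selection with the deterministic tie-break
# and sign conventions shared by fit_line / fit_plane:
#  - eigen() of the 3x3 scatter matrix (deterministic LAPACK path);
#  - near-equal leading (or trailing) eigenvalues raise an ambiguity
#    warning; the lowest-index axis of the decomposition is kept.
.principal_axes <- function(pts) {
  ctr <- colMeans(pts)
  X <- sweep(pts, 2L, ctr)
  S <- crossprod(X) / nrow(X)
  e <- eigen(S, symmetric = TRUE)
  list(centre = ctr, values = e$values, vectors = e$vectors, X = X)
}

# Sign convention: make the dot product with (last - first selected point)
# non-negative; if that is zero, make the largest-magnitude component
# positive.
.orient_direction <- function(dir, pts) {
  span <- pts[nrow(pts), ] - pts[1L, ]
  d <- sum(dir * span)
  if (abs(d) > 1e-12) {
    if (d < 0) dir <- -dir
  } else {
    k <- which.max(abs(dir))
    if (dir[k] < 0) dir <- -dir
  }
  dir
}

#' Fit a point (centroid) to a selection
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param sel a \code{\link{selection}} resolving to >= 1 point.
#' @return length-3 centroid of the selected points.
#' @export
fit_point <- function(cloud, sel) {
  colMeans(.selected_points(cloud, sel, 1L, "fit_point"))
}

#' Fit a total-least-squares line to a selection
#'
#' The direction is the principal axis of the centred selection (the axis
#' maximising projected variance); the residual is the RMS perpendicular
#' distance. Direction sign follows the first-to-last selected point.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param sel a \code{\link{selection}} resolving to >= 2 non-coincident
#'   points.
#' @return object of class \code{fitted_line}: list(point, direction,
#'   rms_residual).
#' @export
fit_line <- function(cloud, sel) {
  pts <- .selected_points(cloud, sel, 2L, "fit_line")
  pa <- .principal_axes(pts)
  if (pa$values[1L] < 1e-24)
    cg_stop("degenerate_fit_error", "all selected points coincident")
  if (pa$values[1L] - pa$values[2L] < 1e-9 * pa$values[1L])
    cg_warn("ambiguous_fit_warning",
            "two leading principal values nearly equal; line direction ambiguous, keeping lowest-index axis")
  dir <- .orient_direction(pa$vectors[, 1L], pts)
  perp2 <- rowSums(pa$X^2) - as.numeric(pa$X %*% dir)^2
  structure(list(point = pa$centre, direction = dir,
                 rms_residual = sqrt(max(0, mean(perp2)))),
            class = "fitted_line")
}

#' @export
print.fitted_line <- function(x, ...) {
  cat(sprintf("<fitted_line> through (%.4g, %.4g, %.4g), direction (%.4g, %.4g, %.4g), rms %.3g\n",
              x$point[1L], x$point[2L], x$point[3L],
              x$direction[1L], x$direction[2L], x$direction[3L],
              x$rms_residual))
  invisible(x)
}

#' Fit a total-least-squares plane to a selection
#'
#' The normal is the least-variance axis of the centred selection; the
#' residual is the RMS point-to-plane distance. Normal sign: largest
#' magnitude component positive (a plane has no intrinsic side).
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param sel a \code{\link{selection}} resolving to >= 3 non-collinear
#'   points.
#' @return object of class \code{fitted_plane}: list(point, normal,
#'   rms_residual).
#' @export
fit_plane <- function(cloud, sel) {
  pts <- .selected_points(cloud, sel, 3L, "fit_plane")
  pa <- .principal_axes(pts)
  if (pa$values[2L] < 1e-12 * max(pa$values[1L], 1e-300))
    cg_stop("degenerate_fit_error", "selected points are collinear")
  if (pa$values[2L] - pa$values[3L] < 1e-9 * max(pa$values[1L], 1e-300))
    cg_warn("ambiguous_fit_warning",
            "two trailing principal values nearly equal; plane normal ambiguous, keeping lowest-index axis")
  nrm <- pa$vectors[, 3L]
  k <- which.max(abs(nrm))
  if (nrm[k] < 0) nrm <- -nrm
  res2 <- as.numeric(pa$X %*% nrm)^2
  structure(list(point = pa$centre, normal = nrm,
                 rms_residual = sqrt(mean(res2))),
            class = "fitted_plane")
}

#' @export
print.fitted_plane <- function(x, ...) {
  cat(sprintf("<fitted_plane> through (%.4g, %.4g, %.4g), normal (%.4g, %.4g, %.4g), rms %.3g\n",
              x$point[1L], x$point[2L], x$point[3L],
              x$normal[1L], x$normal[2L], x$normal[3L], x$rms_residual))
  invisible(x)
}
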