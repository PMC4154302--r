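# Virtual-marker digitising.
#
# Markers are placed on the reconstructed body surface over presumed joint
# centres (shoulder, hip, knee, ankle, metatarsal head, ...). A marker
# specification names a seed position and a search radius; the placement is
# the centroid of the cloud points inside the search sphere. Dense
# reconstruction leaves gaps wherever the surface lacks texture, so sparse
# regions yield an explicit missing placement, never an error, and batch
# digitising carries the last accepted position forward as the next frame's
# search centre.

#' Define a marker specification
#'
#' @param name marker name (non-empty).
#' @param seed length-3 starting search centre (frame-1 coordinates, in the
#'   units of the digitised clouds).
#' @param radius search-sphere radius (> 0, same units).
#' @param min_points minimum cloud points inside the sphere for a placement
#'   to be accepted (default 5).
#' @return object of class \code{marker_spec}.
#' @export
marker_spec <- function(name, seed, radius, min_points = 5L) {
  if (!nzchar(name)) cg_stop("invalid_marker_error", "marker name must be non-empty")
  if (!is_number(radius) || radius <= 0)
    cg_stop("invalid_marker_error", "search radius must be > 0")
  seed <- as.numeric(seed)
  if (length(seed) != 3L || !all(is.finite(seed)))
    cg_stop("invalid_marker_error", "seed must be a finite 3-vector")
  structure(list(name = name, seed = seed, radius = radius,
                 min_points = as.integer(min_points)),
            class = "marker_spec")
}

#' Place one virtual marker on a cloud
#'
#' @param cloud an oriented, calibrated \code{\link{point_cloud}}.
#' @param spec a \code{\link{marker_spec}}.
#' @param centre search centre for this frame (defaults to the spec's seed).
#' @return list(position = 3-vector or NULL when missing, n_points = count
#'   of cloud points inside the search sphere).
#' @export
place_marker <- function(cloud, spec, centre = spec$seed) {
  p <- cloud$points
  d2 <- (p[, 1L] - centre[1L])^2 + (p[, 2L] - centre[2L])^2 +
        (p[, 3L] - centre[3L])^2
  idx <- which(d2 <= spec$radius^2)
  if (length(idx) < spec$min_points)
    return(list(position = NULL, n_points = length(idx)))
  list(position = colMeans(p[idx, , drop = FALSE]), n_points = length(idx))
}

#' Batch-digitise a cloud sequence
#'
#' Steps through every frame, applies the orientation/calibration transform,
#' and places each marker. Frame i's accepted position becomes frame i+1's
#' search centre; a missing frame does not break propagation (the last valid
#' position carries forward). Markers missing on more than
#' \code{warn_missing_fraction} of frames raise a warning in the run report.
#'
#' @param seq a \code{\link{cloud_sequence}}.
#' @param specs list of \code{\link{marker_spec}} (seed positions in the
#'   transformed coordinates).
#' @param T \code{\link{similarity_transform}} applied to each frame before
#'   placement (default identity).
#' @param units units flag for the output series (\code{"metres"} when
#'   \code{T} carries a calibrated scale).
#' @param warn_missing_fraction warning threshold (default 0.5).
#' @return list with \code{series} (named list of
#'   \code{\link{marker_series}}) and \code{log} (data.frame: frame, marker,
#'   n_points, placed).
#' @export
batch_digitise <- function(seq, specs, T = similarity_transform(),
                           units = c("uncalibrated", "metres"),
                           warn_missing_fraction = 0.5) {
  units <- match.arg(units)
  nf <- length(seq$frames)
  ns <- length(specs)
  if (ns == 0L)
    return(list(series = list(),
                log = data.frame(frame = integer(), marker = character(),
                                 n_points = integer(), placed = logical())))
  pos <- lapply(specs, function(s) matrix(NA_real_, nf, 3L))
  counts <- matrix(0L, nf, ns)
  placed <- matrix(FALSE, nf, ns)
  centres <- lapply(specs, `[[`, "seed")

  identity_T <- max(abs(T$R - diag(3))) < .Machine$double.eps &&
    all(T$t == 0) && T$s == 1
  for (i in seq_len(nf)) {
    cl <- if (identity_T) seq$frames[[i]] else apply_transform(seq$frames[[i]], T)
    for (j in seq_len(ns)) {
      res <- place_marker(cl, specs[[j]], centres[[j]])
      counts[i, j] <- res$n_points
      if (!is.null(res$position)) {
        pos[[j]][i, ] <- res$position
        centres[[j]] <- res$position   # forward propagation
        placed[i, j] <- TRUE
      }
    }
  }
  series <- lapply(seq_len(ns), function(j) {
    frac_missing <- 1 - mean(placed[, j])
    if (frac_missing > warn_missing_fraction)
      cg_warn("marker_coverage_warning",
              "marker '%s' missing on %.0f%% of frames",
              specs[[j]]$name, 100 * frac_missing)
    marker_series(specs[[j]]$name, seq$frame_indices, pos[[j]],
                  valid = placed[, j], units = units)
  })
  names(series) <- vapply(specs, `[[`, "", "name")
  log <- data.frame(
    frame = rep(seq$frame_indices, ns),
    marker = rep(names(series), each = nf),
    n_points = as.vector(counts),
    placed = as.vector(placed))
  list(series = series, log = log)
}
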