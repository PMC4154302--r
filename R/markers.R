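# Marker documents and series.
#
# A marker document is the digitising output: per frame, the named virtual
# markers placed on the cloud. Serialised as XML (schema is ours, carried in
# a version attribute so future revisions parse safely) and convertible to a
# wide CSV table. A marker series is the per-marker view used by the
# kinematics layer: frame -> position with explicit validity flags, because
# reconstruction gaps make missing frames routine.

MARKER_SCHEMA_VERSION <- "1.0"

#' Construct a marker series
#'
#' @param name marker name (non-empty).
#' @param frames integer frame indices (strictly increasing).
#' @param positions n x 3 matrix; rows may be NA where the marker is missing.
#' @param valid logical vector; defaults to rows with no NA.
#' @param units \code{"uncalibrated"} or \code{"metres"}.
#' @return object of class \code{marker_series}.
#' @export
marker_series <- function(name, frames, positions,
                          valid = NULL,
                          units = c("uncalibrated", "metres")) {
  units <- match.arg(units)
  if (!nzchar(name)) cg_stop("invalid_marker_error", "marker name must be non-empty")
  frames <- as.integer(frames)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3, byrow = TRUE)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) != length(frames))
    cg_stop("invalid_marker_error", "positions must have one row per frame")
  if (any(diff(frames) <= 0L))
    cg_stop("invalid_marker_error", "frame indices must be strictly increasing")
  if (is.null(valid)) valid <- stats::complete.cases(positions)
  if (any(valid & !stats::complete.cases(positions)))
    cg_stop("invalid_marker_error", "valid frames must have finite positions")
  structure(list(name = name, frames = frames, positions = positions,
                 valid = as.logical(valid), units = units),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> '%s': %d frames (%d valid), %s\n",
              x$name, length(x$frames), sum(x$valid), x$units))
  invisible(x)
}

#' Construct a marker document
#'
#' @param frames list of per-frame entries, each a list with \code{index}
#'   (integer), \code{file} (source cloud filename, may be ""), \code{time}
#'   (seconds) and \code{markers}: a named list of length-3 numeric
#'   positions (possibly empty when every marker was occluded).
#' @param rate a \code{\link{frame_rate}}.
#' @param units units flag.
#' @return object of class \code{marker_document}.
#' @export
marker_document <- function(frames, rate,
                            units = c("uncalibrated", "metres")) {
  units <- match.arg(units)
  if (!inherits(rate, "frame_rate"))
    cg_stop("invalid_frame_rate_error", "rate must be a frame_rate")
  idx <- vapply(frames, function(f) as.integer(f$index), integer(1))
  if (anyDuplicated(idx) || is.unsorted(idx))
    cg_stop("invalid_marker_error", "frame indices must be unique and sorted")
  for (f in frames) {
    nm <- names(f$markers)
    if (length(nm) && anyDuplicated(nm))
      cg_stop("marker_validation_error",
              "duplicate marker name in frame %d: %s", f$index,
              nm[duplicated(nm)][1L])
  }
  structure(list(frames = frames, frame_rate = rate, units = units),
            class = "marker_document")
}

#' @export
print.marker_document <- function(x, ...) {
  nm <- unique(unlist(lapply(x$frames, function(f) names(f$markers))))
  cat(sprintf("<marker_document> %d frames, markers: %s (%s)\n",
              length(x$frames), paste(nm, collapse = ", "), x$units))
  invisible(x)
}

#' Write a marker document as XML
#'
#' Coordinates are serialised with 17 significant digits so that
#' \code{read_markers(write_markers(doc))} reproduces every value exactly.
#'
#' @param doc a \code{\link{marker_document}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_markers <- function(doc, path) {
  root <- xml2::xml_new_root("marker_document",
    version = MARKER_SCHEMA_VERSION,
    units = doc$units,
    frame_rate_num = as.character(doc$frame_rate$num),
    frame_rate_den = as.character(doc$frame_rate$den))
  for (f in doc$frames) {
    fr <- xml2::xml_add_child(root, "frame",
                              index = as.character(as.integer(f$index)),
                              file = as.character(f$file %||% ""),
                              time = fmt_full(f$time))
    for (nm in names(f$markers)) {
      p <- f$markers[[nm]]
      xml2::xml_add_child(fr, "marker", name = nm,
                          x = fmt_full(p[1L]), y = fmt_full(p[2L]),
                          z = fmt_full(p[3L]))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read a marker XML document
#'
#' @param path path written by \code{\link{write_markers}}.
#' @return a \code{\link{marker_document}}.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) cg_stop("io_error", "marker file not found: %s", path)
  root <- xml2::read_xml(path)
  ver <- xml2::xml_attr(root, "version")
  if (!identical(ver, MARKER_SCHEMA_VERSION))
    cg_stop("marker_schema_error",
            "unknown marker schema version '%s' (this build reads %s)",
            ver, MARKER_SCHEMA_VERSION)
  rate <- frame_rate(as.integer(xml2::xml_attr(root, "frame_rate_num")),
                     as.integer(xml2::xml_attr(root, "frame_rate_den")))
  units <- xml2::xml_attr(root, "units")
  frames <- lapply(xml2::xml_find_all(root, "./frame"), function(fr) {
    mk <- xml2::xml_find_all(fr, "./marker")
    markers <- lapply(mk, function(m)
      as.numeric(c(xml2::xml_attr(m, "x"), xml2::xml_attr(m, "y"),
                   xml2::xml_attr(m, "z"))))
    names(markers) <- xml2::xml_attr(mk, "name")
    list(index = as.integer(xml2::xml_attr(fr, "index")),
         file = xml2::xml_attr(fr, "file"),
         time = as.numeric(xml2::xml_attr(fr, "time")),
         markers = markers)
  })
  marker_document(frames, rate, units)
}

#' Split a marker document into per-marker series
#'
#' @param doc a \code{\link{marker_document}}.
#' @return named list of \code{\link{marker_series}}, one per marker name,
#'   covering every document frame with validity flags where the marker is
#'   absent.
#' @export
document_to_series <- function(doc) {
  idx <- vapply(doc$frames, function(f) as.integer(f$index), integer(1))
  all_names <- unique(unlist(lapply(doc$frames, function(f) names(f$markers))))
  out <- lapply(all_names, function(nm) {
    pos <- t(vapply(doc$frames, function(f) {
      p <- f$markers[[nm]]
      if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else p
    }, numeric(3)))
    marker_series(nm, idx, pos, units = doc$units)
  })
  names(out) <- all_names
  out
}

#' Assemble a marker document from series
#'
#' @param series named list of \code{\link{marker_series}} sharing one frame
#'   grid is not required; the union of frames is used.
#' @param rate a \code{\link{frame_rate}}.
#' @param files optional character vector of source filenames, one per
#'   union frame.
#' @param units units flag (defaults to the first series' flag).
#' @return a \code{\link{marker_document}}.
#' @export
series_to_document <- function(series, rate, files = NULL, units = NULL) {
  units <- units %||% series[[1L]]$units
  idx <- sort(unique(unlist(lapply(series, `[[`, "frames"))))
  frames <- lapply(seq_along(idx), function(i) {
    fi <- idx[i]
    markers <- list()
    for (s in series) {
      j <- match(fi, s$frames)
      if (!is.na(j) && s$valid[j]) markers[[s$name]] <- s$positions[j, ]
    }
    list(index = fi, file = if (is.null(files)) "" else files[i],
         time = frame_times(rate, fi), markers = markers)
  })
  marker_document(frames, rate, units)
}

#' Export marker series as a wide CSV table
#'
#' One row per frame; columns \code{frame}, \code{time}, then
#' \code{<name>_x}, \code{<name>_y}, \code{<name>_z} per marker. Missing
#' placements become empty cells.
#'
#' @param series named list of \code{\link{marker_series}}.
#' @param rate a \code{\link{frame_rate}} for the time column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_marker_csv <- function(series, rate, path) {
  idx <- sort(unique(unlist(lapply(series, `[[`, "frames"))))
  cols <- list(frame = as.character(idx),
               time = fmt_full(frame_times(rate, idx)))
  for (s in series) {
    m <- matrix(NA_real_, length(idx), 3L)
    j <- match(s$frames, idx)
    m[j[s$valid], ] <- s$positions[s$valid, , drop = FALSE]
    txt <- matrix(ifelse(is.na(m), "", fmt_full(m)), nrow = length(idx))
    cols[[paste0(s$name, "_x")]] <- txt[, 1L]
    cols[[paste0(s$name, "_y")]] <- txt[, 2L]
    cols[[paste0(s$name, "_z")]] <- txt[, 3L]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
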