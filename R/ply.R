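# PLY point-cloud I/O.
#
# Supports the two dialects dense multi-view stereo tools emit: format
# ascii 1.0 and binary_little_endian 1.0. The PMVS output dialect (normals
# plus diffuse_red/diffuse_green/diffuse_blue colours) is normalised onto
# the same internal colour field as the standard red/green/blue naming.
# Big-endian files are rejected loudly rather than silently byte-swapped.

.ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.ply_read_column <- function(raw_body, type, offset, record_size, n) {
  size <- .ply_type_size[[type]]
  idx <- rep.int((seq_len(n) - 1L) * record_size + offset, size) +
    rep(seq_len(size), each = n)
  bytes <- raw_body[sort(idx)]
  switch(type,
    float = , float32 = readBin(bytes, "numeric", n = n, size = 4L, endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n = n, size = 8L, endian = "little"),
    uchar = , uint8 = as.integer(readBin(bytes, "integer", n = n, size = 1L,
                                         signed = FALSE, endian = "little")),
    char = , int8 = readBin(bytes, "integer", n = n, size = 1L, signed = TRUE,
                            endian = "little"),
    short = , int16 = readBin(bytes, "integer", n = n, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", n = n, size = 2L, signed = FALSE,
                                endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", n = n, size = 4L, endian = "little"),
    cg_stop("ply_format_error", "unsupported PLY property type '%s'", type)
  )
}

.ply_parse_header <- function(lines, path) {
  if (length(lines) < 2L || trimws(lines[1L]) != "ply")
    cg_stop("ply_format_error", "%s: not a PLY file (missing 'ply' magic)", path)
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (length(fmt_line) != 1L)
    cg_stop("ply_format_error", "%s: missing format declaration", path)
  fmt_tok <- strsplit(trimws(fmt_line), "[ \t]+")[[1L]]
  format <- fmt_tok[2L]
  if (format == "binary_big_endian")
    cg_stop("ply_unsupported_dialect_error",
            "%s: binary_big_endian PLY is not supported (use ascii or binary_little_endian)",
            path)
  if (!format %in% c("ascii", "binary_little_endian"))
    cg_stop("ply_format_error", "%s: unknown PLY format '%s'", path, format)

  elements <- list()
  current <- NULL
  for (ln in lines[-1L]) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(tok) == 0L || tok[1L] %in% c("comment", "obj_info", "")) next
    if (tok[1L] == "format") next
    if (tok[1L] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2L], count = as.integer(tok[3L]),
                      properties = list())
    } else if (tok[1L] == "property") {
      if (is.null(current))
        cg_stop("ply_format_error", "%s: property before any element", path)
      if (tok[2L] == "list") {
        current$properties[[tok[5L]]] <- list(type = "list",
                                              count_type = tok[3L],
                                              item_type = tok[4L])
      } else {
        current$properties[[tok[3L]]] <- list(type = tok[2L])
      }
    } else if (tok[1L] == "end_header") {
      break
    }
  }
  if (!is.null(current)) elements[[current$name]] <- current
  list(format = format, elements = elements)
}

#' Read a PLY point cloud
#'
#' Reads \code{format ascii 1.0} or \code{format binary_little_endian 1.0}
#' PLY files. The vertex element must carry float \code{x}, \code{y},
#' \code{z} properties; optional \code{nx}, \code{ny}, \code{nz} normals and
#' RGB colours named either \code{red}/\code{green}/\code{blue} or (PMVS
#' dialect) \code{diffuse_red}/\code{diffuse_green}/\code{diffuse_blue} are
#' mapped onto the \code{normals} and \code{colours} fields. Non-vertex
#' elements (e.g. \code{face}) are ignored.
#'
#' @param path path to a \code{.ply} file.
#' @param frame_index frame number to attach to the cloud (default 0; set
#'   automatically by \code{\link{load_sequence}}).
#' @param units coordinate units flag for the returned cloud.
#' @return a \code{\link{point_cloud}}.
#' @export
read_ply <- function(path, frame_index = 0L,
                     units = c("uncalibrated", "metres")) {
  units <- match.arg(units)
  if (!file.exists(path)) cg_stop("io_error", "PLY file not found: %s", path)
  raw_all <- readBin(path, "raw", n = file.size(path))

  # Locate end_header terminated by \n (tolerate \r\n).
  marker <- charToRaw("end_header")
  hdr_end <- NA_integer_
  limit <- min(length(raw_all), 65536L)
  for (i in seq_len(limit - length(marker))) {
    if (raw_all[i] == marker[1L] &&
        identical(raw_all[i:(i + length(marker) - 1L)], marker)) {
      j <- i + length(marker)
      while (j <= length(raw_all) && raw_all[j] != as.raw(10L)) j <- j + 1L
      hdr_end <- j
      break
    }
  }
  if (is.na(hdr_end))
    cg_stop("ply_format_error", "%s: no end_header found", path)

  header_txt <- rawToChar(raw_all[seq_len(hdr_end)])
  header <- .ply_parse_header(strsplit(header_txt, "\r?\n")[[1L]], path)
  if (is.null(header$elements$vertex))
    cg_stop("ply_format_error", "%s: no vertex element", path)

  vert <- header$elements$vertex
  pnames <- names(vert$properties)
  for (req in c("x", "y", "z"))
    if (!req %in% pnames)
      cg_stop("ply_format_error", "%s: vertex element missing property '%s'", path, req)
  colour_names <- if (all(c("red", "green", "blue") %in% pnames)) {
    c("red", "green", "blue")
  } else if (all(c("diffuse_red", "diffuse_green", "diffuse_blue") %in% pnames)) {
    c("diffuse_red", "diffuse_green", "diffuse_blue")
  } else NULL
  has_normals <- all(c("nx", "ny", "nz") %in% pnames)
  n <- vert$count
  body <- raw_all[-seq_len(hdr_end)]

  if (header$format == "ascii") {
    lines <- strsplit(rawToChar(body), "\r?\n")[[1L]]
    lines <- lines[nzchar(trimws(lines))]
    pos <- 0L
    columns <- NULL
    for (el in header$elements) {
      if (el$name == "vertex") {
        if (pos + n > length(lines))
          cg_stop("io_error", "%s: expected %d vertex lines, found %d",
                  path, n, length(lines) - pos)
        vlines <- lines[pos + seq_len(n)]
        tok <- scan(text = vlines, what = numeric(), quiet = TRUE)
        np <- length(vert$properties)
        if (length(tok) != n * np)
          cg_stop("io_error", "%s: expected %d vertex values, found %d",
                  path, n * np, length(tok))
        columns <- matrix(tok, nrow = n, ncol = np, byrow = TRUE,
                          dimnames = list(NULL, pnames))
        break
      }
      # elements before vertex occupy one line per item (list properties
      # included: lists stay on their line)
      pos <- pos + el$count
    }
    get_col <- function(nm) columns[, nm]
  } else {
    # binary little-endian: walk elements in declared order
    offset <- 0L
    columns <- NULL
    for (el in header$elements) {
      types <- vapply(el$properties, `[[`, "", "type")
      if (any(types == "list") && el$name != "vertex") {
        if (is.null(columns))
          cg_stop("ply_unsupported_dialect_error",
                  "%s: binary list element '%s' precedes vertex data", path, el$name)
        break  # list elements after vertex: ignore
      }
      sizes <- .ply_type_size[types]
      record <- sum(sizes)
      need <- record * el$count
      if (el$name == "vertex") {
        if (offset + need > length(body))
          cg_stop("io_error",
                  "%s: truncated binary payload (expected %d bytes, found %d)",
                  path, offset + need, length(body))
        seg <- body[offset + seq_len(need)]
        offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
        columns <- lapply(seq_along(types), function(j)
          .ply_read_column(seg, types[[j]], offs[j], record, el$count))
        names(columns) <- names(el$properties)
        break
      }
      offset <- offset + need
    }
    get_col <- function(nm) columns[[nm]]
  }

  pts <- unname(cbind(get_col("x"), get_col("y"), get_col("z")))
  normals <- if (has_normals)
    unname(cbind(get_col("nx"), get_col("ny"), get_col("nz"))) else NULL
  colours <- if (!is.null(colour_names)) {
    cm <- unname(cbind(get_col(colour_names[1L]), get_col(colour_names[2L]),
                       get_col(colour_names[3L])))
    storage.mode(cm) <- "integer"
    cm
  } else NULL
  point_cloud(pts, colours = colours, normals = normals, units = units,
              frame_index = frame_index)
}

#' Write a PLY point cloud
#'
#' Emits \code{ascii} (9 significant digits) or \code{binary_little_endian}
#' (IEEE 4-byte floats) PLY. Colours are always written under the standard
#' \code{red}/\code{green}/\code{blue} naming regardless of how they were
#' read.
#'
#' @param cloud a \code{\link{point_cloud}}.
#' @param path output path.
#' @param dialect \code{"binary_little_endian"} (default) or \code{"ascii"}.
#' @return \code{path}, invisibly.
#' @export
write_ply <- function(cloud, path,
                      dialect = c("binary_little_endian", "ascii")) {
  dialect <- match.arg(dialect)
  n <- n_points(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0", dialect),
           "comment written by cloudgait",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z")
  if (!is.null(cloud$normals))
    hdr <- c(hdr, "property float nx", "property float ny", "property float nz")
  if (!is.null(cloud$colours))
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  hdr <- c(hdr, "end_header")

  fmat <- cloud$points
  if (!is.null(cloud$normals)) fmat <- cbind(fmat, cloud$normals)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) cg_stop("io_error", "cannot open %s for writing", path))
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)

  if (dialect == "ascii") {
    txt <- apply(fmat, 1L, function(r) paste(fmt_ply(r), collapse = " "))
    if (!is.null(cloud$colours))
      txt <- paste(txt, apply(cloud$colours, 1L, paste, collapse = " "))
    writeBin(charToRaw(paste0(paste(txt, collapse = "\n"), "\n")), con)
  } else {
    k <- ncol(fmat)
    fbytes <- writeBin(as.numeric(t(fmat)), raw(), size = 4L, endian = "little")
    if (is.null(cloud$colours)) {
      writeBin(fbytes, con)
    } else {
      record <- 4L * k + 3L
      m <- matrix(raw(), nrow = record, ncol = n)
      m[seq_len(4L * k), ] <- matrix(fbytes, nrow = 4L * k)
      m[4L * k + 1:3, ] <- matrix(as.raw(t(cloud$colours)), nrow = 3L)
      writeBin(as.vector(m), con)
    }
  }
  invisible(path)
}

#' Load a numbered folder of PLY clouds as a sequence
#'
#' Reconstruction pipelines leave one PLY per frame in a folder; this steps
#' through them in frame order. The frame number is the last run of
#' consecutive digits in the file stem (overridable via \code{frame_regex},
#' whose first capture group must be the number). Gaps in the numbering are
#' recorded on the sequence, never silently renumbered.
#'
#' @param folder directory containing the clouds.
#' @param pattern filename glob (default \code{"*.ply"}).
#' @param rate a \code{\link{frame_rate}}.
#' @param frame_regex optional regex overriding frame-number extraction.
#' @param units units flag applied to every cloud.
#' @return a \code{\link{cloud_sequence}}.
#' @export
load_sequence <- function(folder, pattern = "*.ply", rate,
                          frame_regex = NULL,
                          units = c("uncalibrated", "metres")) {
  units <- match.arg(units)
  files <- list.files(folder, pattern = utils::glob2rx(pattern))
  if (length(files) == 0L)
    cg_stop("empty_sequence_error", "no files matching '%s' in %s", pattern, folder)
  stems <- tools::file_path_sans_ext(files)
  nums <- if (is.null(frame_regex)) {
    vapply(stems, function(s) {
      m <- gregexpr("[0-9]+", s)[[1L]]
      if (m[1L] == -1L) return(NA_integer_)
      last <- length(m)
      as.integer(substr(s, m[last], m[last] + attr(m, "match.length")[last] - 1L))
    }, integer(1))
  } else {
    vapply(stems, function(s) {
      m <- regmatches(s, regexec(frame_regex, s))[[1L]]
      if (length(m) < 2L) return(NA_integer_)
      as.integer(m[2L])
    }, integer(1))
  }
  if (anyNA(nums))
    cg_stop("invalid_sequence_error", "no frame number found in: %s",
            paste(files[is.na(nums)], collapse = ", "))
  if (anyDuplicated(nums)) {
    dup <- nums[duplicated(nums)][1L]
    cg_stop("ambiguous_sequence_error",
            "frame number %d claimed by multiple files: %s", dup,
            paste(files[nums == dup], collapse = ", "))
  }
  ord <- order(nums)
  frames <- lapply(ord, function(i)
    read_ply(file.path(folder, files[i]), frame_index = nums[i], units = units))
  cloud_sequence(frames, rate)
}
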