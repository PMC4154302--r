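# Time series: the unit the kinematics layer works on.

#' Construct a time series
#'
#' @param times seconds, strictly increasing (derive from the sequence's
#'   exact rational frame rate where possible).
#' @param values numeric vector, or n x k matrix for vector-valued series.
#' @param valid logical validity flags (default: finite rows).
#' @return object of class \code{time_series}; \code{$uniform} is TRUE iff
#'   the sampling grid is uniform to 1e-9 s.
#' @export
time_series <- function(times, values, valid = NULL) {
  times <- as.numeric(times)
  if (is.null(dim(values))) values <- as.numeric(values)
  if (NROW(values) != length(times))
    cg_stop("invalid_series_error", "values must have one row per time")
  if (length(times) > 1L && any(diff(times) <= 0))
    cg_stop("invalid_series_error", "times must be strictly increasing")
  if (is.null(valid)) {
    valid <- if (is.matrix(values)) apply(is.finite(values), 1L, all)
             else is.finite(values)
  }
  uniform <- length(times) < 3L ||
    max(abs(diff(times) - stats::median(diff(times)))) < 1e-9
  structure(list(times = times, values = values, valid = as.logical(valid),
                 uniform = uniform),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples (%d valid), %s, [%.4g..%.4g] s\n",
              length(x$times), sum(x$valid),
              if (x$uniform) "uniform" else "non-uniform",
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Time series of one marker component
#'
#' @param series a \code{\link{marker_series}}.
#' @param rate a \code{\link{frame_rate}}.
#' @param component \code{"x"}, \code{"y"}, \code{"z"}, or \code{"xyz"} for
#'   the full 3-vector series.
#' @return a \code{\link{time_series}} on the marker's frame grid.
#' @export
marker_time_series <- function(series, rate, component = c("x", "y", "z", "xyz")) {
  component <- match.arg(component)
  times <- frame_times(rate, series$frames)
  vals <- switch(component,
                 x = series$positions[, 1L],
                 y = series$positions[, 2L],
                 z = series$positions[, 3L],
                 xyz = series$positions)
  time_series(times, vals, valid = series$valid)
}

# Columns of a series as a list of scalar series (shared times/valid).
.series_columns <- function(ts) {
  if (!is.matrix(ts$values)) return(list(ts))
  lapply(seq_len(ncol(ts$values)), function(j)
    time_series(ts$times, ts$values[, j], ts$valid))
}

#' Export scalar/vector time series as CSV
#'
#' Columns: \code{time}, then one column per named series component; empty
#' cells where invalid.
#'
#' @param series named list of \code{time_series} sharing one time grid.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_series_csv <- function(series, path) {
  times <- series[[1L]]$times
  cols <- list(time = fmt_full(times))
  for (nm in names(series)) {
    s <- series[[nm]]
    if (!isTRUE(all.equal(s$times, times)))
      cg_stop("invalid_series_error", "series '%s' is on a different time grid", nm)
    v <- if (is.matrix(s$values)) s$values else matrix(s$values, ncol = 1L)
    sub <- if (ncol(v) == 3L) c("_x", "_y", "_z") else
      if (ncol(v) == 1L) "" else paste0("_", seq_len(ncol(v)))
    for (j in seq_len(ncol(v))) {
      txt <- ifelse(s$valid & is.finite(v[, j]), fmt_full(v[, j]), "")
      cols[[paste0(nm, sub[j])]] <- txt
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
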