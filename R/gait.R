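# Stance/swing detection and stride summaries.
#
# On a treadmill, the stance foot rides the belt: stance shows as periods
# of constant positive X velocity of the foot marker (the metatarsal head),
# while swing returns the foot. Overground, the stance foot is stationary.
# Both detectors operate on a (caller-filtered) foot velocity series and
# return half-open frame intervals so that stance + swing tile the span
# exactly.

#' Detect stance phases from foot velocity
#'
#' Treadmill mode: the plateau velocity p is the median of samples with
#' v_x > 0; stance is any maximal run with |v_x - p| <= beta * |p|.
#' Overground mode: stance is any maximal run with |v| <= gamma * (95th
#' percentile of |v|). Runs shorter than \code{min_duration} frames are
#' discarded; adjacent runs separated by fewer than \code{min_gap} frames
#' are merged. The series should be low-pass filtered first (the caller's
#' responsibility; record the cutoff in the run log).
#'
#' @param foot_vx \code{\link{time_series}} of the foot marker's X velocity
#'   (treadmill) or speed component of interest (overground), covering at
#'   least 1 s.
#' @param mode \code{"treadmill"} or \code{"overground"}.
#' @param beta treadmill plateau tolerance band (default 0.25).
#' @param gamma overground fraction of the 95th-percentile speed
#'   (default 0.15).
#' @param min_duration minimum stance length, frames (default 3).
#' @param min_gap merge stances separated by fewer than this many frames
#'   (default 2).
#' @param refine_boundaries treadmill mode only: extend each run to the
#'   half-plateau crossing (default TRUE). A zero-phase low-pass filter
#'   smears the stance/swing velocity step symmetrically about the true
#'   event, so the filtered signal crosses p/2 at the event itself, while
#'   the entry into the tolerance band lags it by a fraction of the filter
#'   rise time; refining to the p/2 crossing removes that bias. On an
#'   unfiltered square wave the refinement changes nothing.
#' @return object of class \code{gait_events}: list(intervals = data.frame
#'   (start, end, plateau_velocity) with half-open sample intervals
#'   [start, end), mode, plateau).
#' @export
detect_stance <- function(foot_vx, mode = c("treadmill", "overground"),
                          beta = 0.25, gamma = 0.15,
                          min_duration = 3L, min_gap = 2L,
                          refine_boundaries = TRUE) {
  mode <- match.arg(mode)
  if (is.matrix(foot_vx$values))
    cg_stop("invalid_series_error", "detect_stance expects a scalar velocity series")
  tt <- foot_vx$times
  if (tt[length(tt)] - tt[1L] < 1)
    cg_stop("insufficient_data_error", "need at least 1 s of velocity data")
  v <- foot_vx$values
  ok <- foot_vx$valid & is.finite(v)

  if (mode == "treadmill") {
    pos <- v[ok & v > 0]
    if (length(pos) == 0L)
      cg_stop("no_plateau_error",
              "no positive-velocity samples; cannot anchor the stance plateau")
    plateau <- stats::median(pos)
    in_stance <- ok & abs(v - plateau) <= beta * abs(plateau)
  } else {
    speed <- abs(v[ok])
    ref <- stats::quantile(speed, 0.95, names = FALSE, type = 7)
    plateau <- 0
    in_stance <- ok & abs(v) <= gamma * ref
  }

  r <- rle(as.vector(in_stance))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)

  # merge runs separated by < min_gap, then drop short runs
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$start[i] - last$end < min_gap) {
        keep[[length(keep)]]$end <- runs$end[i]
      } else {
        keep[[length(keep) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }
  runs <- runs[runs$end - runs$start >= min_duration, , drop = FALSE]
  rownames(runs) <- NULL

  if (refine_boundaries && mode == "treadmill" && nrow(runs) > 0L) {
    half <- plateau / 2
    n <- length(v)
    for (i in seq_len(nrow(runs))) {
      s0 <- runs$start[i]
      while (s0 > 1L && ok[s0 - 1L] && v[s0 - 1L] >= half &&
             (i == 1L || s0 - 1L >= runs$end[i - 1L])) s0 <- s0 - 1L
      e0 <- runs$end[i]
      while (e0 <= n && ok[e0] && v[e0] >= half &&
             (i == nrow(runs) || e0 < runs$start[i + 1L])) e0 <- e0 + 1L
      runs$start[i] <- s0
      runs$end[i] <- e0
    }
  }
  runs$plateau_velocity <- if (nrow(runs)) vapply(seq_len(nrow(runs)),
    function(i) mean(v[runs$start[i]:(runs$end[i] - 1L)]), 0) else numeric(0)

  structure(list(intervals = runs, mode = mode,
                 plateau = plateau, times = tt),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s: %d stance intervals, plateau %.3g m/s\n",
              x$mode, nrow(x$intervals), x$plateau))
  invisible(x)
}

#' Summarise stride parameters from gait events
#'
#' Stride duration is the mean interval between consecutive stance onsets;
#' duty factor is mean stance duration over stride duration; stride length
#' is the mean foot displacement between consecutive stance onsets
#' (overground) or plateau speed times stride duration (treadmill, where
#' the foot's displacement is belt travel).
#'
#' @param events \code{\link{detect_stance}} output with >= 2 stance
#'   onsets.
#' @param foot_x \code{\link{time_series}} of the foot marker's X position,
#'   on the same sample grid as the velocity the events came from.
#' @return object of class \code{gait_summary}: list(stride_duration_s,
#'   duty_factor, stride_length_m, n_strides).
#' @export
summarise_gait <- function(events, foot_x) {
  iv <- events$intervals
  if (nrow(iv) < 2L)
    cg_stop("insufficient_strides_error",
            "need at least 2 stance onsets, have %d", nrow(iv))
  tt <- events$times
  onset_t <- tt[iv$start]
  stride <- mean(diff(onset_t))
  stance <- mean(tt[pmin(iv$end, length(tt))] - tt[iv$start])
  duty <- stance / stride
  stride_len <- if (events$mode == "overground") {
    mean(abs(diff(foot_x$values[iv$start])))
  } else {
    abs(events$plateau) * stride
  }
  structure(list(stride_duration_s = stride, duty_factor = duty,
                 stride_length_m = stride_len,
                 n_strides = nrow(iv) - 1L),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(
    "<gait_summary> %d strides: duration %.3f s, duty factor %.3f, stride length %.3f m\n",
    x$n_strides, x$stride_duration_s, x$duty_factor, x$stride_length_m))
  invisible(x)
}

#' Export gait events as CSV
#'
#' Columns: onset frame-sample index, offset index (half-open), onset time
#' (s), stance duration (s), plateau velocity.
#'
#' @param events a \code{gait_events}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gait_csv <- function(events, path) {
  iv <- events$intervals
  tt <- events$times
  df <- data.frame(
    onset = iv$start, offset = iv$end,
    onset_time = fmt_full(tt[iv$start]),
    stance_duration = fmt_full(tt[pmin(iv$end, length(tt))] - tt[iv$start]),
    plateau_velocity = fmt_full(iv$plateau_velocity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
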