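# Zero-phase Butterworth low-pass filtering.
#
# Manually digitised marker tracks are noisy; the classical remedy is a
# low-order Butterworth low-pass run forward and then backward so the net
# phase shift is zero and the effective magnitude response is the
# single-pass response squared: |H_bi(f)| = 1 / (1 + (f/f_c)^(2p)) for p
# poles. Coefficients come from signal::butter (bilinear transform with
# cutoff prewarping); the bidirectional pass, odd reflective padding and
# steady-state initialisation are implemented here so edge transients do
# not leak into the data span.

#' Define a Butterworth filter specification
#'
#' @param order number of poles (even, positive; default 4).
#' @param cutoff_hz -3 dB cutoff of the single pass, Hz (> 0; default 2, the
#'   very low cutoff that noisy digitised tracks at video rates require).
#' @param bidirectional run forward then backward for zero phase
#'   (default TRUE).
#' @param padding reflective padding length in samples; NULL (default) uses
#'   three times the impulse-settling estimate \code{fs / cutoff_hz},
#'   capped at the data length minus one.
#' @return object of class \code{filter_spec}.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 2, bidirectional = TRUE,
                        padding = NULL) {
  order <- as.integer(order)
  if (order <= 0L || order %% 2L != 0L)
    cg_stop("filter_spec_error", "filter order must be a positive even integer")
  if (!is_number(cutoff_hz) || cutoff_hz <= 0)
    cg_stop("filter_spec_error", "cutoff_hz must be > 0")
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 bidirectional = isTRUE(bidirectional), padding = padding),
            class = "filter_spec")
}

# Steady-state initial filter state (direct form II transposed) for unit
# step input, so a constant signal passes through with no transient.
.lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  A <- matrix(0, n - 1L, n - 1L)
  A[, 1L] <- -a[-1L]
  if (n > 2L) A[seq_len(n - 2L), 2L:(n - 1L)] <- diag(n - 2L)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - A, B)
}

# Direct-form-II-transposed IIR filter with supplied initial state.
.iir_filter <- function(b, a, x, zi) {
  nb <- length(b); y <- numeric(length(x)); z <- zi
  nz <- length(z)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nz > 1L) {
      z[seq_len(nz - 1L)] <- b[2L:nz] * xi + z[2L:nz] - a[2L:nz] * yi
      z[nz] <- b[nb] * xi - a[nb] * yi
    } else {
      z[1L] <- b[nb] * xi - a[nb] * yi
    }
    y[i] <- yi
  }
  y
}

# One zero-phase pass over a gap-free numeric vector.
.zero_phase <- function(x, b, a, zi, pad, bidirectional) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- if (pad > 0L)
    c(2 * x[1L] - x[seq(pad + 1L, 2L)], x, 2 * x[n] - x[n - 1L:pad])
  else x
  y <- .iir_filter(b, a, xp, zi * xp[1L])
  if (bidirectional) {
    y <- rev(y)
    y <- rev(.iir_filter(b, a, y, zi * y[1L]))
  }
  if (pad > 0L) y <- y[pad + seq_len(n)]
  y
}

#' Zero-phase Butterworth low-pass filter a time series
#'
#' Requires a uniform sampling grid. Interior gaps (invalid samples) of at
#' most \code{max_gap} samples are linearly interpolated before filtering;
#' longer gaps raise an error naming the offending samples. Leading and
#' trailing invalid samples are excluded and remain invalid in the output.
#'
#' @param series a \code{\link{time_series}} (scalar or vector valued).
#' @param spec a \code{\link{filter_spec}}.
#' @param max_gap largest interior gap (samples) to interpolate (default 5).
#' @return filtered \code{\link{time_series}} on the same time grid.
#' @export
butterworth_filter <- function(series, spec = filter_spec(), max_gap = 5L) {
  if (!inherits(spec, "filter_spec"))
    cg_stop("filter_spec_error", "spec must be a filter_spec")
  if (!series$uniform)
    cg_stop("gap_error", "butterworth_filter requires a uniform sampling grid")
  n <- length(series$times)
  if (n < 2L) cg_stop("insufficient_data_error", "need at least 2 samples")
  fs <- 1 / stats::median(diff(series$times))
  nyq <- fs / 2
  if (spec$cutoff_hz >= nyq)
    cg_stop("filter_spec_error",
            "cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
            spec$cutoff_hz, nyq)

  valid <- series$valid
  core <- range(which(valid))
  span <- core[1L]:core[2L]
  inv <- span[!valid[span]]
  if (length(inv)) {
    runs <- split(inv, cumsum(c(1L, diff(inv) != 1L)))
    too_long <- runs[vapply(runs, length, 0L) > max_gap]
    if (length(too_long))
      cg_stop("gap_error",
              "gap longer than max_gap = %d samples at samples %s",
              max_gap,
              paste(vapply(too_long, function(r)
                sprintf("%d-%d", r[1L], r[length(r)]), ""), collapse = ", "))
  }

  bt <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  b <- bt$b; a <- bt$a
  zi <- .lfilter_zi(b, a)
  pad <- spec$padding %||% as.integer(ceiling(3 * fs / spec$cutoff_hz))

  vals <- if (is.matrix(series$values)) series$values else
    matrix(series$values, ncol = 1L)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[span, j]
    if (length(inv))  # fill interior gaps linearly before filtering
      x <- stats::approx(series$times[span][valid[span]],
                         vals[span, j][valid[span]],
                         xout = series$times[span])$y
    out[span, j] <- .zero_phase(x, b, a, zi, pad, spec$bidirectional)
  }
  out_valid <- logical(n)
  out_valid[span] <- TRUE
  if (!is.matrix(series$values)) out <- out[, 1L]
  time_series(series$times, out, valid = out_valid)
}
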