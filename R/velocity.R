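# Velocity estimation.
#
# Three complementary estimators, matching how digitised tracks are
# analysed in practice: (1) cubic (smoothing-)spline fit differentiated
# analytically -- the moderate-noise workhorse; (2) finite differences of
# the raw or Butterworth-filtered positions; (3) ordinary least squares of
# position against time for absolute mean velocities.

#' Spline-fit a series and differentiate
#'
#' Fits a cubic spline per component over the valid samples only (gaps are
#' simply absent knots) and evaluates the fit and its analytic derivative at
#' all sample times. \code{smoothing = 0} gives the interpolating cubic
#' spline (Forsythe--Malcolm--Moler end conditions: exact for cubic
#' polynomials); \code{smoothing = "gcv"} (default) is a smoothing spline
#' with the parameter chosen by generalised cross-validation; a number in
#' (0, 1] is passed as \code{spar} to \code{\link[stats]{smooth.spline}}.
#'
#' @param series a \code{\link{time_series}} (scalar or vector valued) with
#'   >= 4 valid samples.
#' @param smoothing \code{"gcv"}, 0, or a \code{spar} value.
#' @return list(position, velocity): two \code{\link{time_series}} on the
#'   input grid (all samples marked valid -- the spline interpolates through
#'   gaps).
#' @export
spline_velocity <- function(series, smoothing = "gcv") {
  ok <- series$valid
  if (sum(ok) < 4L)
    cg_stop("insufficient_data_error",
            "spline fit needs at least 4 valid samples, have %d", sum(ok))
  vals <- if (is.matrix(series$values)) series$values else
    matrix(series$values, ncol = 1L)
  pos <- vals; vel <- vals
  tt <- series$times
  for (j in seq_len(ncol(vals))) {
    x <- tt[ok]; y <- vals[ok, j]
    if (identical(smoothing, 0) || identical(smoothing, 0L)) {
      f <- stats::splinefun(x, y, method = "fmm")
      pos[, j] <- f(tt)
      vel[, j] <- f(tt, deriv = 1L)
    } else {
      fit <- if (identical(smoothing, "gcv"))
        stats::smooth.spline(x, y, cv = FALSE)
      else
        stats::smooth.spline(x, y, spar = smoothing)
      pos[, j] <- stats::predict(fit, tt)$y
      vel[, j] <- stats::predict(fit, tt, deriv = 1L)$y
    }
  }
  if (!is.matrix(series$values)) { pos <- pos[, 1L]; vel <- vel[, 1L] }
  list(position = time_series(tt, pos, valid = rep(TRUE, length(tt))),
       velocity = time_series(tt, vel, valid = rep(TRUE, length(tt))))
}

#' Finite-difference velocity
#'
#' Central differences at interior samples, one-sided at the ends, using the
#' actual (exact-rational-derived) time steps, so linear motion is
#' recovered exactly and central differences are exact for quadratics.
#' Invalid samples yield invalid velocities, as do their neighbours (a
#' central difference needs both flanking positions).
#'
#' @param series a \code{\link{time_series}} with >= 2 valid samples.
#' @return velocity \code{\link{time_series}} in input units per second.
#' @export
finite_difference_velocity <- function(series) {
  n <- length(series$times)
  if (sum(series$valid) < 2L)
    cg_stop("insufficient_data_error", "finite differences need at least 2 valid samples")
  vals <- if (is.matrix(series$values)) series$values else
    matrix(series$values, ncol = 1L)
  tt <- series$times
  vel <- matrix(NA_real_, n, ncol(vals))
  ok <- series$valid
  vvalid <- logical(n)
  if (n >= 2L) {
    for (j in seq_len(ncol(vals))) {
      if (n > 2L) {
        i <- 2L:(n - 1L)
        vel[i, j] <- (vals[i + 1L, j] - vals[i - 1L, j]) / (tt[i + 1L] - tt[i - 1L])
      }
      vel[1L, j] <- (vals[2L, j] - vals[1L, j]) / (tt[2L] - tt[1L])
      vel[n, j] <- (vals[n, j] - vals[n - 1L, j]) / (tt[n] - tt[n - 1L])
    }
    vvalid[1L] <- ok[1L] && ok[2L]
    vvalid[n] <- ok[n] && ok[n - 1L]
    if (n > 2L) {
      i <- 2L:(n - 1L)
      vvalid[i] <- ok[i - 1L] & ok[i + 1L]
    }
  }
  if (!is.matrix(series$values)) vel <- vel[, 1L]
  time_series(tt, vel, valid = vvalid)
}

#' Mean velocity by linear regression
#'
#' Absolute mean velocities are extracted as the ordinary-least-squares
#' slope of a positional component against time over the valid samples
#' (gaps are never interpolated for regression).
#'
#' @param series a \code{\link{time_series}}.
#' @param component column for vector-valued series: 1/2/3 or
#'   \code{"x"}/\code{"y"}/\code{"z"} (ignored for scalar series).
#' @return list(slope, intercept, r_squared); slope in input units per
#'   second.
#' @export
mean_velocity_regression <- function(series, component = 1L) {
  vals <- if (is.matrix(series$values)) {
    j <- if (is.character(component)) match(component, c("x", "y", "z")) else component
    series$values[, j]
  } else series$values
  ok <- series$valid & is.finite(vals)
  if (sum(ok) < 2L)
    cg_stop("insufficient_data_error", "regression needs at least 2 valid samples")
  t <- series$times[ok]; y <- vals[ok]
  if (stats::var(t) == 0)
    cg_stop("degenerate_input_error", "zero time variance in regression")
  fit <- stats::lm.fit(cbind(1, t), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}
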