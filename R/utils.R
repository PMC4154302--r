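# Internal helpers shared across modules.

# Classed condition thrown for user-facing failures so callers can
# distinguish format, selection, and numeric errors programmatically.
cg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cloudgait_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

cg_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "cloudgait_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Format doubles so that read-back reproduces the value exactly
# (17 significant digits round-trips IEEE doubles).
fmt_full <- function(x) sprintf("%.17g", x)

# 9 significant digits: the ASCII PLY precision contract.
fmt_ply <- function(x) sprintf("%.9g", x)

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) cg_stop("degenerate_input_error", "cannot normalise a zero vector")
  v / n
}

# Rodrigues rotation: angle (rad) about unit axis.
rotation_about_axis <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Angle (rad) of a rotation matrix, clamped for acos safety.
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

assert_rotation <- function(R, tol = 1e-6, what = "rotation") {
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) <= 0)
    cg_stop("invalid_rotation_error", "%s matrix is not a proper rotation", what)
  invisible(R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
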