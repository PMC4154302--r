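# Synthetic locomotion scenes with exact ground truth.
#
# Validation data for the whole measurement chain: noisy, gappy point-cloud
# sequences whose generating transform, marker trajectories, stance
# intervals and mean velocities are known exactly by construction. The
# model is marker-trajectory-first: joint paths are analytic functions of
# time, body segments are rendered as point scatter around the
# joint-to-joint lines, and reconstruction artefacts are layered on top
# (global Gaussian noise, contiguous angular-sector dropout mimicking
# textureless fur patches, a static textured background, and one global
# similarity transform carrying the scene into arbitrary "reconstruction"
# units). Scenario presets carry the camera spacings, frame rates and
# speeds of the four study set-ups.

.POLE_N <- 80L
.RAIL_N <- 80L

#' Walker scenario parameters
#'
#' Defaults describe a moderate bipedal walk; the scenario presets
#' (\code{\link{scenario_params}}) override them with each study set-up.
#'
#' @param mode \code{"treadmill"} (hip near-fixed, stance foot rides the
#'   belt at +V) or \code{"overground"} (hip advances at V, stance foot
#'   planted).
#' @param speed_ms walking (belt) speed V, m/s.
#' @param stride_hz stride frequency f, Hz; stride length is V/f.
#' @param duty_factor stance fraction of the stride, in (0, 1).
#' @param thigh_m,shank_m,foot_m,torso_m segment lengths, metres.
#' @param lateral_amplitude_m swing lateral-deviation (abduction)
#'   amplitude, metres.
#' @param lift_height_m swing foot-lift height, metres.
#' @param rate a \code{\link{frame_rate}} or preset name.
#' @param duration_s clip length, seconds.
#' @param points_per_segment rendered points per body segment per frame.
#' @param noise_sd_m isotropic Gaussian reconstruction noise sigma, metres.
#' @param dropout fraction in [0, 1): angular width of the per-segment
#'   missing sector (contiguous, not i.i.d. thinning).
#' @param background_points static scene-texture points besides the pole
#'   and rail.
#' @param seed RNG seed; equal seeds give byte-identical output.
#' @param transform \code{NULL} (identity), \code{"random"} (seeded random
#'   similarity into reconstruction units), or a
#'   \code{\link{similarity_transform}}.
#' @return object of class \code{walker_params}.
#' @export
walker_params <- function(mode = c("overground", "treadmill"),
                          speed_ms = 0.85, stride_hz = 1, duty_factor = 0.6,
                          thigh_m = 0.30, shank_m = 0.28, foot_m = 0.10,
                          torso_m = 0.30,
                          lateral_amplitude_m = 0.04, lift_height_m = 0.05,
                          rate = frame_rate("30p"), duration_s = 10,
                          points_per_segment = 60L, noise_sd_m = 0.005,
                          dropout = 0, background_points = 300L,
                          seed = 1L, transform = NULL) {
  mode <- match.arg(mode)
  if (is.character(rate)) rate <- frame_rate(rate)
  if (!(duty_factor > 0 && duty_factor < 1))
    cg_stop("parameter_error", "duty_factor must be in (0, 1)")
  if (noise_sd_m < 0 || dropout < 0 || dropout >= 1)
    cg_stop("parameter_error", "need noise_sd_m >= 0 and dropout in [0, 1)")
  if (min(thigh_m, shank_m, foot_m, torso_m) <= 0)
    cg_stop("parameter_error", "segment lengths must be > 0")
  if (speed_ms < 0 || stride_hz <= 0 || duration_s <= 0)
    cg_stop("parameter_error", "speeds, frequencies and durations must be positive")
  structure(list(mode = mode, speed_ms = speed_ms, stride_hz = stride_hz,
                 duty_factor = duty_factor, thigh_m = thigh_m,
                 shank_m = shank_m, foot_m = foot_m, torso_m = torso_m,
                 lateral_amplitude_m = lateral_amplitude_m,
                 lift_height_m = lift_height_m, rate = rate,
                 duration_s = duration_s,
                 points_per_segment = as.integer(points_per_segment),
                 noise_sd_m = noise_sd_m, dropout = dropout,
                 background_points = as.integer(background_points),
                 seed = as.integer(seed), transform = transform),
            class = "walker_params")
}

#' Flyer scenario parameters
#'
#' A bird climbing through the scene on a straight path: the head advances
#' at the given ground speed and climb rate along a heading, wingtips flap
#' sinusoidally relative to the body.
#'
#' @param ground_speed_ms horizontal speed over the ground, m/s.
#' @param climb_rate_ms rate of ascent, m/s.
#' @param flap_hz wingbeat frequency, Hz.
#' @param wingtip_amplitude_m vertical flap amplitude, metres.
#' @param heading_deg ground-track direction, degrees from +X toward +Y.
#' @param semispan_m wingtip lateral offset from the body axis, metres.
#' @inheritParams walker_params
#' @return object of class \code{flyer_params}.
#' @export
flyer_params <- function(ground_speed_ms = 4.74, climb_rate_ms = 0.82,
                         flap_hz = 4, wingtip_amplitude_m = 0.25,
                         heading_deg = 0, semispan_m = 0.45,
                         rate = frame_rate("30p"), duration_s = 2.5,
                         points_per_segment = 60L, noise_sd_m = 0.005,
                         dropout = 0, background_points = 300L,
                         seed = 1L, transform = NULL) {
  if (is.character(rate)) rate <- frame_rate(rate)
  if (ground_speed_ms < 0 || climb_rate_ms < 0)
    cg_stop("parameter_error", "speeds must be >= 0")
  if (flap_hz <= 0) cg_stop("parameter_error", "flap_hz must be > 0")
  if (noise_sd_m < 0 || dropout < 0 || dropout >= 1)
    cg_stop("parameter_error", "need noise_sd_m >= 0 and dropout in [0, 1)")
  structure(list(ground_speed_ms = ground_speed_ms,
                 climb_rate_ms = climb_rate_ms, flap_hz = flap_hz,
                 wingtip_amplitude_m = wingtip_amplitude_m,
                 heading_deg = heading_deg, semispan_m = semispan_m,
                 rate = rate, duration_s = duration_s,
                 points_per_segment = as.integer(points_per_segment),
                 noise_sd_m = noise_sd_m, dropout = dropout,
                 background_points = as.integer(background_points),
                 seed = as.integer(seed), transform = transform),
            class = "flyer_params")
}

# Seeded random similarity transform into "reconstruction units":
# uniform random rotation (normalised quaternion), translation in
# [-5, 5]^3, log-uniform scale in [0.5, 2].
.random_similarity <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
  similarity_transform(R = R, t = stats::runif(3L, -5, 5),
                       s = exp(stats::runif(1L, log(0.5), log(2))))
}

.resolve_transform <- function(transform) {
  if (is.null(transform)) return(similarity_transform())
  if (identical(transform, "random")) return(.random_similarity())
  if (inherits(transform, "similarity_transform")) return(transform)
  cg_stop("parameter_error", "transform must be NULL, \"random\", or a similarity_transform")
}

# Scatter n points around the line segment a -> b at the given surface
# radius; returns points plus each point's azimuth (for sector dropout).
.render_segment <- function(a, b, radius, n) {
  axis <- b - a
  len <- vnorm(axis)
  ax <- if (len > 1e-12) axis / len else c(0, 0, 1)
  ref <- if (abs(ax[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(c(ax[2L] * ref[3L] - ax[3L] * ref[2L],
               ax[3L] * ref[1L] - ax[1L] * ref[3L],
               ax[1L] * ref[2L] - ax[2L] * ref[1L]))
  e2 <- c(ax[2L] * e1[3L] - ax[3L] * e1[2L],
          ax[3L] * e1[1L] - ax[1L] * e1[3L],
          ax[1L] * e1[2L] - ax[2L] * e1[1L])
  u <- stats::runif(n)
  psi <- stats::runif(n, 0, 2 * pi)
  r <- radius * (1 + 0.15 * stats::rnorm(n))
  pts <- matrix(a, n, 3L, byrow = TRUE) + outer(u, axis) +
    r * (outer(cos(psi), e1) + outer(sin(psi), e2))
  list(points = pts, psi = psi)
}

.apply_sector_dropout <- function(seg, dropout) {
  if (dropout <= 0) return(seg$points)
  psi0 <- stats::runif(1L, 0, 2 * pi)
  d <- (seg$psi - psi0) %% (2 * pi)
  seg$points[d > 2 * pi * dropout, , drop = FALSE]
}

# Static scene structure: an exactly-vertical pole, an exactly +X rail at
# known height, and scattered texture points. Pole and rail carry no
# structural scatter so noiseless orientation recovery is exact.
.scene_background <- function(x_max, background_points) {
  pole_base <- c(-0.5, 0.8, 0)
  pole_top  <- c(-0.5, 0.8, 2)
  rail_a <- c(-1, 0.8, 0.1)
  rail_b <- c(x_max + 1, 0.8, 0.1)
  pole <- matrix(pole_base, .POLE_N, 3L, byrow = TRUE) +
    outer(stats::runif(.POLE_N), pole_top - pole_base)
  rail <- matrix(rail_a, .RAIL_N, 3L, byrow = TRUE) +
    outer(stats::runif(.RAIL_N), rail_b - rail_a)
  scatter <- cbind(stats::runif(background_points, -1, x_max + 1),
                   stats::runif(background_points, -1.5, 1.5),
                   stats::runif(background_points, 0, 2.2))
  list(points = rbind(pole, rail, scatter),
       pole_indices = seq_len(.POLE_N),
       rail_indices = .POLE_N + seq_len(.RAIL_N),
       pole = rbind(pole_base, pole_top),
       rail = rbind(rail_a, rail_b))
}

# Foot contact-point trajectory. Stance: phase in [0, duty); treadmill
# stance rides the belt at +V, overground stance is planted. Swing returns
# (treadmill) or advances (overground) the foot with a smooth cosine
# profile plus sinusoidal lift and lateral deviation.
.foot_contact <- function(t, p, phase0, y_off) {
  f <- p$stride_hz; V <- p$speed_ms; beta <- p$duty_factor
  L <- V / f
  ph <- f * t + phase0
  k <- floor(ph)
  phi <- ph - k
  # round the phase for classification so samples landing exactly on the
  # stance/swing boundary classify identically in trajectory and truth
  stance <- round(phi, 9L) < beta
  u <- pmax(0, (phi - beta) / (1 - beta))
  x <- if (p$mode == "treadmill") {
    ifelse(stance, -beta * L / 2 + V * phi / f, (beta * L / 2) * cos(pi * u))
  } else {
    plant <- (k + beta / 2 - phase0) * L
    ifelse(stance, plant, plant + L * (1 - cos(pi * u)) / 2)
  }
  z <- ifelse(stance, 0, p$lift_height_m * sin(pi * u))
  y <- y_off + ifelse(stance, 0, p$lateral_amplitude_m * sin(pi * u))
  cbind(x, y, z)
}

# Two-link inverse kinematics: knee position given hip joint and ankle,
# bending toward +X.
.knee_ik <- function(hip, ankle, thigh, shank) {
  v <- ankle - hip
  d <- vnorm(v)
  if (d > 0.999 * (thigh + shank))
    cg_stop("parameter_error",
            "stride geometry exceeds leg reach (hip-ankle %.3f m vs legs %.3f m)",
            d, thigh + shank)
  a <- (thigh^2 - shank^2 + d^2) / (2 * d)
  h <- sqrt(max(thigh^2 - a^2, 0))
  uhat <- v / d
  fwd <- c(1, 0, 0)
  w <- fwd - sum(fwd * uhat) * uhat
  wn <- vnorm(w)
  w <- if (wn > 1e-9) w / wn else c(0, 0, 1)
  hip + a * uhat + h * w
}

# Analytic joint/marker positions for one frame time.
.walker_joints <- function(t, p) {
  f <- p$stride_hz
  hip_h <- 0.88 * (p$thigh_m + p$shank_m)
  hx <- if (p$mode == "overground") p$speed_ms * t else 0
  # small lateral sway and vertical bob on the pelvis, as in real walking
  hip_c <- c(hx,
             0.01 * sin(2 * pi * f * t),
             hip_h + 0.005 * sin(4 * pi * f * t))
  hip_l <- hip_c + c(0, 0.05, 0)
  hip_r <- hip_c - c(0, 0.05, 0)
  shoulder <- hip_c + c(0.02, 0, p$torso_m)
  head <- shoulder + c(0.08, 0, 0.08)
  cl <- .foot_contact(t, p, 0,  0.06)[1L, ]
  cr <- .foot_contact(t, p, 0.5, -0.06)[1L, ]
  ankle_l <- cl + c(-0.02, 0, 0.04)
  ankle_r <- cr + c(-0.02, 0, 0.04)
  mt5_l <- cl + c(0.06, 0, 0.01)
  mt5_r <- cr + c(0.06, 0, 0.01)
  knee_l <- .knee_ik(hip_l, ankle_l, p$thigh_m, p$shank_m)
  knee_r <- .knee_ik(hip_r, ankle_r, p$thigh_m, p$shank_m)
  list(head = head, shoulder = shoulder, hip = hip_c,
       hip_l = hip_l, hip_r = hip_r,
       knee_l = knee_l, knee_r = knee_r,
       ankle_l = ankle_l, ankle_r = ankle_r,
       mt5_l = mt5_l, mt5_r = mt5_r)
}

.walker_segments <- function(j) {
  list(list(j$hip, j$shoulder, 0.07),
       list(j$shoulder, j$head, 0.05),
       list(j$hip_l, j$knee_l, 0.035), list(j$knee_l, j$ankle_l, 0.03),
       list(j$ankle_l, j$mt5_l, 0.02),
       list(j$hip_r, j$knee_r, 0.035), list(j$knee_r, j$ankle_r, 0.03),
       list(j$ankle_r, j$mt5_r, 0.02))
}

.truth_stance <- function(times, stride_hz, duty, phase0) {
  phi <- (stride_hz * times + phase0) %% 1
  r <- rle(round(phi, 9L) < duty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values] + 1L)
}

.generate_scene <- function(p, joints_fun, segments_fun, marker_names,
                            x_max, mean_velocity) {
  set.seed(p$seed)
  T_applied <- .resolve_transform(p$transform)
  bg <- .scene_background(x_max, p$background_points)
  nT <- floor(p$duration_s * p$rate$fps)
  idx <- 0:(nT - 1L)
  times <- frame_times(p$rate, idx)

  markers <- lapply(marker_names, function(nm) matrix(NA_real_, nT, 3L))
  names(markers) <- marker_names
  frames <- vector("list", nT)
  identity_T <- is.null(p$transform)
  for (i in seq_len(nT)) {
    j <- joints_fun(times[i], p)
    for (nm in marker_names) markers[[nm]][i, ] <- j[[nm]]
    body <- lapply(segments_fun(j), function(sg) {
      seg <- .render_segment(sg[[1L]], sg[[2L]], sg[[3L]], p$points_per_segment)
      .apply_sector_dropout(seg, p$dropout)
    })
    pts <- rbind(bg$points, do.call(rbind, body))
    if (p$noise_sd_m > 0)
      pts <- pts + stats::rnorm(length(pts), sd = p$noise_sd_m)
    cl <- point_cloud(pts, units = "metres", frame_index = idx[i])
    if (!identity_T) cl <- apply_transform(cl, T_applied, units = "uncalibrated")
    frames[[i]] <- cl
  }
  truth <- structure(list(
    transform = T_applied,
    scale_m_per_unit = 1 / T_applied$s,
    markers = markers,
    frames = idx,
    times = times,
    mean_velocity = mean_velocity,
    scene = list(pole = bg$pole, rail = bg$rail,
                 pole_indices = bg$pole_indices,
                 rail_indices = bg$rail_indices),
    frame_rate = p$rate),
    class = "ground_truth")
  list(sequence = cloud_sequence(frames, p$rate), truth = truth)
}

#' Generate a synthetic walker sequence
#'
#' See \code{\link{walker_params}} for the model. The returned ground truth
#' records the applied transform, the exact marker trajectories (world
#' frame, metres), per-foot stance intervals (half-open sample intervals),
#' and the mean velocity.
#'
#' @param params a \code{\link{walker_params}}.
#' @return list(sequence = \code{\link{cloud_sequence}} in reconstruction
#'   units, truth = \code{ground_truth}).
#' @export
generate_walker <- function(params) {
  if (!inherits(params, "walker_params"))
    cg_stop("parameter_error", "params must be walker_params")
  p <- params
  x_max <- if (p$mode == "overground") p$speed_ms * p$duration_s else
    p$speed_ms / p$stride_hz
  marker_names <- c("head", "shoulder", "hip", "hip_l", "hip_r",
                    "knee_l", "knee_r", "ankle_l", "ankle_r",
                    "mt5_l", "mt5_r")
  mean_v <- c(x = if (p$mode == "overground") p$speed_ms else 0, y = 0, z = 0)
  out <- .generate_scene(p, .walker_joints, .walker_segments, marker_names,
                         x_max, mean_v)
  out$truth$stance <- list(
    left = .truth_stance(out$truth$times, p$stride_hz, p$duty_factor, 0),
    right = .truth_stance(out$truth$times, p$stride_hz, p$duty_factor, 0.5))
  out$truth$params <- p
  out
}

.flyer_joints <- function(t, p) {
  th <- p$heading_deg * pi / 180
  dirg <- c(cos(th), sin(th), 0)
  body <- c(0, 0, 0.8) + (p$ground_speed_ms * t) * dirg +
    c(0, 0, p$climb_rate_ms * t)
  head <- body + 0.20 * dirg + c(0, 0, 0.02)
  tail <- body - 0.22 * dirg
  lat <- c(-dirg[2L], dirg[1L], 0)   # left of travel
  flap <- p$wingtip_amplitude_m * sin(2 * pi * p$flap_hz * t)
  sweep <- 0.05 * cos(2 * pi * p$flap_hz * t)
  wing_l <- body + (p$semispan_m + sweep) * lat + c(0, 0, flap)
  wing_r <- body - (p$semispan_m + sweep) * lat + c(0, 0, flap)
  list(head = head, body = body, tail = tail,
       wingtip_l = wing_l, wingtip_r = wing_r)
}

.flyer_segments <- function(j) {
  list(list(j$tail, j$head, 0.05),
       list(j$body, j$wingtip_l, 0.02),
       list(j$body, j$wingtip_r, 0.02))
}

#' Generate a synthetic flyer sequence
#'
#' A bird on a straight climbing path with flapping wingtips; see
#' \code{\link{flyer_params}}.
#'
#' @param params a \code{\link{flyer_params}}.
#' @return list(sequence, truth) as for \code{\link{generate_walker}}.
#' @export
generate_flyer <- function(params) {
  if (!inherits(params, "flyer_params"))
    cg_stop("parameter_error", "params must be flyer_params")
  p <- params
  p$mode <- "flyer"
  th <- p$heading_deg * pi / 180
  x_max <- max(1, p$ground_speed_ms * p$duration_s * cos(th))
  mean_v <- c(x = p$ground_speed_ms * cos(th),
              y = p$ground_speed_ms * sin(th),
              z = p$climb_rate_ms)
  out <- .generate_scene(p, .flyer_joints, .flyer_segments,
                         c("head", "body", "tail", "wingtip_l", "wingtip_r"),
                         x_max, mean_v)
  out$truth$params <- p
  out
}

#' Generate a synthetic Bundler camera rig
#'
#' Camera centres follow a jittered near-collinear rig with *exact*
#' adjacent separations of \code{spacing_m / scale_s} cloud units (the
#' physical spacing divided by the metres-per-cloud-unit scale), each
#' camera looking at the scene; extrinsics satisfy t = -R c by
#' construction.
#'
#' @param n_cameras number of cameras (>= 2).
#' @param spacing_m physical adjacent spacing, metres.
#' @param scale_s metres per cloud unit (the scale calibration should
#'   recover this).
#' @param seed RNG seed.
#' @param path optional path; when given, a bundle.out v0.3 file is
#'   written.
#' @param distance_m rig distance from the scene, metres.
#' @return object of class \code{synthetic_rig}: list(cameras,
#'   physical_separations, centres (cloud units), scale_s, path).
#' @export
generate_bundler_file <- function(n_cameras = 4L, spacing_m = 2,
                                  scale_s = 1, seed = 1L, path = NULL,
                                  distance_m = 10) {
  if (n_cameras < 2L) cg_stop("parameter_error", "need at least 2 cameras")
  if (spacing_m <= 0 || scale_s <= 0)
    cg_stop("parameter_error", "spacing_m and scale_s must be > 0")
  set.seed(seed)
  spacing_units <- spacing_m / scale_s
  centres <- matrix(NA_real_, n_cameras, 3L)
  centres[1L, ] <- c(-(n_cameras - 1) / 2 * spacing_units,
                     -distance_m / scale_s, 1.5 / scale_s)
  for (k in 2:n_cameras) {
    step <- unit(c(1, stats::rnorm(1L, 0, 0.03), stats::rnorm(1L, 0, 0.03)))
    centres[k, ] <- centres[k - 1L, ] + spacing_units * step
  }
  target <- c(0, 0, 1 / scale_s)
  cameras <- lapply(seq_len(n_cameras), function(k) {
    c_k <- centres[k, ]
    zc <- unit(target - c_k)
    up <- c(0, 0, 1)
    xc <- unit(c(zc[2L] * up[3L] - zc[3L] * up[2L],
                 zc[3L] * up[1L] - zc[1L] * up[3L],
                 zc[1L] * up[2L] - zc[2L] * up[1L]))
    yc <- c(zc[2L] * xc[3L] - zc[3L] * xc[2L],
            zc[3L] * xc[1L] - zc[1L] * xc[3L],
            zc[1L] * xc[2L] - zc[2L] * xc[1L])
    R <- rbind(xc, yc, zc)
    structure(list(focal = 1500 + stats::runif(1L, -50, 50), k1 = 0, k2 = 0,
                   R = R, t = as.numeric(-R %*% c_k), centre = c_k,
                   registered = TRUE, suspect = FALSE),
              class = "camera_pose")
  })
  if (!is.null(path)) write_bundler(cameras, path)
  structure(list(cameras = cameras,
                 physical_separations = rep(spacing_m, n_cameras - 1L),
                 centres = centres, scale_s = scale_s, path = path),
            class = "synthetic_rig")
}

#' Serialise / restore synthetic ground truth as JSON
#'
#' @param truth a \code{ground_truth} object.
#' @param path output (input) path.
#' @return \code{write_ground_truth}: \code{path} invisibly;
#'   \code{read_ground_truth}: the \code{ground_truth}.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    transform = list(R = matrix(truth$transform$R, 3L, 3L),
                     t = truth$transform$t, s = truth$transform$s),
    scale_m_per_unit = truth$scale_m_per_unit,
    markers = lapply(truth$markers, function(m) unname(as.matrix(m))),
    frames = truth$frames,
    times = truth$times,
    stance = lapply(truth$stance, function(df)
      list(start = df$start, end = df$end)),
    mean_velocity = as.list(truth$mean_velocity),
    scene = list(pole = unname(truth$scene$pole), rail = unname(truth$scene$rail),
                 pole_indices = truth$scene$pole_indices,
                 rail_indices = truth$scene$rail_indices),
    frame_rate = list(num = truth$frame_rate$num, den = truth$frame_rate$den))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- similarity_transform(R = json_matrix(o$transform$R),
                             t = o$transform$t, s = o$transform$s)
  structure(list(
    transform = tr,
    scale_m_per_unit = o$scale_m_per_unit,
    markers = lapply(o$markers, json_matrix),
    frames = o$frames,
    times = o$times,
    stance = if (!is.null(o$stance))
      lapply(o$stance, function(s) data.frame(start = s$start, end = s$end)),
    mean_velocity = unlist(o$mean_velocity),
    scene = list(pole = json_matrix(o$scene$pole),
                 rail = json_matrix(o$scene$rail),
                 pole_indices = o$scene$pole_indices,
                 rail_indices = o$scene$rail_indices),
    frame_rate = frame_rate(o$frame_rate$num, o$frame_rate$den)),
    class = "ground_truth")
}

#' Scenario presets
#'
#' Named parameter sets reproducing the four study set-ups:
#' \code{treadmill_macaque} (bipedal treadmill walk filmed at 60/1.001 fps,
#' cameras 0.35 m apart at 2.5 m), \code{rope_chimp} (overground bipedal
#' walk at 0.85 m/s, 30/1.001 fps, cameras 2 m apart at 30 m),
#' \code{plan_group} (overground walk viewed from 20 m, cameras 1.7 m
#' apart; single subject), and \code{crow} (climbing flight at 4.74 m/s
#' ground speed, 0.82 m/s climb, cameras 1.7 m apart).
#'
#' @param preset preset name.
#' @param seed RNG seed forwarded to the parameter object.
#' @param ... overrides passed to \code{\link{walker_params}} or
#'   \code{\link{flyer_params}}.
#' @return a \code{walker_params} or \code{flyer_params}; the attached
#'   \code{camera} attribute holds the rig description (spacing, count,
#'   distance).
#' @export
scenario_params <- function(preset = c("treadmill_macaque", "rope_chimp",
                                       "plan_group", "crow"),
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  camera <- switch(preset,
    treadmill_macaque = list(n_cameras = 4L, spacing_m = 0.35, distance_m = 2.5),
    rope_chimp = list(n_cameras = 4L, spacing_m = 2, distance_m = 30),
    plan_group = list(n_cameras = 4L, spacing_m = 1.7, distance_m = 20),
    crow = list(n_cameras = 4L, spacing_m = 1.7, distance_m = 30))
  base <- switch(preset,
    treadmill_macaque = list(
      mode = "treadmill", speed_ms = 0.7, stride_hz = 1, duty_factor = 0.6,
      thigh_m = 0.22, shank_m = 0.21, foot_m = 0.10, torso_m = 0.25,
      rate = frame_rate("60p"), duration_s = 8, noise_sd_m = 0.005),
    rope_chimp = list(
      mode = "overground", speed_ms = 0.85, stride_hz = 1, duty_factor = 0.6,
      thigh_m = 0.30, shank_m = 0.28, foot_m = 0.12, torso_m = 0.35,
      lateral_amplitude_m = 0.08, lift_height_m = 0.05,
      rate = frame_rate("30p"), duration_s = 10, noise_sd_m = 0.010),
    plan_group = list(
      mode = "overground", speed_ms = 0.6, stride_hz = 1.1,
      thigh_m = 0.22, shank_m = 0.21, foot_m = 0.10, torso_m = 0.25,
      rate = frame_rate("30p"), duration_s = 10, noise_sd_m = 0.010),
    crow = list(
      ground_speed_ms = 4.74, climb_rate_ms = 0.82, flap_hz = 4,
      wingtip_amplitude_m = 0.25, heading_deg = 20,
      rate = frame_rate("30p"), duration_s = 2.5, noise_sd_m = 0.010))
  overrides <- list(...)
  base[names(overrides)] <- overrides
  base$seed <- seed
  ctor <- if (preset == "crow") flyer_params else walker_params
  p <- do.call(ctor, base)
  attr(p, "camera") <- camera
  p
}

#' Write a synthetic scenario to disk
#'
#' Emits the numbered PLY sequence, a matching bundle.out, and the
#' ground-truth JSON -- the on-disk layout the measurement pipeline
#' consumes.
#'
#' @param generated list(sequence, truth) from \code{\link{generate_walker}}
#'   or \code{\link{generate_flyer}}.
#' @param folder output folder (created).
#' @param camera rig description list(n_cameras, spacing_m, distance_m).
#' @param dialect PLY dialect.
#' @return list of written paths.
#' @export
write_scenario <- function(generated, folder,
                           camera = list(n_cameras = 4L, spacing_m = 2,
                                         distance_m = 10),
                           dialect = "binary_little_endian") {
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  seqc <- generated$sequence
  ply_paths <- character(length(seqc$frames))
  for (i in seq_along(seqc$frames)) {
    f <- seqc$frames[[i]]
    ply_paths[i] <- file.path(folder, sprintf("frame%06d.ply", f$frame_index))
    write_ply(f, ply_paths[i], dialect = dialect)
  }
  bundle_path <- file.path(folder, "bundle.out")
  rig <- generate_bundler_file(
    n_cameras = camera$n_cameras, spacing_m = camera$spacing_m,
    scale_s = generated$truth$scale_m_per_unit,
    seed = generated$truth$params$seed, path = bundle_path,
    distance_m = camera$distance_m)
  truth_path <- file.path(folder, "ground_truth.json")
  write_ground_truth(generated$truth, truth_path)
  list(folder = folder, ply = ply_paths, bundle = bundle_path,
       truth = truth_path, separations = rig$physical_separations)
}
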