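# Shared fixtures, built in code.

# Geodesic angle of a rotation matrix (for recovery-error assertions).
rot_angle <- function(R) acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))

# Digitise named markers of a generated scenario, seeding each at its true
# first-frame position and measuring in the world (metre) frame.
digitise_truth_markers <- function(gen, names, radius = 0.08, min_points = 5L) {
  tr <- gen$truth
  specs <- lapply(names, function(nm)
    marker_spec(nm, tr$markers[[nm]][1L, ], radius, min_points))
  suppressWarnings(
    batch_digitise(gen$sequence, specs, T = invert_transform(tr$transform),
                   units = "metres"))
}

# A bare translating Gaussian joint cluster: the minimal digitising target.
cluster_sequence <- function(centres, sigma = 0.005, n_pts = 60L,
                             rate = frame_rate(50), seed = 1L,
                             drop_frames = integer(0)) {
  set.seed(seed)
  frames <- lapply(seq_len(nrow(centres)), function(i) {
    pts <- matrix(stats::rnorm(n_pts * 3L, sd = sigma), ncol = 3L) +
      matrix(centres[i, ], n_pts, 3L, byrow = TRUE)
    if (i %in% drop_frames)   # simulated occlusion: park the cluster far away
      pts <- pts + 100
    point_cloud(pts, units = "metres", frame_index = i - 1L)
  })
  cloud_sequence(frames, rate)
}

# Uniform random rotation matrix from a normalised quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# Elementary rotation about coordinate axis 1 (X), 2 (Y) or 3 (Z).
rotation_about_axis_test <- function(axis, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  switch(axis,
    matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3L, 3L),
    matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L),
    matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L))
}

# Sinusoid amplitude by least squares over a central window.
fitted_amplitude <- function(t, y, freq_hz, window = seq(150L, length(t) - 150L)) {
  co <- stats::lm.fit(cbind(sin(2 * pi * freq_hz * t[window]),
                            cos(2 * pi * freq_hz * t[window])),
                      y[window])$coefficients
  sqrt(sum(co^2))
}
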