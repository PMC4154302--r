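# Primitive fitting, orientation, scale calibration, similarity transforms.

cloud_of <- function(pts) point_cloud(pts)

test_that("fit_point returns the centroid of the selection", {
  cl <- cloud_of(rbind(c(1, 2, 3), c(0, 0, 0), c(2, 0, 0)))
  expect_equal(fit_point(cl, selection(indices = 1L)), c(1, 2, 3))
  expect_equal(fit_point(cl, selection(indices = 2:3)), c(1, 0, 0))

  set.seed(5)
  pts <- matrix(rnorm(3000), ncol = 3L)
  # brute-force mean by explicit summation
  oracle <- c(sum(pts[, 1L]), sum(pts[, 2L]), sum(pts[, 3L])) / nrow(pts)
  expect_equal(fit_point(cloud_of(pts), selection(indices = seq_len(1000L))),
               oracle)
  expect_error(fit_point(cloud_of(pts), selection(sphere = list(centre = c(99, 99, 99), radius = 0.1))),
               class = "selection_error")
})

test_that("fit_line recovers direction and residual for exact and noisy lines", {
  cl <- cloud_of(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  fl <- fit_line(cl, selection(indices = 1:3))
  expect_equal(fl$direction, c(1, 0, 0))
  expect_equal(fl$rms_residual, 0)

  diag_cl <- cloud_of(outer(0:4, c(1, 1, 0)))
  fd <- fit_line(diag_cl, selection(indices = 1:5))
  expect_equal(fd$direction, c(1, 1, 0) / sqrt(2))

  # 500 seeded points on a noisy line vs an independent eigendecomposition
  set.seed(9)
  t <- runif(500L, -1, 1)
  pts <- outer(t, c(0.3, -0.5, 0.81)) + matrix(rnorm(1500L, sd = 0.01), ncol = 3L)
  fl2 <- fit_line(cloud_of(pts), selection(indices = 1:500))
  C <- stats::cov(pts) * (499 / 500)
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1L]
  ang <- acos(min(1, abs(sum(fl2$direction * ev))))
  expect_lt(ang, 1e-6)

  expect_error(fit_line(cloud_of(rbind(c(1, 1, 1), c(1, 1, 1))),
                        selection(indices = 1:2)),
               class = "degenerate_fit_error")
})

test_that("fit_line sign follows the first-to-last selected point", {
  cl <- cloud_of(rbind(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(fit_line(cl, selection(indices = 1:3))$direction, c(-1, 0, 0))
})

test_that("near-isotropic selections raise an ambiguous-fit warning", {
  sq <- cloud_of(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)))
  expect_warning(fit_line(sq, selection(indices = 1:4)),
                 class = "ambiguous_fit_warning")
})

test_that("fit_plane recovers the normal, point and residual", {
  cl <- cloud_of(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  fp <- fit_plane(cl, selection(indices = 1:3))
  expect_equal(abs(fp$normal), c(0, 0, 1))

  sq5 <- cloud_of(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 5))
  f5 <- fit_plane(sq5, selection(indices = 1:4))
  expect_equal(f5$point[3L], 5)
  expect_equal(abs(f5$normal), c(0, 0, 1))
  expect_equal(f5$rms_residual, 0)

  set.seed(13)
  u <- runif(400L, -1, 1); v <- runif(400L, -1, 1)
  e1 <- c(1, 0, 0.2); e2 <- c(0, 1, -0.1)
  pts <- outer(u, e1) + outer(v, e2) + matrix(rnorm(1200L, sd = 0.01), ncol = 3L)
  fp2 <- fit_plane(cloud_of(pts), selection(indices = 1:400))
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 3L]
  expect_lt(acos(min(1, abs(sum(fp2$normal * ev)))), 1e-6)

  line_cl <- cloud_of(outer(1:5, c(1, 2, 3)))
  expect_error(fit_plane(line_cl, selection(indices = 1:5)),
               class = "degenerate_fit_error")
})

test_that("rotation_to_vertical sends any direction to +Z, with the declared antiparallel convention", {
  expect_equal(rotation_to_vertical(c(0, 0, 5))$R, diag(3))
  R90 <- rotation_to_vertical(c(1, 0, 0))$R
  expect_equal(as.numeric(R90 %*% c(1, 0, 0)), c(0, 0, 1))
  expect_equal(rot_angle(R90), pi / 2)
  Rap <- rotation_to_vertical(c(0, 0, -1))$R
  expect_equal(as.numeric(Rap %*% c(0, 0, -1)), c(0, 0, 1))
  expect_equal(Rap, diag(c(1, -1, -1)))   # 180 degrees about +X
  expect_error(rotation_to_vertical(c(0, 0, 0)), class = "degenerate_input_error")
})

test_that("rotation_about_z_to_x aligns the horizontal component with +X", {
  expect_equal(rotation_about_z_to_x(c(1, 0, 0))$R, diag(3))
  Rm <- rotation_about_z_to_x(c(0, 1, 0))$R
  expect_equal(as.numeric(Rm %*% c(0, 1, 0)), c(1, 0, 0))
  Rd <- rotation_about_z_to_x(c(1, 1, 0.3))$R
  expect_equal(as.numeric(Rd %*% c(1, 1, 0.3)), c(sqrt(2), 0, 0.3))
  expect_error(rotation_about_z_to_x(c(0, 0, 1)), class = "degenerate_input_error")
})

test_that("orient_cloud is the identity on an already-oriented scene", {
  set.seed(3)
  vert <- outer(runif(40L), c(0, 0, 1)) + matrix(c(0.5, 0.5, 0), 40L, 3L, byrow = TRUE)
  trav <- outer(runif(40L), c(1, 0, 0)) + matrix(c(0, 0, 0.1), 40L, 3L, byrow = TRUE)
  cl <- point_cloud(rbind(vert, trav))
  T <- orient_cloud(cl, selection(indices = 1:40), selection(indices = 41:80),
                    up_hint = c(0, 0, 1), forward_hint = c(1, 0, 0))
  expect_lt(rot_angle(T$R), 1e-9)
})

test_that("orient_cloud inverts a known rotation on a pre-rotated scene", {
  set.seed(21)
  for (rep in 1:3) {
    R_true <- random_rotation()
    vert <- outer(runif(50L), c(0, 0, 2))
    trav <- outer(runif(50L), c(3, 0, 0)) + matrix(c(0, 0.8, 0.1), 50L, 3L, byrow = TRUE)
    pts <- rbind(vert, trav) %*% t(R_true)
    cl <- point_cloud(pts)
    T <- orient_cloud(cl, selection(indices = 1:50), selection(indices = 51:100),
                      up_hint = as.numeric(R_true %*% c(0, 0, 1)),
                      forward_hint = as.numeric(R_true %*% c(1, 0, 0)))
    expect_lt(rot_angle(T$R %*% R_true), 1e-6)
  }
})

test_that("travel direction sign is flipped so motion proceeds toward +X", {
  set.seed(4)
  vert <- outer(runif(30L), c(0, 0, 1))
  # travel selection ordered so the fit's raw direction points toward -X
  trav <- outer(seq(1, 0, length.out = 30L), c(1, 0, 0)) +
    matrix(c(0, 0.5, 0), 30L, 3L, byrow = TRUE)
  cl <- point_cloud(rbind(vert, trav))
  T <- orient_cloud(cl, selection(indices = 1:30), selection(indices = 31:60),
                    up_hint = c(0, 0, 1), forward_hint = c(1, 0, 0))
  expect_equal(as.numeric(T$R %*% c(1, 0, 0)), c(1, 0, 0), tolerance = 1e-9)
})

test_that("scale factors follow the known-distance ratio", {
  expect_equal(scale_from_known_distance(c(0, 0, 0), c(2.5, 0, 0), 1), 0.4)
  expect_equal(scale_from_known_distance(c(0, 0, 0), c(1, 0, 0), 1), 1)
  expect_error(scale_from_known_distance(c(1, 1, 1), c(1, 1, 1), 1),
               class = "degenerate_input_error")
})

test_that("camera-separation scale uses the ratio of means", {
  # two cameras 0.5 units apart, taped at 2 m: s = 4 (the rope set-up used
  # 2 m spacing between cameras)
  rig <- generate_bundler_file(2, spacing_m = 2, scale_s = 4, seed = 1)
  f <- withr::local_tempfile()
  cloudgait:::write_bundler(rig$cameras, f)
  expect_equal(scale_from_camera_separation(read_bundler(f), c(2)), 4,
               tolerance = 1e-12)

  # four cameras, cloud spacing 1 unit, physical spacing 1.7 m -> s = 1.7
  rig4 <- generate_bundler_file(4, spacing_m = 1.7, scale_s = 1.7, seed = 2)
  g <- withr::local_tempfile()
  cloudgait:::write_bundler(rig4$cameras, g)
  expect_equal(camera_separations(read_bundler(g)), rep(1, 3L),
               tolerance = 1e-12)
  expect_equal(scale_from_camera_separation(read_bundler(g), rep(1.7, 3)), 1.7,
               tolerance = 1e-12)
  expect_error(scale_from_camera_separation(read_bundler(g), c(1.7)),
               class = "input_error")
})

test_that("similarity transforms compose, invert and scale distances exactly", {
  set.seed(17)
  T1 <- similarity_transform(R = random_rotation(), t = rnorm(3L), s = 2.5)
  pts <- matrix(rnorm(300L), ncol = 3L)
  cl <- point_cloud(pts, normals = matrix(rep(c(0, 0, 1), each = 100L), ncol = 3L))

  moved <- apply_transform(cl, T1)
  back <- apply_transform(moved, invert_transform(T1))
  expect_equal(back$points, cl$points, tolerance = 1e-9)

  # pairwise distances scale exactly by s
  d0 <- as.numeric(stats::dist(pts[1:20, ]))
  d1 <- as.numeric(stats::dist(moved$points[1:20, ]))
  expect_equal(d1, 2.5 * d0, tolerance = 1e-9)
  # normals rotate but stay unit length
  expect_equal(sqrt(rowSums(moved$normals^2)), rep(1, 100L), tolerance = 1e-12)

  T2 <- similarity_transform(R = random_rotation(), t = rnorm(3L), s = 0.3)
  x <- rnorm(3L)
  expect_equal(apply_transform(apply_transform(x, T1), T2),
               apply_transform(x, compose_transform(T2, T1)), tolerance = 1e-9)

  f <- withr::local_tempfile(fileext = ".json")
  write_transform(T1, f)
  T1b <- read_transform(f)
  expect_equal(T1b$R, T1$R)
  expect_equal(T1b$t, T1$t)
  expect_equal(T1b$s, T1$s)
})
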