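# PLY, Bundler, sequence-folder and marker-XML I/O.

test_that("ASCII PLY identity parse and PMVS dialect colours", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 2 3"), f)
  cl <- read_ply(f)
  expect_equal(cl$points, rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_null(cl$colours)

  # PMVS-style vertex: normals plus diffuse_* colour naming, hand-written
  # byte-for-byte, read back field by field
  g <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "comment PMVS output",
               "element vertex 1",
               "property float x", "property float y", "property float z",
               "property float nx", "property float ny", "property float nz",
               "property uchar diffuse_red", "property uchar diffuse_green",
               "property uchar diffuse_blue", "end_header",
               "0.5 -1.25 2 0 0 1 10 20 30"), g)
  cl <- read_ply(g)
  expect_equal(cl$points, matrix(c(0.5, -1.25, 2), 1L))
  expect_equal(cl$normals, matrix(c(0, 0, 1), 1L))
  expect_identical(cl$colours, matrix(c(10L, 20L, 30L), 1L))

  # on write, colours are emitted under the standard red/green/blue naming
  h <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl, h, dialect = "ascii")
  hdr <- readLines(h, n = 12L)
  expect_true(any(grepl("^property uchar red$", hdr)))
  expect_false(any(grepl("diffuse", hdr)))
})

test_that("binary little-endian PLY round-trips bit-for-bit", {
  set.seed(42)
  n <- 1e4L
  cl <- point_cloud(matrix(rnorm(3L * n), ncol = 3L),
                    colours = matrix(sample(0:255, 3L * n, TRUE), ncol = 3L),
                    normals = matrix(rep(c(0, 0, 1), each = n), ncol = 3L))
  f <- withr::local_tempfile(fileext = ".ply")
  g <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl, f)
  c1 <- read_ply(f)
  write_ply(c1, g)
  c2 <- read_ply(g)
  expect_identical(c1$points, c2$points)
  expect_identical(c1$colours, c2$colours)
  expect_identical(c1$normals, c2$normals)
  # ASCII holds 9 significant digits
  a <- withr::local_tempfile(fileext = ".ply")
  write_ply(c1, a, dialect = "ascii")
  expect_equal(read_ply(a)$points, c1$points, tolerance = 1e-8)
})

test_that("PLY reader rejects malformed files loudly", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property float x", "property float y",
               "end_header", "0 0"), f)
  expect_error(read_ply(f), "missing property 'z'", class = "ply_format_error")

  g <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format binary_big_endian 1.0", "element vertex 1",
               "property float x", "property float y", "property float z",
               "end_header"), g)
  expect_error(read_ply(g), class = "ply_unsupported_dialect_error")

  # truncated binary payload reports expected vs actual byte count
  h <- withr::local_tempfile(fileext = ".ply")
  cl <- point_cloud(matrix(rnorm(30), ncol = 3L))
  write_ply(cl, h)
  bytes <- readBin(h, "raw", file.size(h))
  writeBin(bytes[seq_len(length(bytes) - 10L)], h)
  expect_error(read_ply(h), "expected .* bytes", class = "io_error")
})

test_that("load_sequence sorts by embedded frame number and records gaps", {
  dir <- withr::local_tempdir()
  cl <- function(i) point_cloud(matrix(c(i, 0, 0), 1L), frame_index = i)
  write_ply(cl(0), file.path(dir, "frame000000.ply"))
  write_ply(cl(2), file.path(dir, "frame000002.ply"))
  s <- load_sequence(dir, "frame*.ply", rate = frame_rate(50))
  expect_identical(s$frame_indices, c(0L, 2L))
  expect_identical(s$missing, 1L)

  dir2 <- withr::local_tempdir()
  for (i in sample(10:19)) write_ply(cl(i), file.path(dir2, sprintf("out_%d.ply", i)))
  s2 <- load_sequence(dir2, "out_*.ply", rate = frame_rate(50))
  expect_identical(s2$frame_indices, 10:19)
  expect_equal(vapply(s2$frames, function(f) f$points[1L], 0), as.numeric(10:19))

  expect_error(load_sequence(dir2, "nope*.ply", rate = frame_rate(50)),
               class = "empty_sequence_error")
  write_ply(cl(11), file.path(dir2, "out_011.ply"))  # same frame number twice
  expect_error(load_sequence(dir2, "out_*.ply", rate = frame_rate(50)),
               class = "ambiguous_sequence_error")
})

test_that("rational frame rates give drift-free uniform timestamps", {
  r <- frame_rate("30p")
  expect_identical(c(r$num, r$den), c(30000L, 1001L))
  s <- cloud_sequence(lapply(0:99, function(i)
    point_cloud(matrix(c(0, 0, 0), 1L), frame_index = i)), r)
  tt <- sequence_times(s)
  expect_equal(diff(tt), rep(1001 / 30000, 99L), tolerance = 1e-12)
  expect_error(frame_rate(0), class = "invalid_frame_rate_error")
})

test_that("Bundler parsing derives optical centres satisfying R c + t = 0", {
  f <- withr::local_tempfile()
  writeLines(c("# Bundle file v0.3", "1 0",
               "800 0 0", "1 0 0", "0 1 0", "0 0 1", "1 2 3"), f)
  b <- read_bundler(f)
  expect_equal(b$cameras[[1L]]$centre, c(-1, -2, -3))

  # seeded random rigs against an independent linear solve
  set.seed(7)
  cams <- lapply(1:4, function(i) {
    R <- random_rotation()
    list(focal = 1000, k1 = 0, k2 = 0, R = R, t = rnorm(3L))
  })
  g <- withr::local_tempfile()
  cloudgait:::write_bundler(cams, g)
  parsed <- read_bundler(g)
  for (i in 1:4) {
    cam <- parsed$cameras[[i]]
    oracle <- solve(cam$R, -cam$t)   # independent 3x3 linear solve
    expect_equal(cam$centre, oracle, tolerance = 1e-9)
    expect_lt(sqrt(sum((cam$R %*% cam$centre + cam$t)^2)),
              1e-9 * (1 + sqrt(sum(cam$t^2))))
  }
})

test_that("unregistered (f = 0) cameras are excluded from separations", {
  f <- withr::local_tempfile()
  writeLines(c("# Bundle file v0.3", "3 0",
               "800 0 0", "1 0 0", "0 1 0", "0 0 1", "0 0 0",
               "0 0 0",   "1 0 0", "0 1 0", "0 0 1", "0 0 0",
               "800 0 0", "1 0 0", "0 1 0", "0 0 1", "-1 0 0"), f)
  b <- read_bundler(f)
  expect_false(b$cameras[[2L]]$registered)
  expect_equal(camera_separations(b), 1)   # only the two registered centres
})

test_that("truncated Bundler camera blocks raise a parse error", {
  f <- withr::local_tempfile()
  writeLines(c("2 0", "800 0 0", "1 0 0", "0 1 0", "0 0 1", "0 0 0",
               "800 0 0", "1 0 0"), f)
  expect_error(read_bundler(f), class = "bundler_parse_error")
})

test_that("marker XML round-trips every stored value exactly", {
  r <- frame_rate("60p")
  doc <- marker_document(list(
    list(index = 0L, file = "frame0.ply", time = 0,
         markers = list(hip = c(0.1, -0.2, 0.93))),
    list(index = 1L, file = "frame1.ply", time = 1001 / 60000,
         markers = list())   # all markers occluded: frame kept, empty
  ), r, units = "metres")
  f <- withr::local_tempfile(fileext = ".xml")
  write_markers(doc, f)
  back <- read_markers(f)
  expect_identical(back$frames[[1L]]$markers$hip, c(0.1, -0.2, 0.93))
  expect_length(back$frames[[2L]]$markers, 0L)
  expect_identical(c(back$frame_rate$num, back$frame_rate$den),
                   c(60000L, 1001L))

  # 100-frame, 7-marker seeded document
  set.seed(11)
  nm <- paste0("m", 1:7)
  frames <- lapply(0:99, function(i) {
    mk <- lapply(nm, function(x) rnorm(3L))
    names(mk) <- nm
    list(index = i, file = sprintf("f%03d.ply", i), time = i * 1001 / 60000,
         markers = mk)
  })
  doc2 <- marker_document(frames, r)
  g <- withr::local_tempfile(fileext = ".xml")
  write_markers(doc2, g)
  back2 <- read_markers(g)
  for (i in c(1L, 50L, 100L))
    expect_identical(back2$frames[[i]]$markers, doc2$frames[[i]]$markers)
})

test_that("marker documents reject schema violations", {
  r <- frame_rate(50)
  expect_error(
    marker_document(list(list(index = 0L, file = "", time = 0,
                              markers = list(a = c(0, 0, 0), a = c(1, 1, 1)))), r),
    class = "marker_validation_error")
  doc <- marker_document(list(list(index = 0L, file = "", time = 0,
                                   markers = list(a = c(0, 0, 0)))), r)
  f <- withr::local_tempfile(fileext = ".xml")
  write_markers(doc, f)
  txt <- sub('marker_document version="1.0"', 'marker_document version="9.9"',
             readLines(f))
  writeLines(txt, f)
  expect_error(read_markers(f), class = "marker_schema_error")
})

test_that("marker CSV export is one row per frame with empty missing cells", {
  s1 <- marker_series("hip", c(0L, 1L, 2L),
                      rbind(c(0, 0, 1), c(NA, NA, NA), c(2, 0, 1)),
                      units = "metres")
  f <- withr::local_tempfile(fileext = ".csv")
  write_marker_csv(list(hip = s1), frame_rate(50), f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), 3L)
  expect_true(is.na(df$hip_x[2L]))
  expect_equal(df$hip_x[3L], 2)
})
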