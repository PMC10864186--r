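test_that("TIFF stacks round-trip through write/read", {
  set.seed(1)
  arr <- array(runif(5 * 32 * 32), c(32, 32, 5))
  seq <- image_sequence(arr)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(seq, path, dtype_policy = "float32")
  back <- read_image_stack(path)
  expect_equal(dim(back$frames), dim(arr))
  expect_lt(max(abs(back$frames - arr)), 1e-6)

  # integer data round-trips bit-exactly under "preserve"
  ints <- array(sample(0:65535, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  write_image_stack(image_sequence(ints), path, dtype_policy = "preserve")
  expect_identical(read_image_stack(path)$frames, ints + 0)
})

test_that("single-page and 4-D TIFF stacks keep their axes", {
  path <- withr::local_tempfile(fileext = ".tif")
  one <- image_sequence(matrix(runif(64), 8, 8))
  write_image_stack(one, path, dtype_policy = "float32")
  expect_equal(n_frames(read_image_stack(path)), 1L)

  vol <- volume_sequence(array(runif(8 * 8 * 3 * 4), c(8, 8, 3, 4)))
  write_image_stack(vol, path, dtype_policy = "float32")
  back <- read_image_stack(path, n_z = 3)
  expect_s3_class(back, "volume_sequence")
  expect_equal(dim(back$frames), c(8, 8, 3, 4))
  expect_lt(max(abs(back$frames - vol$frames)), 1e-6)
})

test_that("invalid image input is rejected", {
  expect_error(read_image_stack("no/such/file.tif"), "not found")
  expect_error(write_image_stack(image_sequence(matrix(0, 4, 4)), ""),
               "path")
  bad <- image_sequence(matrix(1, 4, 4))
  bad$frames[1] <- NaN
  expect_error(write_image_stack(bad, withr::local_tempfile()), "finite")
  expect_error(image_sequence(array(NA_real_, c(2, 2, 1))), "finite")
})

test_that("track XML round-trips and reports malformed detections", {
  set.seed(2)
  ts <- track_list_to_set(random_track_list(3))
  path <- withr::local_tempfile(fileext = ".xml")
  write_isbi_xml(ts, path)
  back <- read_isbi_xml(path)
  expect_equal(n_tracks(back), 3L)
  a <- ts$detections[order(ts$detections$track_id, ts$detections$frame), ]
  b <- back$detections
  expect_equal(b$frame, a$frame)
  expect_equal(b$x, a$x, tolerance = 1e-12)
  expect_equal(b$y, a$y, tolerance = 1e-12)

  single <- track_set(data.frame(track_id = "a", frame = 5, x = 1.5, y = 2.5))
  write_isbi_xml(single, path)
  back <- read_isbi_xml(path)
  expect_equal(nrow(back$detections), 1L)
  expect_equal(back$detections$frame, 5L)

  writeLines(c("<root><TrackContestISBI2012><particle>",
               '<detection t="0" y="1" z="0"/>',
               "</particle></TrackContestISBI2012></root>"), path)
  expect_error(read_isbi_xml(path), "missing attribute 'x'")
})

test_that("track tables round-trip and validate columns", {
  set.seed(3)
  ts <- track_list_to_set(random_track_list(4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_table(ts, path)
  expect_true(tracks_equal_fi(read_tracks_table(path), ts))

  file.create(empty <- withr::local_tempfile(fileext = ".csv"))
  expect_equal(n_tracks(read_tracks_table(empty)), 0L)

  writeLines(c("track_id,frame,x,y,z", "a,0,oops,2,0"), path)
  expect_error(read_tracks_table(path), "non-numeric")
  writeLines(c("track_id,frame,y,z", "a,0,2,0"), path)
  expect_error(read_tracks_table(path), "missing column")
})

test_that("max projection dominates every slice and preserves extremes", {
  set.seed(4)
  vol <- volume_sequence(array(runif(6 * 7 * 3 * 2), c(6, 7, 3, 2)))
  proj <- max_project_z(vol)
  for (t in 1:2) {
    for (z in 1:3) {
      expect_true(all(proj$frames[, , t] >= vol$frames[, , z, t]))
    }
    expect_equal(proj$frames[, , t],
                 pmax(vol$frames[, , 1, t], vol$frames[, , 2, t],
                      vol$frames[, , 3, t]))
  }
  # constant volume projects to the same constant
  cvol <- volume_sequence(array(3.5, c(4, 4, 2, 2)))
  expect_true(all(max_project_z(cvol)$frames == 3.5))
  # two disjoint bright spots in different slices both survive
  spots <- array(0, c(8, 8, 2, 1))
  spots[2, 2, 1, 1] <- 1
  spots[6, 6, 2, 1] <- 2
  p <- max_project_z(volume_sequence(spots))$frames[, , 1]
  expect_equal(p[2, 2], 1)
  expect_equal(p[6, 6], 2)
})

test_that("global min-max normalization fixes the data range", {
  seq <- image_sequence(array(c(0, 127.5, 255), c(1, 3, 1)))
  n <- normalize_sequence(seq, "minmax_global")
  expect_equal(range(n$frames), c(0, 1))
  expect_equal(n$frames[1, 2, 1], 0.5)
  expect_identical(normalize_sequence(seq, "none"), seq)
  expect_warning(z <- normalize_sequence(image_sequence(array(2, c(2, 2, 2)))),
                 "constant")
  expect_true(all(z$frames == 0))
})

test_that("random stacks and track sets survive io round trips", {
  set.seed(5)
  for (k in 1:5) {
    ts <- track_list_to_set(random_track_list(sample(1:5, 1)))
    p <- withr::local_tempfile(fileext = ".xml")
    write_isbi_xml(ts, p)
    expect_equal(nrow(read_isbi_xml(p)$detections), nrow(ts$detections))
    arr <- array(sample(0:4095, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    p2 <- withr::local_tempfile(fileext = ".tif")
    write_image_stack(image_sequence(arr), p2)
    expect_identical(read_image_stack(p2)$frames, arr + 0)
  }
})
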