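test_that("classical interpolators satisfy their closed forms", {
  A <- matrix(0, 8, 8)
  B <- matrix(1, 8, 8)
  expect_identical(interp_duplicate(A, B), A)
  expect_identical(interp_duplicate(B, B), B)
  expect_equal(rmse(interp_duplicate(A, B), A), 0)
  expect_true(all(interp_blend(A, B, 0.5) == 0.5))
  expect_true(all(interp_blend(A, B, 0.25) == 0.25))
  expect_identical(interp_blend(A, A), A)
  # cubic reproduces constants and linear ramps ...
  expect_true(all(interp_cubic(A + 3, A + 3, A + 3, A + 3) == 3))
  expect_true(all(abs(interp_cubic(A, A + 1, A + 2, A + 3, 0.5) - 1.5) < 1e-12))
  # ... and is exact on quadratics-in-time (Catmull-Rom closed form)
  q <- function(t) 2 * t^2 - 3 * t + 1
  out <- interp_cubic(A + q(-1), A + q(0), A + q(1), A + q(2), 0.5)
  expect_equal(out[1, 1], q(0.5), tolerance = 1e-12)
  for (t in c(0.25, 0.75)) {
    out <- interp_cubic(A + q(-1), A + q(0), A + q(1), A + q(2), t)
    expect_equal(out[1, 1], q(t), tolerance = 1e-12)
  }
})

test_that("flow estimation recovers global translations", {
  tex <- make_texture(96, 96, seed = 13)
  A <- tex()
  fl <- estimate_flow(A, tex(c(3, 0)))
  expect_lt(abs(median(fl$u) - 3), 0.5)
  expect_lt(abs(median(fl$v)), 0.5)
  fl2 <- estimate_flow(A, tex(c(8, -5)))
  expect_lt(abs(median(fl2$u) - 8), 0.5)
  expect_lt(abs(median(fl2$v) + 5), 0.5)
  same <- estimate_flow(A, A)
  expect_lt(max(abs(same$u), abs(same$v)), 0.05)
  expect_warning(zf <- estimate_flow(matrix(1, 32, 32), matrix(1, 32, 32)),
                 "constant")
  expect_true(all(zf$u == 0))
})

test_that("flow contract: mean endpoint error below half a pixel to 12 px", {
  tex <- make_texture(128, 128, seed = 7)
  A <- tex()
  for (s in list(c(1, 1), c(6, -3), c(12, 7))) {
    fl <- estimate_flow(A, tex(s))
    epe <- mean(sqrt((fl$u - s[1])^2 + (fl$v - s[2])^2))
    expect_lt(epe, 0.5)
  }
})

test_that("warping follows the flow with edge replication", {
  img <- outer(1:10, 1:12, function(i, j) j + 0 * i)  # horizontal ramp
  zero <- flow_field(matrix(0, 10, 12), matrix(0, 10, 12))
  expect_identical(warp_frame(img, zero), img)
  one_right <- flow_field(matrix(1, 10, 12), matrix(0, 10, 12))
  shifted <- warp_frame(img, one_right, 1)
  expect_equal(shifted[, 1:11], img[, 2:12])
  expect_equal(shifted[, 12], img[, 12])  # replicated edge
  expect_identical(warp_frame(img, one_right, 0), img)
  bad <- flow_field(matrix(NaN, 10, 12), matrix(0, 10, 12))
  expect_error(warp_frame(img, bad), "finite")
})

test_that("consistency weights follow the declared kernel", {
  u <- matrix(2, 6, 6)
  z <- matrix(0, 6, 6)
  fwd <- flow_field(u, z)
  bwd <- flow_field(-u, z)
  expect_true(all(consistency_weights(fwd, bwd) == 1))
  # uniform inconsistency e: F_ba = -F_ab + e
  for (e in c(0.5, 1, 2)) {
    w <- consistency_weights(fwd, flow_field(-u + e, z), scale = 1)
    expect_equal(w[3, 3], exp(-e^2), tolerance = 1e-12)
    expect_lt(w[3, 3], 1)
  }
  # larger scale forgives the same inconsistency
  expect_gt(consistency_weights(fwd, flow_field(-u + 1, z), scale = 2)[3, 3],
            consistency_weights(fwd, flow_field(-u + 1, z), scale = 1)[3, 3])
})

test_that("motion-compensated midframe beats blending on translating scenes", {
  tex <- make_texture(128, 128, seed = 17)
  rng <- range(tex())
  for (s in c(2, 6)) {
    A <- tex()
    G <- tex(c(s, -s / 2))
    B <- tex(c(2 * s, -s))
    mid <- cafi_midframe(A, B)
    r_cafi <- rmse(mid, G) / diff(rng)
    r_blend <- rmse(interp_blend(A, B), G) / diff(rng)
    expect_lt(r_cafi, 0.02)
    expect_lt(r_cafi, r_blend)
  }
  # static scene is reproduced exactly
  A <- tex()
  expect_equal(cafi_midframe(A, A), A, tolerance = 1e-12)
})

test_that("midframe places opposite-moving particles at their midpoints", {
  cfg <- simulation_config(width = 96, height = 96, n_frames = 1,
                           n_particles = 0, diameter = 11, seed = 1)
  mk <- function(off) render_frame(
    data.frame(x = c(24 + off, 72 - off), y = c(30, 64)), cfg)
  A <- mk(0)
  B <- mk(4)
  mid <- cafi_midframe(A, B)
  spots <- detect_spots_log(image_sequence(mid), diameter = 11,
                            threshold = 0.05)
  expect_equal(nrow(spots), 2L)
  spots <- spots[order(spots$x), ]
  expect_lt(abs(spots$x[1] - 26), 1)
  expect_lt(abs(spots$y[1] - 30), 1)
  expect_lt(abs(spots$x[2] - 70), 1)
  expect_lt(abs(spots$y[2] - 64), 1)
})

test_that("sequence interpolation preserves anchors and length laws", {
  set.seed(31)
  seq <- image_sequence(array(runif(16 * 16 * 9), c(16, 16, 9)))
  for (m in c("none", "bil", "bic")) {
    out <- interpolate_sequence(seq, m)
    expect_equal(n_frames(out), 17L)
    expect_identical(out$frames[, , seq(1, 17, 2)], seq$frames)
  }
  for (f in c(2, 4, 8, 16)) {
    up <- icafi(seq, "bil", f)
    expect_equal(n_frames(up), f * 8L + 1L)
    expect_identical(downsample_axis(up, f)$frames, seq$frames)
  }
  expect_identical(icafi(seq, "bil", 2)$frames,
                   interpolate_sequence(seq, "bil")$frames)
  expect_error(icafi(seq, "bil", 3), "factor")
  expect_error(interpolate_sequence(image_sequence(matrix(0, 4, 4)), "bil"),
               "two frames")
})

test_that("static sequences are fixed points of every method", {
  frame <- make_texture(32, 32, seed = 3)()
  seq <- image_sequence(array(rep(frame, 5), c(32, 32, 5)))
  for (m in c("none", "bil", "bic", "cafi")) {
    out <- interpolate_sequence(seq, m)
    expect_equal(n_frames(out), 9L)
    for (i in 1:9) expect_equal(out$frames[, , i], frame, tolerance = 1e-12)
  }
  const <- image_sequence(array(2, c(16, 16, 3)))
  out <- suppressWarnings(interpolate_sequence(const, "cafi"))
  expect_true(all(out$frames == 2))
})

test_that("z interpolation equals t interpolation after transposition", {
  set.seed(41)
  arr <- array(runif(12 * 12 * 5 * 3), c(12, 12, 5, 3))
  vol <- volume_sequence(arr)
  out_z <- interpolate_sequence(vol, "bil", axis = "z")
  expect_equal(dim(out_z$frames), c(12, 12, 9, 3))
  for (t in 1:3) {
    as_t <- interpolate_sequence(image_sequence(arr[, , , t]), "bil")
    expect_identical(out_z$frames[, , , t], as_t$frames)
  }
  out_t <- interpolate_sequence(vol, "bil", axis = "t")
  expect_equal(dim(out_t$frames), c(12, 12, 5, 5))
  for (z in 1:5) {
    as_t <- interpolate_sequence(image_sequence(arr[, , z, ]), "bil")
    expect_identical(out_t$frames[, , z, ], as_t$frames)
  }
  # requesting the wrong axis on a planar sequence is an error
  seq_t <- image_sequence(array(0, c(8, 8, 3)))
  expect_error(interpolate_sequence(seq_t, "bil", axis = "z"), "axis")
})

test_that("downsampling keeps the anchor grid and exposes held-out frames", {
  seq <- image_sequence(array(seq_len(4 * 4 * 225) %% 7, c(4, 4, 225)))
  expect_equal(n_frames(downsample_axis(seq, 16)), 15L)
  expect_equal(n_frames(downsample_axis(seq, 2)), 113L)
  s89 <- image_sequence(array(0, c(4, 4, 89)))
  expect_equal(n_frames(downsample_axis(s89, 4)), 23L)
  expect_identical(downsample_axis(downsample_axis(seq, 2), 2)$frames,
                   downsample_axis(seq, 4)$frames)
  ho <- held_out_frames(seq, 2)
  expect_equal(ho$indices, seq(1, 223, by = 2))
  expect_identical(ho$sequence$frames, seq$frames[, , seq(2, 224, 2)])
})

test_that("velocity series follow the stride-and-truncate convention", {
  seq <- image_sequence(array(rep(0:224, each = 4), c(2, 2, 225)))
  v5 <- make_velocity_series(seq, 5)
  expect_equal(n_frames(v5), 17L)
  expect_equal(v5$frames[1, 1, ], seq(0, 80, by = 5))
  v2 <- make_velocity_series(seq, 2)
  expect_equal(v2$frames[1, 1, ], seq(0, 32, by = 2))
  v13 <- make_velocity_series(seq, 13)
  expect_equal(n_frames(v13), 17L)
  expect_equal(v13$frames[1, 1, 17], 208)
  expect_error(make_velocity_series(seq, 15), "too short")
})
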