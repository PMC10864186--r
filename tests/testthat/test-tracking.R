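test_that("assignment solver matches exhaustive enumeration", {
  set.seed(60)
  for (k in 1:100) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    a <- solve_lap(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), ref_lap_cost(cost),
                 tolerance = 1e-12)
  }
  # forbidden entries are avoided when a feasible assignment exists
  cost <- rbind(c(Inf, 1), c(1, Inf))
  expect_equal(solve_lap(cost), c(2L, 1L))
})

test_that("spot detection finds rendered spots to subpixel accuracy", {
  cfg <- simulation_config(width = 64, height = 64, n_frames = 1,
                           n_particles = 0, diameter = 10, seed = 1)
  truth <- data.frame(x = c(20.3, 44.7), y = c(31.6, 12.2))
  frame <- render_frame(truth, cfg)
  spots <- detect_spots_log(image_sequence(frame), diameter = 10,
                            threshold = 0.05)
  expect_equal(nrow(spots), 2L)
  spots <- spots[order(spots$x), ]
  expect_lt(max(abs(spots$x - truth$x)), 0.5)
  expect_lt(max(abs(spots$y - truth$y)), 0.5)
  # blank frames and absurd thresholds yield no detections
  blank <- image_sequence(matrix(0, 64, 64))
  expect_equal(nrow(detect_spots_log(blank, 10, 0.05)), 0L)
  expect_equal(nrow(detect_spots_log(image_sequence(frame), 10, 1e6)), 0L)
})

test_that("linking connects plausible steps and respects the gate", {
  steps <- data.frame(frame = 0:4, x = 10 + 3 * (0:4), y = 20,
                      quality = 1)
  tr <- link_frames(steps, link_config(linking_distance = 25))
  expect_equal(n_tracks(tr), 1L)
  expect_equal(nrow(tr$detections), 5L)
  # a jump beyond the gate splits the trajectory
  jump <- data.frame(frame = 0:2, x = c(0, 3, 60), y = 0, quality = 1)
  tr2 <- link_frames(jump, link_config(linking_distance = 10))
  expect_equal(n_tracks(tr2), 2L)
})

test_that("crossing particles are assigned with minimum total cost", {
  set.seed(61)
  for (k in 1:100) {
    n1 <- sample(1:4, 1)
    n2 <- sample(1:4, 1)
    gate <- runif(1, 5, 15)
    s1 <- data.frame(frame = 0, x = runif(n1, 0, 30), y = runif(n1, 0, 30),
                     quality = 1)
    s2 <- data.frame(frame = 1, x = runif(n2, 0, 30), y = runif(n2, 0, 30),
                     quality = 1)
    tr <- link_frames(rbind(s1, s2), link_config(linking_distance = gate,
                                                 max_frame_gap = 0))
    # recompute the realized cost of the returned linking
    cost <- 0
    linked1 <- linked2 <- 0L
    for (d in split(tr$detections, tr$detections$track_id)) {
      if (nrow(d) == 2L) {
        cost <- cost + (d$x[1] - d$x[2])^2 + (d$y[1] - d$y[2])^2
        linked1 <- linked1 + 1L
        linked2 <- linked2 + 1L
      }
    }
    cost <- cost + gate^2 * ((n1 - linked1) + (n2 - linked2))
    # exhaustive minimum over all injective partial matchings
    best <- Inf
    d2 <- outer(s1$x, s2$x, "-")^2 + outer(s1$y, s2$y, "-")^2
    subsets <- expand.grid(rep(list(c(0L, seq_len(n2))), n1))
    for (r in seq_len(nrow(subsets))) {
      m <- as.integer(subsets[r, ])
      picked <- m[m > 0]
      if (anyDuplicated(picked)) next
      if (any(m > 0 & d2[cbind(seq_len(n1), pmax(m, 1))] > gate^2)) next
      tot <- sum(d2[cbind(which(m > 0), m[m > 0])]) +
        gate^2 * ((n1 - length(picked)) + (n2 - length(picked)))
      best <- min(best, tot)
    }
    expect_equal(cost, best, tolerance = 1e-9)
  }
})

test_that("gap closing bridges short gaps but not long ones", {
  cfg <- link_config(linking_distance = 5, gap_distance = 10,
                     max_frame_gap = 2)
  # one missing middle detection -> merged
  spots <- data.frame(frame = c(0, 1, 3, 4), x = c(0, 1, 3, 4), y = 0,
                      quality = 1)
  tr <- close_gaps(link_frames(spots, cfg), cfg)
  expect_equal(n_tracks(tr), 1L)
  expect_equal(nrow(tr$detections), 4L)  # no interpolated detections
  # three missing frames with max_frame_gap 2 -> stays split
  spots2 <- data.frame(frame = c(0, 1, 5, 6), x = c(0, 1, 5, 6), y = 0,
                       quality = 1)
  tr2 <- close_gaps(link_frames(spots2, cfg), cfg)
  expect_equal(n_tracks(tr2), 2L)
  # two candidate continuations: the nearer one is chosen
  spots3 <- data.frame(frame = c(0, 2, 2), x = c(0, 1, 6), y = 0,
                       quality = 1)
  tr3 <- close_gaps(link_frames(spots3, cfg), cfg)
  merged <- split(tr3$detections, tr3$detections$track_id)
  lens <- unname(sort(vapply(merged, nrow, 0L)))
  expect_equal(lens, c(1L, 2L))
  long <- merged[[which.max(vapply(merged, nrow, 0L))]]
  expect_equal(sort(long$x), c(0, 1))
})

test_that("end-to-end tracking recovers clean simulated tracks", {
  # low density so spots stay resolved throughout (localization on merged
  # spot pairs is biased, which is a property of the scene, not the
  # tracker)
  cfg <- simulation_config(width = 256, height = 256, n_frames = 45,
                           n_particles = 5, seed = 33)
  sim <- simulate_particles(cfg)
  v2 <- make_velocity_series(normalize_sequence(sim$sequence,
                                                "minmax_global"), 2, 17)
  gt <- downsample_tracks(sim$tracks, 2, 17)
  est <- track_particles(v2, diameter = 10, threshold = 0.1)
  sc <- score_tracks(gt, est, 5)
  expect_equal(n_tracks(est), 5L)
  expect_gte(sc$alpha, 0.99)
  expect_equal(sc$jsc_points, 1)
  # reproducible
  est2 <- track_particles(v2, diameter = 10, threshold = 0.1)
  expect_identical(est$detections[, c("frame", "x", "y")],
                   est2$detections[, c("frame", "x", "y")])
  # empty movie -> empty track set
  empty <- image_sequence(array(0, c(32, 32, 4)))
  expect_equal(n_tracks(track_particles(empty)), 0L)
})

test_that("tracks never hold two detections in one frame and respect gates", {
  set.seed(62)
  cfg <- link_config(linking_distance = 8, gap_distance = 8,
                     max_frame_gap = 2)
  for (k in 1:20) {
    spots <- data.frame(frame = sample(0:5, 30, replace = TRUE),
                        x = runif(30, 0, 40), y = runif(30, 0, 40),
                        quality = 1)
    spots <- spots[!duplicated(spots), ]
    tr <- close_gaps(link_frames(spots, cfg), cfg)
    for (d in split(tr$detections, tr$detections$track_id)) {
      expect_false(anyDuplicated(d$frame) > 0)
      if (nrow(d) > 1L) {
        dd <- sqrt(diff(d$x)^2 + diff(d$y)^2)
        gap <- diff(d$frame)
        expect_true(all(gap <= cfg$max_frame_gap | gap == 1))
        expect_true(all(dd <= pmax(cfg$linking_distance,
                                   cfg$gap_distance) + 1e-9))
      }
    }
  }
})
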