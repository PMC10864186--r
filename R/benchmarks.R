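#' Benchmark drivers
#'
#' Reproducible experiment protocols built from the simulator, the
#' interpolators, the quality metrics and the tracker.  Each driver
#' returns a long-form data frame (`protocol`, `method`, `level`,
#' `metric`, `value`, `seed`) with one row per method, level and metric.
#'
#' `run_velocity_benchmark()`: a densely sampled movie (unit per-frame
#' motion) is simulated once; for each velocity `v` the V`v` ground truth
#' is built by stride-`v` selection (17 frames), downsampled by 2,
#' re-interpolated with every method, scored against the held-out frames
#' (SSIM/RMSE/PSNR), then tracked and scored against the ground-truth
#' tracks (five criteria).
#'
#' @param cfg a [simulation_config()]; its seed is replaced by `seed`.
#' @param velocities integer velocity labels (strides), default 2:10.
#' @param methods interpolation methods to compare.
#' @param seed integer seed, mandatory.
#' @param max_frames ground-truth length per velocity (default 17).
#' @param epsilon pairing gate for track scoring, pixels.
#' @param detect_diameter,detect_threshold LoG detection settings used on
#'   the interpolated movies (threshold on the \[0, 1\]-normalized scale).
#' @param link a [link_config()].
#' @param eval_frames score only the `"held_out"` frames (default) or
#'   `"all"` reconstructed frames.
#' @param opts flow options for the motion-compensated method.
#' @return A long-form benchmark data frame.
#' @export
run_velocity_benchmark <- function(cfg = simulation_config(),
                                   velocities = 2:10,
                                   methods = c("none", "bil", "cafi"),
                                   seed = 1, max_frames = 17, epsilon = 5,
                                   detect_diameter = 10,
                                   detect_threshold = 0.1,
                                   link = link_config(),
                                   eval_frames = c("held_out", "all"),
                                   opts = flow_options()) {
  eval_frames <- match.arg(eval_frames)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  cfg$seed <- as.integer(seed)
  sim <- simulate_particles(cfg)
  rows <- list()
  for (v in velocities) {
    gt_v <- make_velocity_series(sim$sequence, v, max_frames)
    gt_tracks <- downsample_tracks(sim$tracks, v, max_frames)
    down <- downsample_axis(gt_v, 2)
    score_idx <- if (eval_frames == "held_out") {
      held_out_frames(gt_v, 2)$indices
    } else {
      NULL
    }
    lo <- min(gt_v$frames)
    hi <- max(gt_v$frames)
    for (method in methods) {
      pred <- interpolate_sequence(down, method, opts = opts)
      qr <- quality_report(gt_v, pred, frames = score_idx)
      pred_norm <- pred
      if (hi > lo) pred_norm$frames <- (pred$frames - lo) / (hi - lo)
      est <- track_particles(pred_norm, detect_diameter, detect_threshold,
                             link)
      sc <- score_tracks(gt_tracks, est, epsilon)
      rows[[length(rows) + 1L]] <- benchmark_rows(
        "velocity", method, v, seed,
        c(mean_ssim = qr$mean_ssim, mean_rmse = qr$mean_rmse,
          mean_psnr = qr$mean_psnr, alpha = sc$alpha, beta = sc$beta,
          jsc_points = sc$jsc_points, jsc_tracks = sc$jsc_tracks,
          rmse_loc = sc$rmse_loc))
    }
  }
  do.call(rbind, rows)
}

benchmark_rows <- function(protocol, method, level, seed, values) {
  data.frame(protocol = protocol, method = method, level = level,
             metric = names(values), value = unname(values), seed = seed,
             row.names = NULL)
}

#' @describeIn run_velocity_benchmark Multistep (iterative) upsampling
#' quality per interpolated position: the dense movie is reduced to its
#' stride-`factor` anchors and re-upsampled `factor`-fold; SSIM/RMSE/PSNR
#' are averaged per offset position 1 .. `factor - 1` between anchors,
#' yielding the per-position quality curve (worst at the centre).
#' @param factor upsampling factor (2, 4, 8 or 16).
#' @export
run_icafi_benchmark <- function(cfg = simulation_config(), factor = 16,
                                methods = c("none", "bil", "cafi"),
                                seed = 1, opts = flow_options()) {
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  if (!factor %in% c(2, 4, 8, 16)) {
    stop("`factor` must be one of 2, 4, 8, 16", call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  sim <- simulate_particles(cfg)
  dense <- sim$sequence
  T <- n_frames(dense)
  n_anchor <- (T - 1L) %/% factor + 1L
  dense <- subset_frames(dense, seq_len((n_anchor - 1L) * factor + 1L) - 1L)
  anchors <- downsample_axis(dense, factor)
  rows <- list()
  for (method in methods) {
    rec <- icafi(anchors, method, factor, opts = opts)
    for (pos in seq_len(factor - 1L)) {
      idx <- (seq_len(n_anchor - 1L) - 1L) * factor + pos
      qr <- quality_report(dense, rec, frames = idx)
      rows[[length(rows) + 1L]] <- benchmark_rows(
        "icafi", method, pos, seed,
        c(mean_ssim = qr$mean_ssim, mean_rmse = qr$mean_rmse,
          mean_psnr = qr$mean_psnr))
    }
  }
  do.call(rbind, rows)
}

#' @describeIn run_velocity_benchmark Robustness to noise: the V5 ground
#' truth (every fifth frame of the dense movie, 8-bit intensity scale) is
#' corrupted with Gaussian noise of increasing standard deviation,
#' downsampled by 2, re-interpolated, scored against the noisy
#' (undownsampled) ground truth, and tracked with the noise-experiment
#' settings (blob diameter 15, linking and gap-closing distance 15 px,
#' max frame gap 1).  The detection threshold is on this package's
#' response scale; the default 30 is half the noiseless matched-spot
#' response at 8-bit amplitude, an operating point that detects every
#' clean spot while misses and false detections appear as noise grows.
#' @param noise_stds Gaussian noise standard deviations on the 8-bit
#'   (0-255) intensity scale.
#' @param v velocity label of the ground-truth series (default 5).
#' @export
run_noise_benchmark <- function(cfg = simulation_config(),
                                noise_stds = c(0, 10, 20, 40, 80),
                                methods = c("none", "bil", "cafi"),
                                seed = 1, v = 5, epsilon = 5,
                                detect_diameter = 15,
                                detect_threshold = 30,
                                opts = flow_options()) {
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  cfg$seed <- as.integer(seed)
  sim <- simulate_particles(cfg)
  dense <- normalize_sequence(sim$sequence, "minmax_global")
  dense$frames <- dense$frames * 255
  max_frames <- (n_frames(dense) - 1L) %/% v + 1L
  if (max_frames %% 2L == 0L) max_frames <- max_frames - 1L
  gt_v <- make_velocity_series(dense, v, max_frames)
  gt_tracks <- downsample_tracks(sim$tracks, v, max_frames)
  noise_link <- link_config(linking_distance = 15, gap_distance = 15,
                            max_frame_gap = 1)
  rows <- list()
  for (k in seq_along(noise_stds)) {
    std <- noise_stds[k]
    noisy <- add_gaussian_noise(gt_v, std, seed = seed + k)
    down <- downsample_axis(noisy, 2)
    held <- held_out_frames(noisy, 2)$indices
    for (method in methods) {
      pred <- interpolate_sequence(down, method, opts = opts)
      qr <- quality_report(noisy, pred, frames = held)
      est <- track_particles(pred, diameter = detect_diameter,
                             threshold = detect_threshold,
                             cfg = noise_link)
      sc <- score_tracks(gt_tracks, est, epsilon)
      rows[[length(rows) + 1L]] <- benchmark_rows(
        "noise", method, std, seed,
        c(mean_ssim = qr$mean_ssim, mean_rmse = qr$mean_rmse,
          mean_psnr = qr$mean_psnr, alpha = sc$alpha, beta = sc$beta,
          jsc_points = sc$jsc_points, jsc_tracks = sc$jsc_tracks,
          rmse_loc = sc$rmse_loc))
    }
  }
  do.call(rbind, rows)
}
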