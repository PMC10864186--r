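#' Classical frame interpolators
#'
#' The three baseline in-between-frame constructions: `interp_duplicate()`
#' returns a copy of the earlier frame (frame duplication, "none");
#' `interp_blend()` is the temporal linear blend `(1 - t) A + t B`
#' ("bil"); `interp_cubic()` evaluates a per-pixel Catmull-Rom cubic in
#' time through four consecutive frames ("bic").  All operate purely in
#' time — no spatial resampling is involved.
#'
#' @param A,B frames (numeric matrices of identical shape).
#' @param t fractional time in (0, 1), default 0.5.
#' @return The interpolated frame.
#' @export
interp_duplicate <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  A
}

#' @rdname interp_duplicate
#' @export
interp_blend <- function(A, B, t = 0.5) {
  if (!identical(dim(A), dim(B))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  stopifnot_scalar_number(t, "t", 0, 1)
  (1 - t) * A + t * B
}

#' @rdname interp_duplicate
#' @param Fm1,F0,F1,F2 four consecutive frames; the interpolation time `t`
#'   runs between `F0` and `F1`.  At sequence ends the missing outer
#'   neighbour is replicated.
#' @export
interp_cubic <- function(Fm1, F0, F1, F2, t = 0.5) {
  stopifnot_scalar_number(t, "t", 0, 1)
  # Catmull-Rom basis (tangents from centred differences)
  0.5 * ((2 * F0) + (-Fm1 + F1) * t +
           (2 * Fm1 - 5 * F0 + 4 * F1 - F2) * t^2 +
           (-Fm1 + 3 * F0 - 3 * F1 + F2) * t^3)
}

interp_methods <- c("none", "bil", "bic", "cafi")

# Insert one frame between frames i and i+1 of the H x W x T array `arr`.
midframe_for <- function(arr, i, method, opts, consistency_scale) {
  T <- dim(arr)[3]
  A <- arr[, , i]
  B <- arr[, , i + 1]
  switch(method,
    none = interp_duplicate(A, B),
    bil = interp_blend(A, B, 0.5),
    bic = interp_cubic(arr[, , max(1L, i - 1L)], A, B,
                       arr[, , min(T, i + 2L)], 0.5),
    cafi = cafi_midframe(A, B, 0.5, opts = opts,
                         consistency_scale = consistency_scale))
}

#' Double the sampling of a sequence by interpolation
#'
#' Inserts one synthesized frame between every adjacent pair of frames,
#' giving `2 T - 1` frames; the original frames are preserved bit-exactly
#' at the even output indices (anchors).  Works along time or depth: an
#' `image_sequence` is interpolated along its leading axis, a
#' `volume_sequence` along the axis named by `axis`.
#'
#' @param seq an `image_sequence` or `volume_sequence` with at least two
#'   frames along the interpolation axis.
#' @param method one of `"none"` (duplication), `"bil"` (linear blend),
#'   `"bic"` (Catmull-Rom), `"cafi"` (motion-compensated, see
#'   [cafi_midframe()]).
#' @param axis `"t"` or `"z"`; for an `image_sequence` it must match the
#'   sequence's own `axis_label` (default).
#' @param opts flow options for `method = "cafi"`.
#' @param consistency_scale consistency kernel scale for `"cafi"`.
#' @return A sequence of the same class with doubled sampling.
#' @export
interpolate_sequence <- function(seq, method = interp_methods, axis = NULL,
                                 opts = flow_options(),
                                 consistency_scale = 1) {
  method <- match.arg(method, interp_methods)
  UseMethod("interpolate_sequence")
}

#' @export
interpolate_sequence.image_sequence <- function(seq, method = interp_methods,
                                                axis = NULL,
                                                opts = flow_options(),
                                                consistency_scale = 1) {
  method <- match.arg(method, interp_methods)
  if (!is.null(axis) && axis != seq$axis_label) {
    stop(sprintf("sequence runs along '%s' but axis '%s' was requested",
                 seq$axis_label, axis), call. = FALSE)
  }
  arr <- seq$frames
  T <- dim(arr)[3]
  if (T < 2L) stop("need at least two frames to interpolate", call. = FALSE)
  out <- array(0, c(dim(arr)[1:2], 2L * T - 1L))
  out[, , seq(1L, 2L * T - 1L, by = 2L)] <- arr
  for (i in seq_len(T - 1L)) {
    out[, , 2L * i] <- midframe_for(arr, i, method, opts, consistency_scale)
  }
  res <- seq
  res$frames <- out
  if (!is.null(res$frame_interval) && seq$axis_label == "t") {
    res$frame_interval <- res$frame_interval / 2
  }
  res
}

#' @export
interpolate_sequence.volume_sequence <- function(seq, method = interp_methods,
                                                 axis = c("t", "z"),
                                                 opts = flow_options(),
                                                 consistency_scale = 1) {
  method <- match.arg(method, interp_methods)
  axis <- match.arg(axis)
  d <- dim(seq$frames)
  if (axis == "z") {
    out <- array(0, c(d[1], d[2], 2L * d[3] - 1L, d[4]))
    for (t in seq_len(d[4])) {
      sub <- image_sequence(seq$frames[, , , t], axis_label = "z")
      out[, , , t] <- interpolate_sequence(sub, method, opts = opts,
                                           consistency_scale =
                                             consistency_scale)$frames
    }
  } else {
    out <- array(0, c(d[1], d[2], d[3], 2L * d[4] - 1L))
    for (z in seq_len(d[3])) {
      sub <- image_sequence(seq$frames[, , z, ], axis_label = "t")
      out[, , z, ] <- interpolate_sequence(sub, method, opts = opts,
                                           consistency_scale =
                                             consistency_scale)$frames
    }
  }
  res <- seq
  res$frames <- out
  res
}

#' Iterative multistep interpolation
#'
#' Applies [interpolate_sequence()] `log2(factor)` times, upsampling a
#' sequence 2x, 4x, 8x or 16x.  Output length is `factor * (T - 1) + 1`;
#' the input frames remain bit-exact at indices that are multiples of
#' `factor`.
#'
#' @inheritParams interpolate_sequence
#' @param factor upsampling factor, one of 2, 4, 8, 16.
#' @return The upsampled sequence.
#' @export
icafi <- function(seq, method = interp_methods, factor = 2, axis = NULL,
                  opts = flow_options(), consistency_scale = 1) {
  method <- match.arg(method, interp_methods)
  if (!factor %in% c(2, 4, 8, 16)) {
    stop("`factor` must be one of 2, 4, 8, 16", call. = FALSE)
  }
  for (k in seq_len(as.integer(log2(factor)))) {
    seq <- interpolate_sequence(seq, method, axis = axis, opts = opts,
                                consistency_scale = consistency_scale)
  }
  seq
}

# Keep frames of an image_sequence at the given 0-based indices.
subset_frames <- function(seq, idx0) {
  res <- seq
  res$frames <- seq$frames[, , idx0 + 1L, drop = FALSE]
  res
}

#' Stride-downsample a sequence
#'
#' Keeps frames at indices 0, `stride`, `2 stride`, ... (0-based); the
#' complementary frames — the ones an interpolator is later asked to
#' recover — are returned by [held_out_frames()].
#'
#' @param seq an `image_sequence`.
#' @param stride keep-every-`stride` step (>= 2).
#' @param keep_first kept for interface symmetry; the anchor grid always
#'   starts at frame 0.
#' @return The downsampled `image_sequence`.
#' @export
downsample_axis <- function(seq, stride, keep_first = TRUE) {
  stopifnot(is_image_sequence(seq))
  stopifnot_scalar_number(stride, "stride", 2, integer = TRUE)
  T <- n_frames(seq)
  res <- subset_frames(seq, seq(0L, T - 1L, by = stride))
  if (!is.null(res$frame_interval)) {
    res$frame_interval <- res$frame_interval * stride
  }
  res
}

#' @rdname downsample_axis
#' @return `held_out_frames()`: a list with `indices` (0-based indices of
#'   the removed frames) and `sequence` (those frames).
#' @export
held_out_frames <- function(seq, stride) {
  stopifnot(is_image_sequence(seq))
  stopifnot_scalar_number(stride, "stride", 2, integer = TRUE)
  T <- n_frames(seq)
  kept <- seq(0L, T - 1L, by = stride)
  removed <- setdiff(seq_len(T) - 1L, kept)
  list(indices = removed, sequence = subset_frames(seq, removed))
}

#' Build a velocity-series ground truth
#'
#' Selects every `v`-th frame of a densely sampled movie (so the maximum
#' directed travel between consecutive kept frames is `v` pixels — the
#' "velocity Vv" labelling) and truncates to `max_frames` frames for
#' comparability across velocities.
#'
#' @param dense an `image_sequence` with unit per-frame motion.
#' @param v velocity label (stride), integer >= 2.
#' @param max_frames number of frames kept (default 17).
#' @return The V`v` `image_sequence`.
#' @export
make_velocity_series <- function(dense, v, max_frames = 17) {
  stopifnot(is_image_sequence(dense))
  stopifnot_scalar_number(v, "v", 2, integer = TRUE)
  stopifnot_scalar_number(max_frames, "max_frames", 2, integer = TRUE)
  T <- n_frames(dense)
  if (v * (max_frames - 1) >= T) {
    stop(sprintf("dense sequence too short: need > %d frames for v = %d",
                 v * (max_frames - 1), v), call. = FALSE)
  }
  subset_frames(dense, v * (seq_len(max_frames) - 1L))
}
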