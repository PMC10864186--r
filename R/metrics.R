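#' Quality-metric configuration
#'
#' Standard settings for the pixel-based metrics: data range `L` (1 after
#' global min-max normalization), the 11 x 11 Gaussian SSIM window with
#' sigma 1.5, and the stabilizers `K1 = 0.01`, `K2 = 0.03` giving
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2`.
#'
#' @param data_range dynamic range `L` of the intensities (> 0).
#' @param window_size odd SSIM window size in pixels.
#' @param window_sigma Gaussian window sigma in pixels.
#' @param K1,K2 SSIM stabilizer constants.
#' @return A `metric_config` list.
#' @export
metric_config <- function(data_range = 1, window_size = 11,
                          window_sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot_scalar_number(data_range, "data_range", .Machine$double.eps)
  stopifnot_scalar_number(window_size, "window_size", 3, integer = TRUE)
  if (window_size %% 2 == 0) stop("`window_size` must be odd", call. = FALSE)
  list(data_range = data_range, window_size = window_size,
       window_sigma = window_sigma, K1 = K1, K2 = K2)
}

#' Root-mean-square error between two frames
#'
#' @param a,b numeric matrices of identical shape.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 log10(data_range / rmse)` in decibels.  Identical frames return
#' `Inf`; [quality_report()] excludes such frames from averages.
#'
#' @param a,b numeric matrices of identical shape.
#' @param cfg a [metric_config()].
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, cfg = metric_config()) {
  r <- rmse(a, b)
  if (r == 0) return(Inf)
  20 * log10(cfg$data_range / r)
}

#' Structural similarity index
#'
#' The standard luminance-contrast-structure form with a Gaussian sliding
#' window: local means, variances and covariance are aggregated under an
#' 11 x 11 Gaussian window (sigma 1.5 by default) and combined as
#' `((2 mu_a mu_b + C1)(2 cov + C2)) / ((mu_a^2 + mu_b^2 + C1)(var_a + var_b + C2))`.
#' The mean is taken over the valid (fully overlapping) window positions;
#' the local map over that region is returned for visualization.
#'
#' @param a,b numeric matrices of identical shape, at least the window
#'   size in each dimension.
#' @param cfg a [metric_config()].
#' @return A list with `value` (mean SSIM) and `map` (the local SSIM map
#'   over the valid region).
#' @export
ssim <- function(a, b, cfg = metric_config()) {
  if (!identical(dim(a), dim(b))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  r <- (cfg$window_size - 1L) / 2L
  if (nrow(a) < cfg$window_size || ncol(a) < cfg$window_size) {
    stop("frames smaller than the SSIM window", call. = FALSE)
  }
  win <- gaussian_kernel_1d(cfg$window_sigma, radius = r)
  mu_a <- sepconv_replicate(a, win)
  mu_b <- sepconv_replicate(b, win)
  e_aa <- sepconv_replicate(a * a, win)
  e_bb <- sepconv_replicate(b * b, win)
  e_ab <- sepconv_replicate(a * b, win)
  var_a <- e_aa - mu_a^2
  var_b <- e_bb - mu_b^2
  cov_ab <- e_ab - mu_a * mu_b
  c1 <- (cfg$K1 * cfg$data_range)^2
  c2 <- (cfg$K2 * cfg$data_range)^2
  map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  rows <- (r + 1L):(nrow(a) - r)
  cols <- (r + 1L):(ncol(a) - r)
  map <- map[rows, cols]
  list(value = mean(map), map = map)
}

#' Per-pixel absolute-error map
#'
#' The root of the per-pixel squared error, `|a - b|`.
#'
#' @param a,b numeric matrices of identical shape.
#' @return An H x W matrix.
#' @export
rse_map <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  abs(a - b)
}

#' Frame-by-frame quality report
#'
#' Computes SSIM, RMSE and PSNR per selected frame of a predicted sequence
#' against its ground truth, plus their arithmetic means.  When
#' `normalize = TRUE` (default) both sequences are first mapped by one
#' global affine transform — the ground-truth sequence's min-max — so all
#' methods are scored on a common \[0, 1\] scale (and `cfg$data_range`
#' should be 1).  Frames with infinite PSNR (bit-identical prediction) are
#' excluded from the PSNR mean; their count is reported.
#'
#' @param gt,pred `image_sequence`s of equal length.
#' @param frames 0-based frame indices to score (`NULL` = all frames).
#' @param cfg a [metric_config()].
#' @param normalize apply the global ground-truth min-max transform first.
#' @param want_maps also return per-frame SSIM and error maps.
#' @return A `quality_report` list: `per_frame` data frame (`frame`,
#'   `ssim`, `rmse`, `psnr`), `mean_ssim`, `mean_rmse`, `mean_psnr`,
#'   `n_infinite_psnr`, and optionally `ssim_maps`, `rse_maps`.
#' @export
quality_report <- function(gt, pred, frames = NULL, cfg = metric_config(),
                           normalize = TRUE, want_maps = FALSE) {
  stopifnot(is_image_sequence(gt), is_image_sequence(pred))
  if (n_frames(gt) != n_frames(pred)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (is.null(frames)) frames <- seq_len(n_frames(gt)) - 1L
  if (length(frames) == 0L || any(frames < 0L | frames >= n_frames(gt))) {
    stop("`frames` must be valid 0-based indices", call. = FALSE)
  }
  if (normalize) {
    lo <- min(gt$frames)
    hi <- max(gt$frames)
    if (hi > lo) {
      gt$frames <- (gt$frames - lo) / (hi - lo)
      pred$frames <- (pred$frames - lo) / (hi - lo)
    }
  }
  n <- length(frames)
  ssim_v <- rmse_v <- psnr_v <- numeric(n)
  ssim_maps <- rse_maps <- if (want_maps) vector("list", n) else NULL
  for (i in seq_len(n)) {
    a <- get_frame(gt, frames[i] + 1L)
    b <- get_frame(pred, frames[i] + 1L)
    s <- ssim(a, b, cfg)
    ssim_v[i] <- s$value
    rmse_v[i] <- rmse(a, b)
    psnr_v[i] <- psnr(a, b, cfg)
    if (want_maps) {
      ssim_maps[[i]] <- s$map
      rse_maps[[i]] <- rse_map(a, b)
    }
  }
  finite_psnr <- psnr_v[is.finite(psnr_v)]
  structure(list(
    per_frame = data.frame(frame = frames, ssim = ssim_v, rmse = rmse_v,
                           psnr = psnr_v),
    mean_ssim = mean(ssim_v),
    mean_rmse = mean(rmse_v),
    mean_psnr = if (length(finite_psnr)) mean(finite_psnr) else Inf,
    n_infinite_psnr = sum(!is.finite(psnr_v)),
    ssim_maps = ssim_maps, rse_maps = rse_maps), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d frames: SSIM %.4f, RMSE %.4f, PSNR %s dB\n",
              nrow(x$per_frame), x$mean_ssim, x$mean_rmse,
              format(round(x$mean_psnr, 2))))
  invisible(x)
}

#' Temporal colour-coded projection
#'
#' Tints each frame with a perceptually ordered colormap position (early
#' frames one end, late frames the other) and combines the tinted frames
#' by per-pixel, per-channel maximum, so a moving structure traces a
#' colour-coded trajectory.
#'
#' @param seq an `image_sequence`.
#' @param palette a colormap function `f(n)` returning `n` colours
#'   (default `grDevices::hcl.colors` with the viridis map).
#' @return An H x W x 3 RGB array in \[0, 1\].
#' @export
temporal_color_projection <- function(seq,
                                      palette = function(n)
                                        grDevices::hcl.colors(n, "viridis")) {
  stopifnot(is_image_sequence(seq))
  T <- n_frames(seq)
  lo <- min(seq$frames)
  hi <- max(seq$frames)
  scale <- if (hi > lo) 1 / (hi - lo) else 0
  cols <- grDevices::col2rgb(palette(T)) / 255
  d <- dim(seq$frames)
  out <- array(0, c(d[1], d[2], 3))
  for (t in seq_len(T)) {
    f <- (seq$frames[, , t] - lo) * scale
    for (ch in 1:3) {
      out[, , ch] <- pmax(out[, , ch], f * cols[ch, t])
    }
  }
  out
}

#' Green/magenta ground-truth overlay
#'
#' Maximum-projects both sequences over time, displays the ground truth in
#' green and the prediction in magenta (red + blue); where the two
#' coincide the channels combine to white/gray, so residual pure green or
#' pure magenta marks disagreement.
#'
#' @param gt_seq,pred_seq `image_sequence`s of identical frame shape.
#' @return An H x W x 3 RGB array in \[0, 1\].
#' @export
overlay_comparison <- function(gt_seq, pred_seq) {
  stopifnot(is_image_sequence(gt_seq), is_image_sequence(pred_seq))
  if (!identical(dim(gt_seq$frames)[1:2], dim(pred_seq$frames)[1:2])) {
    stop("sequences must share frame shape", call. = FALSE)
  }
  norm_proj <- function(s) {
    p <- apply(s$frames, c(1, 2), max)
    lo <- min(p)
    hi <- max(p)
    if (hi > lo) (p - lo) / (hi - lo) else p * 0
  }
  g <- norm_proj(gt_seq)
  m <- norm_proj(pred_seq)
  out <- array(0, c(dim(g), 3))
  out[, , 1] <- m
  out[, , 2] <- g
  out[, , 3] <- m
  out
}
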