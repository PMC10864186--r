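#' Pair estimated tracks with ground truth
#'
#' Tracks are paired by an exact minimum-cost assignment under the gated
#' track distance
#' `d(theta, theta_hat) = sum_t min(||p_t - p_hat_t||, epsilon)` taken
#' over the union of the two tracks' frame supports, with a missing
#' detection on either side costing `epsilon`.  Each ground-truth track
#' may instead stay unmatched ("dummy" pairing) at cost `|theta| epsilon`;
#' estimated tracks left unpaired are spurious.
#'
#' @param gt,est [track_set()]s; `gt` must be non-empty.
#' @param epsilon gate distance in pixels (> 0).
#' @return A list: `pairs` data frame (`gt_id`, `est_id` — `NA` for
#'   dummy-matched ground truth — and `distance`), `spurious` (ids of
#'   unpaired estimated tracks), `total_distance` = `d(Theta, Theta_hat*)`
#'   and `empty_distance` = `d(Theta, empty)`.
#' @export
pair_tracks <- function(gt, est, epsilon = 5) {
  stopifnot(is_track_set(gt), is_track_set(est))
  stopifnot_scalar_number(epsilon, "epsilon", 1e-12)
  if (n_tracks(gt) == 0L) {
    stop("criteria are undefined for empty ground truth", call. = FALSE)
  }
  gt_trks <- split_tracks(gt)
  est_trks <- split_tracks(est)
  ng <- length(gt_trks)
  ne <- length(est_trks)
  gt_len <- vapply(gt_trks, nrow, 0L)
  dmat <- matrix(0, ng, max(ne, 1L))
  if (ne > 0L) {
    for (i in seq_len(ng)) {
      for (j in seq_len(ne)) {
        dmat[i, j] <- track_distance(gt_trks[[i]], est_trks[[j]], epsilon)
      }
    }
  }
  dummy_cost <- gt_len * epsilon
  # rows: gt tracks + one dummy row per est track (absorbs spurious at 0);
  # cols: est tracks + one dummy col per gt track.
  n <- ng + ne
  cost <- matrix(Inf, n, n)
  if (ne > 0L) cost[seq_len(ng), seq_len(ne)] <- dmat
  cost[cbind(seq_len(ng), ne + seq_len(ng))] <- dummy_cost
  if (ne > 0L) {
    cost[cbind(ng + seq_len(ne), seq_len(ne))] <- 0
    cost[ng + seq_len(ne), ne + seq_len(ng)] <- 0
  }
  a <- solve_lap(cost)[seq_len(ng)]
  est_idx <- ifelse(a <= ne, a, NA_integer_)
  dist <- ifelse(is.na(est_idx), dummy_cost,
                 dmat[cbind(seq_len(ng), pmin(est_idx, max(ne, 1L)))])
  # a pair whose distance equals the dummy cost shares no detection within
  # the gate; treat it as unmatched (the assignment cost is unchanged)
  fake <- !is.na(est_idx) & dist >= dummy_cost - 1e-12
  est_idx[fake] <- NA_integer_
  dist[fake] <- dummy_cost[fake]
  pairs <- data.frame(gt_id = names(gt_trks),
                      est_id = ifelse(is.na(est_idx), NA_character_,
                                      names(est_trks)[est_idx]),
                      distance = dist, row.names = NULL)
  list(pairs = pairs,
       spurious = setdiff(names(est_trks), pairs$est_id),
       total_distance = sum(dist),
       empty_distance = sum(dummy_cost))
}

# Gated distance between one gt and one est track (data frames with
# columns frame, x, y, z).
track_distance <- function(g, e, epsilon) {
  frames <- union(g$frame, e$frame)
  ig <- match(frames, g$frame)
  ie <- match(frames, e$frame)
  both <- !is.na(ig) & !is.na(ie)
  d <- rep(epsilon, length(frames))
  if (any(both)) {
    dd <- sqrt((g$x[ig[both]] - e$x[ie[both]])^2 +
                 (g$y[ig[both]] - e$y[ie[both]])^2 +
                 (g$z[ig[both]] - e$z[ie[both]])^2)
    d[both] <- pmin(dd, epsilon)
  }
  sum(d)
}

#' Five-criteria tracking score
#'
#' Evaluates an estimated track set against ground truth with the five
#' particle-tracking-challenge criteria:
#' `alpha = 1 - d(Theta, Theta_hat*) / d(Theta, empty)` (pairing quality,
#' 1 = perfect); `beta` = the same numerator divided by
#' `d(Theta, empty) + epsilon * (detections in spurious tracks)` (so
#' `beta <= alpha`, penalizing spurious tracks); the detection-level
#' Jaccard `TP / (TP + FN + FP)` where a true positive is a paired
#' detection closer than `epsilon`; the track-level Jaccard
#' `paired / (paired + dummy-matched GT + spurious)`; and the
#' localization RMSE over true-positive pairs.
#'
#' @inheritParams pair_tracks
#' @return A `tracking_score` list with fields `alpha`, `beta`,
#'   `jsc_points`, `jsc_tracks`, `rmse_loc` and a `counts` list
#'   (`tp`, `fp`, `fn`, `paired_tracks`, `missed_gt_tracks`,
#'   `spurious_tracks`).
#' @export
score_tracks <- function(gt, est, epsilon = 5) {
  m <- pair_tracks(gt, est, epsilon)
  gt_trks <- split_tracks(gt)
  est_trks <- split_tracks(est)
  tp <- 0L
  sq_sum <- 0
  for (k in seq_len(nrow(m$pairs))) {
    if (is.na(m$pairs$est_id[k])) next
    g <- gt_trks[[m$pairs$gt_id[k]]]
    e <- est_trks[[m$pairs$est_id[k]]]
    frames <- intersect(g$frame, e$frame)
    if (!length(frames)) next
    ig <- match(frames, g$frame)
    ie <- match(frames, e$frame)
    dd <- sqrt((g$x[ig] - e$x[ie])^2 + (g$y[ig] - e$y[ie])^2 +
                 (g$z[ig] - e$z[ie])^2)
    hit <- dd < epsilon
    tp <- tp + sum(hit)
    sq_sum <- sq_sum + sum(dd[hit]^2)
  }
  n_gt <- nrow(gt$detections)
  n_est <- nrow(est$detections)
  spurious_pts <- sum(vapply(est_trks[m$spurious], nrow, 0L))
  d0 <- m$empty_distance
  dstar <- m$total_distance
  paired <- sum(!is.na(m$pairs$est_id))
  score <- list(
    alpha = 1 - dstar / d0,
    beta = (d0 - dstar) / (d0 + epsilon * spurious_pts),
    jsc_points = tp / (tp + (n_gt - tp) + (n_est - tp)),
    jsc_tracks = paired / (paired + (nrow(m$pairs) - paired) +
                             length(m$spurious)),
    rmse_loc = if (tp > 0) sqrt(sq_sum / tp) else NA_real_,
    counts = list(tp = tp, fp = n_est - tp, fn = n_gt - tp,
                  paired_tracks = paired,
                  missed_gt_tracks = nrow(m$pairs) - paired,
                  spurious_tracks = length(m$spurious)))
  structure(score, class = "tracking_score")
}

#' @export
print.tracking_score <- function(x, ...) {
  cat(sprintf(paste0("<tracking_score> alpha %.4f, beta %.4f, ",
                     "JSC %.4f, JSC_theta %.4f, RMSE %.3f px\n"),
              x$alpha, x$beta, x$jsc_points, x$jsc_tracks, x$rmse_loc))
  invisible(x)
}

#' Downsample ground-truth tracks to a velocity series
#'
#' Keeps detections at the frames selected by [make_velocity_series()]
#' (0, `stride`, `2 stride`, ..., `max_frames` of them) and re-indexes the
#' kept frames to 0 .. `max_frames - 1`, so tracks and images of a
#' velocity dataset stay aligned.
#'
#' @param tracks a dense-movie `track_set`.
#' @param stride frame stride (>= 1).
#' @param max_frames number of kept time points (`NULL` = no truncation).
#' @return The downsampled `track_set`.
#' @export
downsample_tracks <- function(tracks, stride, max_frames = NULL) {
  stopifnot(is_track_set(tracks))
  stopifnot_scalar_number(stride, "stride", 1, integer = TRUE)
  df <- tracks$detections
  keep <- df$frame %% stride == 0L
  df <- df[keep, , drop = FALSE]
  df$frame <- df$frame %/% stride
  if (!is.null(max_frames)) df <- df[df$frame < max_frames, , drop = FALSE]
  track_set(df)
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks are defined as
#' perfectly matching (IoU 1) with a warning.
#'
#' @param maskA,maskB logical (or 0/1) matrices of identical shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) {
    stop("masks must have identical shape", call. = FALSE)
  }
  a <- maskA > 0
  b <- maskB > 0
  uni <- sum(a | b)
  if (uni == 0L) {
    warning("both masks empty: IoU defined as 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Mean matched-object IoU of two label sequences
#'
#' Per frame, ground-truth and predicted objects are matched one-to-one by
#' an exact assignment maximizing total IoU; unmatched objects of either
#' side contribute 0.  The per-frame mean is taken over all object slots
#' (matched pairs plus unmatched objects), then averaged over frames.
#' Frames empty on both sides score 1.
#'
#' @param gt,pred [label_sequence()]s of identical shape.
#' @return Mean IoU in \[0, 1\].
#' @export
mean_matched_iou <- function(gt, pred) {
  stopifnot(inherits(gt, "label_sequence"), inherits(pred, "label_sequence"))
  if (!identical(dim(gt$masks), dim(pred$masks))) {
    stop("label sequences must have identical shape", call. = FALSE)
  }
  T <- dim(gt$masks)[3]
  per_frame <- vapply(seq_len(T), function(t) {
    frame_matched_iou(gt$masks[, , t], pred$masks[, , t])
  }, 0)
  mean(per_frame)
}

frame_matched_iou <- function(g, p) {
  gl <- sort(unique(g[g > 0]))
  pl <- sort(unique(p[p > 0]))
  if (!length(gl) && !length(pl)) return(1)
  if (!length(gl) || !length(pl)) return(0)
  fg <- g > 0 | p > 0
  tab <- table(factor(g[fg], levels = gl), factor(p[fg], levels = pl))
  area_g <- vapply(gl, function(l) sum(g == l), 0L)
  area_p <- vapply(pl, function(l) sum(p == l), 0L)
  inter <- matrix(as.numeric(tab), length(gl), length(pl))
  iou_mat <- inter / (outer(area_g, area_p, "+") - inter)
  a <- solve_lap(1 - iou_mat)
  matched <- !is.na(a)
  vals <- iou_mat[cbind(which(matched), a[matched])]
  # an assigned pair with zero overlap is not a real match
  vals <- vals[vals > 0]
  sum(vals) / (length(gl) + length(pl) - length(vals))
}
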