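#' Spot detection by Laplacian of Gaussian
#'
#' Scale-normalized LoG blob detection: each frame is smoothed with a
#' Gaussian of `sigma = diameter / (2 sqrt(2))` (the scale whose
#' normalized response is maximal for a Gaussian blob of that diameter),
#' the negated Laplacian response `-sigma^2 lap(G * I)` is computed, and
#' local maxima of the response above `threshold` are kept.  Positions are
#' refined to subpixel precision by a separable quadratic fit over the
#' 3 x 3 neighbourhood.
#'
#' @param seq an `image_sequence`.
#' @param diameter estimated blob diameter in pixels (> 2).
#' @param threshold minimum LoG response (quality) of a detection.
#' @return A data frame of spots: `frame` (0-based), `x`, `y` (0-based
#'   subpixel pixels), `quality`.
#' @export
detect_spots_log <- function(seq, diameter = 10, threshold = 0.1) {
  stopifnot(is_image_sequence(seq))
  stopifnot_scalar_number(diameter, "diameter", 2 + 1e-9)
  sigma <- diameter / (2 * sqrt(2))
  out <- vector("list", n_frames(seq))
  for (t in seq_len(n_frames(seq))) {
    resp <- log_response(get_frame(seq, t), sigma)
    out[[t]] <- local_maxima_subpixel(resp, threshold, t - 1L)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x = double(), y = double(),
                      quality = double())
  }
  res
}

# Scale-normalized LoG response map (positive for bright blobs).
log_response <- function(frame, sigma) {
  s <- gaussian_smooth(frame, sigma)
  h <- nrow(s)
  w <- ncol(s)
  lap <- s[c(1, 1:(h - 1)), ] + s[c(2:h, h), ] +
    s[, c(1, 1:(w - 1))] + s[, c(2:w, w)] - 4 * s
  -sigma^2 * lap
}

# 8-neighbour local maxima with quadratic subpixel refinement; border
# pixels excluded.  `frame0` is the 0-based frame index attached to rows.
local_maxima_subpixel <- function(resp, threshold, frame0) {
  h <- nrow(resp)
  w <- ncol(resp)
  if (h < 3L || w < 3L) {
    return(NULL)
  }
  ri <- 2:(h - 1)
  ci <- 2:(w - 1)
  c0 <- resp[ri, ci]
  is_max <- c0 > threshold &
    c0 >= resp[ri - 1, ci] & c0 >= resp[ri + 1, ci] &
    c0 >= resp[ri, ci - 1] & c0 >= resp[ri, ci + 1] &
    c0 >= resp[ri - 1, ci - 1] & c0 >= resp[ri - 1, ci + 1] &
    c0 >= resp[ri + 1, ci - 1] & c0 >= resp[ri + 1, ci + 1]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(NULL)
  }
  rows <- idx[, 1] + 1L  # back to full-image 1-based indices
  cols <- idx[, 2] + 1L
  center <- resp[cbind(rows, cols)]
  quad_offset <- function(m, p) {
    den <- m - 2 * center + p
    off <- ifelse(den < 0, 0.5 * (m - p) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  dx <- quad_offset(resp[cbind(rows, cols - 1L)], resp[cbind(rows, cols + 1L)])
  dy <- quad_offset(resp[cbind(rows - 1L, cols)], resp[cbind(rows + 1L, cols)])
  data.frame(frame = frame0, x = (cols - 1L) + dx, y = (rows - 1L) + dy,
             quality = center)
}

#' Tracker linking configuration
#'
#' Distance gates for frame-to-frame linking and gap closing.  When
#' `pixel_size` is set on the sequence, the gates are interpreted as
#' physical units and divided by it; otherwise they are pixels.
#'
#' @param linking_distance maximum frame-to-frame link distance.
#' @param gap_distance maximum distance for joining a track end to a later
#'   track start.
#' @param max_frame_gap maximum frame difference `start - end` bridged by
#'   gap closing (2 allows one missing detection).
#' @return A `link_config` list.
#' @export
link_config <- function(linking_distance = 25, gap_distance = 25,
                        max_frame_gap = 2) {
  stopifnot_scalar_number(linking_distance, "linking_distance", 1e-12)
  stopifnot_scalar_number(gap_distance, "gap_distance", 1e-12)
  stopifnot_scalar_number(max_frame_gap, "max_frame_gap", 0, integer = TRUE)
  list(linking_distance = linking_distance, gap_distance = gap_distance,
       max_frame_gap = max_frame_gap)
}

# Jaqaman-style square LAP for one frame pair: rows = spots in frame t
# plus one dummy per spot of t+1, columns likewise.  Returns for each spot
# of frame t the linked spot index in frame t+1, or NA.
link_pair <- function(x1, y1, x2, y2, gate) {
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  d2[d2 > gate^2] <- Inf
  b <- gate^2
  cost <- matrix(Inf, n1 + n2, n2 + n1)
  cost[seq_len(n1), seq_len(n2)] <- d2
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- b
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- b
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- solve_lap(cost)[seq_len(n1)]
  a[!is.na(a) & a > n2] <- NA_integer_
  a
}

#' Frame-to-frame spot linking
#'
#' For every pair of consecutive frames, spots are linked by an exact
#' minimum-cost assignment with squared-distance costs; links beyond
#' `linking_distance` are forbidden and unlinked spots terminate or start
#' tracks.  The result contains no gaps; see [close_gaps()] for the second
#' stage.
#'
#' @param spots spot data frame from [detect_spots_log()].
#' @param cfg a [link_config()].
#' @return A [track_set()].
#' @export
link_frames <- function(spots, cfg = link_config()) {
  if (nrow(spots) == 0L) return(track_set())
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  by_frame <- split(spots, factor(spots$frame, levels = frames))
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    sprintf("t%05d", next_id)
  }
  cur <- by_frame[[1]]
  cur$track_id <- vapply(seq_len(nrow(cur)), function(i) new_id(), "")
  rows <- list(cur)
  for (k in seq_along(frames)[-1]) {
    nxt <- by_frame[[k]]
    nxt$track_id <- NA_character_
    if (frames[k] == frames[k - 1] + 1L) {
      a <- link_pair(cur$x, cur$y, nxt$x, nxt$y, cfg$linking_distance)
      linked <- which(!is.na(a))
      nxt$track_id[a[linked]] <- cur$track_id[linked]
    }
    unstarted <- which(is.na(nxt$track_id))
    nxt$track_id[unstarted] <- vapply(unstarted, function(i) new_id(), "")
    rows[[k]] <- nxt
    cur <- nxt
  }
  df <- do.call(rbind, rows)
  track_set(df[, c("track_id", "frame", "x", "y")])
}

#' Gap closing
#'
#' Second assignment stage of the linker: track ends are joined to later
#' track starts when the frame difference is at most `max_frame_gap` and
#' the distance at most `gap_distance`, minimizing total squared distance
#' (exact assignment).  Joined tracks keep no detections for the bridged
#' frames.
#'
#' @param tracks gapless `track_set` from [link_frames()].
#' @param cfg a [link_config()].
#' @return A `track_set` with gaps closed.
#' @export
close_gaps <- function(tracks, cfg = link_config()) {
  stopifnot(is_track_set(tracks))
  if (cfg$max_frame_gap < 1L || n_tracks(tracks) < 2L) return(tracks)
  trks <- split_tracks(tracks)
  ids <- names(trks)
  ends <- do.call(rbind, lapply(trks, function(d) d[nrow(d), ]))
  starts <- do.call(rbind, lapply(trks, function(d) d[1, ]))
  m <- length(trks)
  gap <- outer(ends$frame, starts$frame, function(e, s) s - e)
  d2 <- outer(ends$x, starts$x, "-")^2 + outer(ends$y, starts$y, "-")^2
  eligible <- gap >= 1 & gap <= cfg$max_frame_gap & d2 <= cfg$gap_distance^2
  diag(eligible) <- FALSE
  if (!any(eligible)) return(tracks)
  cost_link <- ifelse(eligible, d2, Inf)
  b <- cfg$gap_distance^2
  cost <- matrix(Inf, 2L * m, 2L * m)
  cost[seq_len(m), seq_len(m)] <- cost_link
  cost[cbind(seq_len(m), m + seq_len(m))] <- b
  cost[cbind(m + seq_len(m), seq_len(m))] <- b
  cost[m + seq_len(m), m + seq_len(m)] <- 0
  a <- solve_lap(cost)[seq_len(m)]
  succ <- ifelse(!is.na(a) & a <= m, a, NA_integer_)
  # merge chains end -> start
  has_pred <- rep(FALSE, m)
  has_pred[succ[!is.na(succ)]] <- TRUE
  df <- tracks$detections
  for (root in which(!has_pred)) {
    j <- succ[root]
    while (!is.na(j)) {
      df$track_id[df$track_id == ids[j]] <- ids[root]
      j_next <- succ[j]
      succ[j] <- NA_integer_
      j <- j_next
    }
  }
  track_set(df)
}

#' Detect and link particles in a sequence
#'
#' The full tracking pipeline: [detect_spots_log()], [link_frames()],
#' [close_gaps()].  Distance gates are converted from physical units to
#' pixels when the sequence carries a `pixel_size`.
#'
#' @param seq an `image_sequence`.
#' @param diameter,threshold detection parameters, see
#'   [detect_spots_log()].
#' @param cfg a [link_config()].
#' @return A [track_set()].
#' @export
track_particles <- function(seq, diameter = 10, threshold = 0.1,
                            cfg = link_config()) {
  if (!is.null(seq$pixel_size) && seq$pixel_size > 0) {
    cfg$linking_distance <- cfg$linking_distance / seq$pixel_size
    cfg$gap_distance <- cfg$gap_distance / seq$pixel_size
  }
  spots <- detect_spots_log(seq, diameter, threshold)
  close_gaps(link_frames(spots, cfg), cfg)
}
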