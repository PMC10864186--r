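#' Particle track sets
#'
#' A `track_set` is a collection of particle trajectories.  Internally it is
#' a data frame with columns `track_id`, `frame` (0-based integer), `x`,
#' `y`, `z` (pixels; `z = 0` for planar data), ordered by track and frame.
#' Frame indices are strictly increasing within a track; a track may skip
#' frames (gaps).
#'
#' @param detections data frame with columns `track_id`, `frame`, `x`, `y`
#'   and optionally `z`.  An empty data frame gives an empty track set.
#' @return An object of class `track_set`.
#' @examples
#' ts <- track_set(data.frame(track_id = 1, frame = 0:2, x = 1:3, y = 0))
#' n_tracks(ts)
#' @export
track_set <- function(detections = data.frame()) {
  if (is.null(detections) || nrow(detections) == 0L) {
    df <- data.frame(track_id = character(), frame = integer(),
                     x = double(), y = double(), z = double())
    return(structure(list(detections = df), class = "track_set"))
  }
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(detections))
  if (length(miss)) {
    stop("missing track column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(detections$z)) detections$z <- 0
  df <- data.frame(track_id = as.character(detections$track_id),
                   frame = as.integer(detections$frame),
                   x = as.double(detections$x),
                   y = as.double(detections$y),
                   z = as.double(detections$z))
  if (any(df$frame < 0L)) stop("frame indices must be >= 0", call. = FALSE)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("track coordinates must be finite", call. = FALSE)
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  dup <- stats::ave(df$frame, df$track_id,
                    FUN = function(f) c(1L, diff(f)))
  if (any(dup <= 0L)) {
    stop("frame indices must be strictly increasing within a track",
         call. = FALSE)
  }
  structure(list(detections = df), class = "track_set")
}

#' @rdname track_set
#' @param x an object.
#' @export
is_track_set <- function(x) inherits(x, "track_set")

#' @rdname track_set
#' @param tracks a `track_set`.
#' @export
n_tracks <- function(tracks) length(unique(tracks$detections$track_id))

#' @rdname track_set
#' @export
track_ids <- function(tracks) unique(tracks$detections$track_id)

# List of per-track data frames, keyed by track id, in id order.
split_tracks <- function(tracks) {
  df <- tracks$detections
  split(df, factor(df$track_id, levels = unique(df$track_id)))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d detections\n",
              n_tracks(x), nrow(x$detections)))
  invisible(x)
}

#' @export
as.data.frame.track_set <- function(x, ...) x$detections

# Equality up to track relabelling is what most tests need; exact equality
# (same ids) is the stricter default.
tracks_equal <- function(a, b, tol = 1e-9) {
  da <- a$detections
  db <- b$detections
  if (nrow(da) != nrow(db)) return(FALSE)
  if (nrow(da) == 0L) return(TRUE)
  all(da$track_id == db$track_id) &&
    all(da$frame == db$frame) &&
    max(abs(da$x - db$x), abs(da$y - db$y), abs(da$z - db$z)) <= tol
}
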