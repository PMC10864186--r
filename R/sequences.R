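#' Image, volume and label sequences
#'
#' `image_sequence()` wraps an ordered stack of 2-D grayscale frames in a
#' light S3 container.  Frames are stored as an `H x W x T` numeric array
#' (rows = y, columns = x); the leading sequence axis may represent time
#' (`axis_label = "t"`) or depth (`axis_label = "z"`), which is all the
#' interpolation code needs to treat a z-stack like a time-lapse.
#'
#' @param frames numeric `H x W x T` array, `H x W` matrix (taken as a
#'   single frame), or list of equally sized matrices.
#' @param pixel_size optional physical size of a pixel (micrometres).
#' @param frame_interval optional time between frames (seconds).
#' @param axis_label `"t"` (time, default) or `"z"` (depth).
#' @return An object of class `image_sequence` with elements `frames`,
#'   `pixel_size`, `frame_interval`, `axis_label`.
#' @examples
#' seq <- image_sequence(array(runif(32 * 32 * 5), c(32, 32, 5)))
#' n_frames(seq)
#' @export
image_sequence <- function(frames, pixel_size = NULL, frame_interval = NULL,
                           axis_label = c("t", "z")) {
  axis_label <- match.arg(axis_label)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must share the same H x W shape", call. = FALSE)
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames))) {
    stop("frame intensities must be finite", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, axis_label = axis_label),
            class = "image_sequence")
}

#' @param x an object.
#' @rdname image_sequence
#' @export
is_image_sequence <- function(x) inherits(x, "image_sequence")

#' @rdname image_sequence
#' @param seq an `image_sequence` or `volume_sequence`.
#' @export
n_frames <- function(seq) {
  d <- dim(seq$frames)
  d[length(d)]
}

#' @rdname image_sequence
#' @param i frame index (1-based).
#' @export
get_frame <- function(seq, i) {
  stopifnot_scalar_number(i, "i", 1, n_frames(seq), integer = TRUE)
  seq$frames[, , i]
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d frames of %d x %d (axis '%s')\n",
              d[3], d[1], d[2], x$axis_label))
  invisible(x)
}

#' @describeIn image_sequence a 4-D (`H x W x Z x T`) stack of volumes.
#' @param z_spacing optional physical z-step (micrometres).
#' @export
volume_sequence <- function(frames, pixel_size = NULL, frame_interval = NULL,
                            z_spacing = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 4L) {
    stop("`frames` must be an H x W x Z x T array", call. = FALSE)
  }
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames))) {
    stop("frame intensities must be finite", call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, z_spacing = z_spacing),
            class = "volume_sequence")
}

#' @rdname image_sequence
#' @export
is_volume_sequence <- function(x) inherits(x, "volume_sequence")

#' @export
print.volume_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<volume_sequence> %d time points, %d z-slices of %d x %d\n",
              d[4], d[3], d[1], d[2]))
  invisible(x)
}

#' Labelled mask sequences
#'
#' A stack of integer-valued segmentation masks (0 = background, k > 0 =
#' object k), one mask per frame, used by the segmentation evaluation.
#'
#' @param masks integer `H x W x T` array or single matrix.
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(masks) {
  if (is.matrix(masks)) masks <- array(masks, c(dim(masks), 1L))
  if (!is.array(masks) || length(dim(masks)) != 3L) {
    stop("`masks` must be an H x W x T array", call. = FALSE)
  }
  if (!all(is.finite(masks)) || any(masks < 0) || any(masks != round(masks))) {
    stop("mask labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(masks) <- "integer"
  structure(list(masks = masks), class = "label_sequence")
}

#' Maximum-intensity z-projection
#'
#' Collapses each volume of a 3D + t series onto a single frame by the
#' per-pixel maximum over z, the usual preprocessing step that turns a 4-D
#' recording into a 2D + t dataset for tracking.
#'
#' @param vol a `volume_sequence`.
#' @return An `image_sequence` of the same length.
#' @export
max_project_z <- function(vol) {
  stopifnot(is_volume_sequence(vol))
  d <- dim(vol$frames)
  out <- array(0, c(d[1], d[2], d[4]))
  for (t in seq_len(d[4])) {
    out[, , t] <- apply(vol$frames[, , , t, drop = FALSE], c(1, 2), max)
  }
  image_sequence(out, pixel_size = vol$pixel_size,
                 frame_interval = vol$frame_interval)
}

#' Intensity normalization
#'
#' `mode = "minmax_global"` affinely maps the global minimum to 0 and the
#' global maximum to 1 using one scale for the whole sequence, so that
#' frames remain mutually comparable and metric data ranges are fixed at 1.
#' A constant sequence is mapped to all zeros with a warning.
#'
#' @param seq an `image_sequence`.
#' @param mode `"minmax_global"` or `"none"`.
#' @return The normalized `image_sequence`.
#' @export
normalize_sequence <- function(seq, mode = c("minmax_global", "none")) {
  mode <- match.arg(mode)
  stopifnot(is_image_sequence(seq))
  if (mode == "none") return(seq)
  lo <- min(seq$frames)
  hi <- max(seq$frames)
  if (hi == lo) {
    warning("constant sequence: normalizing to all zeros")
    seq$frames[] <- 0
  } else {
    seq$frames <- (seq$frames - lo) / (hi - lo)
  }
  seq
}

# Reorder a volume sequence so that the requested axis becomes the leading
# sequence axis of per-timepoint/per-slice image sequences.  Used by the
# axis-agnostic interpolation driver.
split_volume_along <- function(vol, axis = c("t", "z")) {
  axis <- match.arg(axis)
  d <- dim(vol$frames)
  if (axis == "z") {
    # one image_sequence per time point, running along z
    lapply(seq_len(d[4]), function(t) {
      image_sequence(vol$frames[, , , t], axis_label = "z")
    })
  } else {
    # one image_sequence per z-slice, running along t
    lapply(seq_len(d[3]), function(z) {
      image_sequence(vol$frames[, , z, ], axis_label = "t")
    })
  }
}
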