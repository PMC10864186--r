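#' Read a multi-page TIFF stack
#'
#' Reads a grayscale multi-page TIFF into an [image_sequence()] (axes
#' T, Y, X) or, when `n_z` is given, a [volume_sequence()] (axes T, Z, Y, X
#' with z-fastest page interleaving, the order [write_image_stack()] uses).
#' Integer samples are returned as their stored integer values, without
#' rescaling to \[0, 1\].
#'
#' @param path path to a TIFF file.
#' @param n_z number of z-slices per time point for 4-D stacks; `NULL`
#'   (default) reads a plain T x Y x X sequence.
#' @return An `image_sequence` or `volume_sequence`.
#' @export
read_image_stack <- function(path, n_z = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits == 32L) {
    # 32-bit samples are this package's normalized float representation
    # (stored as [0, 1]-scaled values); re-read on that scale
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) {
        p <- p[, , 1]
      } else {
        stop("RGB/multi-channel TIFF not supported: ", path, call. = FALSE)
      }
    }
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) {
    stop("inconsistent page shapes in ", path, call. = FALSE)
  }
  arr <- array(unlist(pages, use.names = FALSE),
               c(dims[[1]], length(pages)))
  if (is.null(n_z)) {
    image_sequence(arr)
  } else {
    stopifnot_scalar_number(n_z, "n_z", 1, integer = TRUE)
    if (length(pages) %% n_z != 0L) {
      stop("page count ", length(pages), " is not a multiple of n_z = ", n_z,
           call. = FALSE)
    }
    volume_sequence(array(arr, c(dims[[1]], n_z, length(pages) / n_z)))
  }
}

#' Write a multi-page TIFF stack
#'
#' Volumes are written with z as the fastest-varying page axis.  With
#' `dtype_policy = "preserve"`, stacks whose values are all integers in
#' \[0, 65535\] are stored as 16-bit unsigned samples and round-trip
#' bit-exactly.  Anything else (and everything under `"float32"`) is
#' stored as 32-bit samples on a \[0, 1\] scale, which round-trips real
#' values to about 2e-10; data outside \[0, 1\] is affinely rescaled into
#' it first, with a warning (grayscale TIFF carries no intensity scale,
#' so normalize explicitly with [normalize_sequence()] when the scale
#' matters).
#'
#' @param seq an `image_sequence` or `volume_sequence`.
#' @param path output path.
#' @param dtype_policy `"preserve"` (default) or `"float32"`.
#' @export
write_image_stack <- function(seq, path, dtype_policy = c("preserve", "float32")) {
  dtype_policy <- match.arg(dtype_policy)
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("`path` must be a non-empty file path", call. = FALSE)
  }
  frames <- seq$frames
  if (!all(is.finite(frames))) {
    stop("cannot write non-finite intensities", call. = FALSE)
  }
  d <- dim(frames)
  pages <- if (length(d) == 4L) {
    # z fastest: page order (z1,t1), (z2,t1), ...
    unlist(lapply(seq_len(d[4]), function(t) {
      lapply(seq_len(d[3]), function(z) frames[, , z, t])
    }), recursive = FALSE)
  } else {
    lapply(seq_len(d[3]), function(t) frames[, , t])
  }
  as_uint16 <- dtype_policy == "preserve" &&
    all(frames >= 0) && all(frames <= 65535) && all(frames == round(frames))
  if (as_uint16) {
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  } else {
    lo <- min(frames)
    hi <- max(frames)
    if (lo < 0 || hi > 1) {
      warning("rescaling intensities from [", format(lo), ", ", format(hi),
              "] to [0, 1] for 32-bit TIFF output")
      span <- if (hi > lo) hi - lo else 1
      pages <- lapply(pages, function(p) (p - lo) / span)
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  }
  invisible(path)
}

#' Track XML input/output (challenge dialect)
#'
#' Lossless mapping between a [track_set()] and the particle-tracking
#' challenge XML dialect: a `root` element containing one `particle`
#' element per track, each holding `detection` elements with attributes
#' `t`, `x`, `y`, `z`.  The `z` attribute is always written (0 for planar
#' data).
#'
#' @param path path to an XML file.
#' @return `read_isbi_xml()` returns a `track_set`.
#' @export
read_isbi_xml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  particles <- xml2::xml_find_all(doc, "//particle")
  rows <- lapply(seq_along(particles), function(i) {
    dets <- xml2::xml_find_all(particles[[i]], "./detection")
    if (length(dets) == 0L) return(NULL)
    get_attr <- function(name, required = TRUE) {
      v <- xml2::xml_attr(dets, name)
      if (required && anyNA(v)) {
        stop(sprintf("detection in particle %d is missing attribute '%s'",
                     i, name), call. = FALSE)
      }
      suppressWarnings(as.numeric(v))
    }
    t <- get_attr("t")
    x <- get_attr("x")
    y <- get_attr("y")
    z <- get_attr("z", required = FALSE)
    if (anyNA(t) || anyNA(x) || anyNA(y)) {
      stop(sprintf("non-numeric detection attribute in particle %d", i),
           call. = FALSE)
    }
    z[is.na(z)] <- 0
    data.frame(track_id = sprintf("p%05d", i), frame = as.integer(t),
               x = x, y = y, z = z)
  })
  track_set(do.call(rbind, rows))
}

#' @rdname read_isbi_xml
#' @param tracks a `track_set`.
#' @export
write_isbi_xml <- function(tracks, path) {
  stopifnot(is_track_set(tracks))
  doc <- xml2::xml_new_root("root")
  content <- xml2::xml_add_child(doc, "TrackContestISBI2012")
  for (trk in split_tracks(tracks)) {
    p <- xml2::xml_add_child(content, "particle")
    for (r in seq_len(nrow(trk))) {
      xml2::xml_add_child(p, "detection",
                          t = format(trk$frame[r]),
                          x = format(trk$x[r], digits = 17),
                          y = format(trk$y[r], digits = 17),
                          z = format(trk$z[r], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Tabular track input/output
#'
#' Plain delimited text with header columns `track_id`, `frame`, `x`, `y`,
#' `z` (comma-separated); lossless round-trip for any valid track set.
#'
#' @param path path to a delimited text file.
#' @return `read_tracks_table()` returns a `track_set`.
#' @export
read_tracks_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(track_set())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(track_set())
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("frame", "x", "y", "z"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv)) {
        stop("non-numeric values in track table column '", col, "'",
             call. = FALSE)
      }
      df[[col]] <- conv
    }
  }
  track_set(df)
}

#' @rdname read_tracks_table
#' @param tracks a `track_set`.
#' @export
write_tracks_table <- function(tracks, path) {
  stopifnot(is_track_set(tracks))
  utils::write.csv(tracks$detections, path, row.names = FALSE)
  invisible(path)
}
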