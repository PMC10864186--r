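#' @keywords internal
#' @useDynLib flowinterp, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Internal helpers shared across modules.
##
## Conventions used throughout the package:
##  * a frame is a numeric H x W matrix: rows = y, columns = x;
##  * continuous coordinates are 0-based and refer to pixel centers, so the
##    intensity "at" (x, y) = (0, 0) is frame[1, 1];
##  * image sequences store frames in an H x W x T array (see image_sequence()).

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so library calls do not perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper || (integer && x != round(x))) {
    stop(sprintf("`%s` must be a %sscalar in [%s, %s], got %s",
                 name, if (integer) "whole-number " else "finite ",
                 format(lower), format(upper),
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Bilinear sampling of matrix `img` at continuous, 0-based (x, y) positions.
# Coordinates outside the image are clamped to the border (edge replication).
# `x` and `y` are numeric vectors of equal length; returns a vector.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x)
  y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0
  fy <- y - y0
  # convert 0-based (col, row) to 1-based linear indices into img
  idx <- function(col0, row0) row0 + 1 + col0 * h
  v00 <- img[idx(x0, y0)]
  v10 <- img[idx(x1, y0)]
  v01 <- img[idx(x0, y1)]
  v11 <- img[idx(x1, y1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

# Separable Gaussian convolution with replicate boundaries (compiled
# two-pass implementation; exact for the Gaussian windows used here).
sepconv_replicate <- function(img, k1d) {
  sepconv_replicate_cpp(img, k1d)
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  sepconv_replicate(img, gaussian_kernel_1d(sigma))
}

# Fast approximate wide Gaussian: three box passes whose summed variance
# matches sigma^2.  Used where the exact kernel shape is immaterial (flow
# regularization); falls back to the exact kernel for small sigmas.
gaussian_smooth_fast <- function(img, sigma) {
  if (sigma <= 4) return(gaussian_smooth(img, sigma))
  r <- max(1L, as.integer(round((sqrt(4 * sigma^2 / 3 + 1) - 1) / 2)))
  boxconv_replicate_cpp(boxconv_replicate_cpp(
    boxconv_replicate_cpp(img, r), r), r)
}

# Half-size image for pyramid construction: Gaussian pre-smooth then
# bilinear resize.  Works on plain matrices.
pyr_down <- function(img) {
  # sigma 1.5 suppresses frequencies above Nyquist/2 before decimation;
  # weaker smoothing lets aliased texture mislead the coarse-level solver
  s <- gaussian_smooth(img, 1.5)
  nh <- max(1L, floor(nrow(img) / 2))
  nw <- max(1L, floor(ncol(img) / 2))
  resize_matrix(s, nh, nw)
}

resize_matrix <- function(img, nh, nw) {
  # map output pixel centers onto input pixel centers
  sy <- nrow(img) / nh
  sx <- ncol(img) / nw
  ys <- (seq_len(nh) - 0.5) * sy - 0.5
  xs <- (seq_len(nw) - 0.5) * sx - 0.5
  grid_x <- rep(xs, each = nh)
  grid_y <- rep(ys, times = nw)
  matrix(bilinear_sample(img, grid_x, grid_y), nh, nw)
}
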