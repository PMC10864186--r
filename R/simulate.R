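#' Particle-motion simulation configuration
#'
#' Parameters of the synthetic "switching uniform" particle movies: bright
#' isotropic Gaussian spots on a dark background whose motion switches per
#' frame between directed runs (a step of `base_speed` pixels along a
#' persistent heading, drawn with probability `p_directed`) and Brownian
#' steps (per-axis Gaussian displacements of scale `sigma_brownian`).
#' Densely sampled movies use `base_speed = 1` so that keeping every k-th
#' frame yields a sequence whose maximum directed travel per frame is k
#' pixels (the "velocity Vk" convention of the benchmarks).
#'
#' @param width,height image size in pixels.
#' @param n_frames number of frames in the dense movie.
#' @param n_particles number of particles.
#' @param diameter spot size in pixels: the full width of the
#'   above-half-maximum disk of the rendered Gaussian spot (default 15,
#'   a typical lysosome size at high magnification).
#' @param base_speed directed step length, pixels/frame (default 1).
#' @param p_directed per-frame probability of a directed step (default 0.5).
#' @param sigma_brownian per-axis Gaussian displacement scale of a Brownian
#'   step, pixels (default 1).
#' @param snr spot peak amplitude divided by the added Gaussian noise
#'   standard deviation; `Inf` (default) renders a noiseless movie.
#' @param background baseline intensity (default 0).
#' @param seed integer seed; every simulation is reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(width = 256, height = 256, n_frames = 225,
                              n_particles = 20, diameter = 15,
                              base_speed = 1, p_directed = 0.5,
                              sigma_brownian = 1, snr = Inf,
                              background = 0, seed = 1) {
  stopifnot_scalar_number(width, "width", 1, integer = TRUE)
  stopifnot_scalar_number(height, "height", 1, integer = TRUE)
  stopifnot_scalar_number(n_frames, "n_frames", 1, integer = TRUE)
  stopifnot_scalar_number(n_particles, "n_particles", 0, integer = TRUE)
  stopifnot_scalar_number(diameter, "diameter", 1)
  stopifnot_scalar_number(base_speed, "base_speed", 0)
  stopifnot_scalar_number(p_directed, "p_directed", 0, 1)
  stopifnot_scalar_number(sigma_brownian, "sigma_brownian", 0)
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    stop("`snr` must be a positive number (Inf for noiseless)", call. = FALSE)
  }
  stopifnot_scalar_number(background, "background", 0)
  stopifnot_scalar_number(seed, "seed", integer = TRUE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 n_particles = as.integer(n_particles),
                 diameter = diameter, base_speed = base_speed,
                 p_directed = p_directed, sigma_brownian = sigma_brownian,
                 snr = snr, background = background,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_heading <- function() {
  a <- stats::runif(1, 0, 2 * pi)
  c(cos(a), sin(a))
}

#' Advance one particle by one frame
#'
#' Draws the motion mode (directed with probability `p_directed`, Brownian
#' otherwise), applies the corresponding displacement, and reflects the
#' position at the image borders.  The heading persists across frames and
#' is re-randomized only when a reflection occurs.  Uses the current R
#' random number generator state.
#'
#' @param state list with `x`, `y` (0-based pixels), `heading` (unit
#'   vector), `mode`.
#' @param cfg a [simulation_config()].
#' @return The updated state.
#' @export
propagate_state <- function(state, cfg) {
  directed <- stats::runif(1) < cfg$p_directed
  if (directed) {
    state$x <- state$x + cfg$base_speed * state$heading[1]
    state$y <- state$y + cfg$base_speed * state$heading[2]
    state$mode <- "directed"
  } else {
    state$x <- state$x + stats::rnorm(1, 0, cfg$sigma_brownian)
    state$y <- state$y + stats::rnorm(1, 0, cfg$sigma_brownian)
    state$mode <- "brownian"
  }
  reflected <- FALSE
  lim_x <- cfg$width - 1
  lim_y <- cfg$height - 1
  while (state$x < 0 || state$x > lim_x) {
    state$x <- if (state$x < 0) -state$x else 2 * lim_x - state$x
    reflected <- TRUE
  }
  while (state$y < 0 || state$y > lim_y) {
    state$y <- if (state$y < 0) -state$y else 2 * lim_y - state$y
    reflected <- TRUE
  }
  if (reflected) state$heading <- random_heading()
  state
}

#' Render one frame of Gaussian spots
#'
#' Each particle is drawn as an isotropic Gaussian of peak amplitude 1
#' above the background, with standard deviation
#' `diameter / (2 * sqrt(2 * log(2)))` so that the disk above half maximum
#' has the configured diameter (FWHM).  Overlapping spots add.
#'
#' @param positions data frame with columns `x`, `y` (0-based pixels).
#' @param cfg a [simulation_config()].
#' @return An `height x width` matrix.
#' @export
render_frame <- function(positions, cfg) {
  frame <- matrix(cfg$background, cfg$height, cfg$width)
  if (NROW(positions) == 0L) return(frame)
  sigma <- cfg$diameter / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(positions))) {
    px <- positions$x[i]
    py <- positions$y[i]
    c0 <- max(1L, floor(px - r) + 1L)
    c1 <- min(cfg$width, ceiling(px + r) + 1L)
    r0 <- max(1L, floor(py - r) + 1L)
    r1 <- min(cfg$height, ceiling(py + r) + 1L)
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1
    rows <- r0:r1
    dx2 <- ((cols - 1) - px)^2
    dy2 <- ((rows - 1) - py)^2
    frame[rows, cols] <- frame[rows, cols] +
      exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  pmax(frame, 0)
}

#' Simulate a particle movie with ground-truth tracks
#'
#' Generates a seeded movie of switching Brownian/directed particles plus
#' the exact ground-truth [track_set()] (one detection per particle per
#' frame).  With finite `snr`, Gaussian noise of standard deviation
#' `1 / snr` times the spot amplitude is added to every pixel.
#'
#' @param cfg a [simulation_config()].
#' @param render set to `FALSE` to skip frame rendering and return only
#'   the ground-truth tracks (`sequence` is then `NULL`), e.g. for
#'   motion-statistics studies on large fields.
#' @return A list with elements `sequence` (an `image_sequence`) and
#'   `tracks` (a `track_set`).
#' @examples
#' sim <- simulate_particles(simulation_config(width = 64, height = 64,
#'                                             n_frames = 5, n_particles = 2,
#'                                             seed = 7))
#' sim$sequence
#' @export
simulate_particles <- function(cfg, render = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    margin <- cfg$diameter / 2
    # initial positions at least one diameter apart (rejection sampling)
    # so spots start resolvable; encounters may still occur later
    px <- py <- numeric(cfg$n_particles)
    for (i in seq_len(cfg$n_particles)) {
      for (try in seq_len(200L)) {
        cx <- stats::runif(1, margin, cfg$width - 1 - margin)
        cy <- stats::runif(1, margin, cfg$height - 1 - margin)
        if (i == 1L || all((px[seq_len(i - 1L)] - cx)^2 +
                             (py[seq_len(i - 1L)] - cy)^2 >=
                             cfg$diameter^2)) break
      }
      px[i] <- cx
      py[i] <- cy
    }
    states <- lapply(seq_len(cfg$n_particles), function(i) {
      list(x = px[i], y = py[i], heading = random_heading(),
           mode = "brownian")
    })
    frames <- if (render) {
      array(0, c(cfg$height, cfg$width, cfg$n_frames))
    } else {
      NULL
    }
    rows <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames)) {
      pos <- data.frame(
        x = vapply(states, `[[`, numeric(1), "x"),
        y = vapply(states, `[[`, numeric(1), "y"))
      if (render) frames[, , t] <- render_frame(pos, cfg)
      if (cfg$n_particles > 0L) {
        rows[[t]] <- data.frame(track_id = sprintf("p%05d",
                                                   seq_len(cfg$n_particles)),
                                frame = t - 1L, x = pos$x, y = pos$y, z = 0)
      }
      if (t < cfg$n_frames) {
        states <- lapply(states, propagate_state, cfg = cfg)
      }
    }
    seq <- NULL
    if (render) {
      seq <- image_sequence(frames)
      if (is.finite(cfg$snr)) {
        seq <- add_gaussian_noise(seq, std = 1 / cfg$snr)
      }
    }
    list(sequence = seq, tracks = track_set(do.call(rbind, rows)))
  })
}

#' Add i.i.d. Gaussian noise to a sequence
#'
#' Noise is added on the sequence's native intensity scale and is not
#' clipped (clipping to a representable range happens only when writing
#' integer TIFFs).
#'
#' @param seq an `image_sequence`.
#' @param std noise standard deviation (>= 0).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return The noisy `image_sequence`.
#' @export
add_gaussian_noise <- function(seq, std, seed = NULL) {
  stopifnot(is_image_sequence(seq))
  if (!is.numeric(std) || length(std) != 1L || !is.finite(std) || std < 0) {
    stop("`std` must be a finite non-negative number", call. = FALSE)
  }
  if (std == 0) return(seq)
  with_seed(seed, {
    seq$frames <- seq$frames +
      array(stats::rnorm(length(seq$frames), 0, std), dim(seq$frames))
    seq
  })
}
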