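# Independent reference implementations and scene builders used as test
# oracles.  These are deliberately naive (explicit loops, exhaustive
# enumeration) and share no code with the package internals they check.

# --- reference image metrics -------------------------------------------------

ref_rmse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      s <- s + (a[i, j] - b[i, j])^2
    }
  }
  sqrt(s / (nrow(a) * ncol(a)))
}

ref_psnr <- function(a, b, data_range = 1) {
  20 * log10(data_range / ref_rmse(a, b))
}

# literal sliding-window SSIM with Gaussian weights over valid positions
ref_ssim <- function(a, b, data_range = 1, win = 11, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  r <- (win - 1) / 2
  d <- seq(-r, r)
  wk <- exp(-d^2 / (2 * sigma^2))
  w <- outer(wk, wk)
  w <- w / sum(w)
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  vals <- c()
  for (i in (r + 1):(nrow(a) - r)) {
    for (j in (r + 1):(ncol(a) - r)) {
      wa <- a[(i - r):(i + r), (j - r):(j + r)]
      wb <- b[(i - r):(i + r), (j - r):(j + r)]
      mu_a <- sum(w * wa)
      mu_b <- sum(w * wb)
      va <- sum(w * wa^2) - mu_a^2
      vb <- sum(w * wb^2) - mu_b^2
      cab <- sum(w * wa * wb) - mu_a * mu_b
      vals <- c(vals, ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
                  ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# --- exhaustive assignment / track pairing ----------------------------------

perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n))[-k][p], nrow(p), n - 1))
  }))
}

ref_lap_cost <- function(cost) {
  n <- nrow(cost)
  pp <- perms(n)
  best <- Inf
  for (r in seq_len(nrow(pp))) {
    tot <- sum(cost[cbind(seq_len(n), pp[r, ])])
    if (tot < best) best <- tot
  }
  best
}

# gated track distance, recomputed independently of the package
ref_track_distance <- function(g, e, eps) {
  frames <- sort(union(g$frame, e$frame))
  tot <- 0
  for (f in frames) {
    gi <- which(g$frame == f)
    ei <- which(e$frame == f)
    if (length(gi) && length(ei)) {
      d <- sqrt((g$x[gi] - e$x[ei])^2 + (g$y[gi] - e$y[ei])^2 +
                  (g$z[gi] - e$z[ei])^2)
      tot <- tot + min(d, eps)
    } else {
      tot <- tot + eps
    }
  }
  tot
}

# exhaustive minimum over all injective partial matchings gt -> est
ref_pairing <- function(gt_list, est_list, eps) {
  ng <- length(gt_list)
  ne <- length(est_list)
  dummy <- vapply(gt_list, nrow, 0L) * eps
  best <- list(total = Inf, assign = NULL)
  assign_next <- function(i, used, cur, total) {
    if (total >= best$total) return()
    if (i > ng) {
      best <<- list(total = total, assign = cur)
      return()
    }
    assign_next(i + 1, used, c(cur, NA), total + dummy[i])
    for (j in seq_len(ne)) {
      if (ne == 0 || j %in% used) next
      assign_next(i + 1, c(used, j), c(cur, j),
                  total + ref_track_distance(gt_list[[i]], est_list[[j]], eps))
    }
  }
  assign_next(1, integer(), integer(), 0)
  best
}

ref_score <- function(gt_list, est_list, eps) {
  pairing <- ref_pairing(gt_list, est_list, eps)
  d0 <- sum(vapply(gt_list, nrow, 0L)) * eps
  spurious <- setdiff(seq_along(est_list), pairing$assign)
  spur_pts <- sum(vapply(est_list[spurious], nrow, 0L))
  tp <- 0
  sq <- 0
  for (i in seq_along(gt_list)) {
    j <- pairing$assign[i]
    if (is.na(j)) next
    g <- gt_list[[i]]
    e <- est_list[[j]]
    for (f in intersect(g$frame, e$frame)) {
      gi <- which(g$frame == f)
      ei <- which(e$frame == f)
      d <- sqrt((g$x[gi] - e$x[ei])^2 + (g$y[gi] - e$y[ei])^2 +
                  (g$z[gi] - e$z[ei])^2)
      if (d < eps) {
        tp <- tp + 1
        sq <- sq + d^2
      }
    }
  }
  n_gt <- sum(vapply(gt_list, nrow, 0L))
  n_est <- sum(vapply(est_list, nrow, 0L))
  paired <- sum(!is.na(pairing$assign))
  list(alpha = 1 - pairing$total / d0,
       beta = (d0 - pairing$total) / (d0 + eps * spur_pts),
       jsc_points = tp / (tp + (n_gt - tp) + (n_est - tp)),
       jsc_tracks = paired / (paired + (length(gt_list) - paired) +
                                length(spurious)),
       rmse_loc = if (tp > 0) sqrt(sq / tp) else NA_real_)
}

random_track_list <- function(n_tracks, max_len = 10, span = 12) {
  lapply(seq_len(n_tracks), function(i) {
    len <- sample(seq_len(max_len), 1)
    f0 <- sample(0:3, 1)
    data.frame(frame = sort(sample(f0:(f0 + span), len)),
               x = runif(len, 0, 40), y = runif(len, 0, 40), z = 0)
  })
}

track_list_to_set <- function(lst) {
  track_set(do.call(rbind, lapply(seq_along(lst), function(i) {
    cbind(data.frame(track_id = sprintf("r%02d", i)), lst[[i]])
  })))
}

tracks_equal_fi <- function(a, b, tol = 1e-9) {
  flowinterp:::tracks_equal(a, b, tol)
}

# --- analytic scenes ---------------------------------------------------------

# analytic textured scene: random Gaussian blobs (aperiodic landmarks,
# microscopy-like) plus low-amplitude sinusoids (fine texture), evaluable
# at any real-valued shift; the closed form is the oracle for translation
# experiments.  Pure wave mixtures are avoided: they are near-self-similar,
# which makes large translations genuinely ambiguous.
make_texture <- function(h, w, n_blobs = 40, n_waves = 20, seed = 7) {
  set.seed(seed)
  bx <- runif(n_blobs, -10, w + 9)
  by <- runif(n_blobs, -10, h + 9)
  bs <- runif(n_blobs, 3, 9)
  ba <- runif(n_blobs, 0.3, 1) * sample(c(-1, 1), n_blobs, replace = TRUE)
  fr <- matrix(runif(2 * n_waves, 0.05, 0.45), n_waves)
  ph <- runif(n_waves, 0, 2 * pi)
  am <- runif(n_waves, 0.1, 0.3) / sqrt(n_waves)
  function(shift = c(0, 0)) {
    xs <- outer(rep(1, h), seq_len(w) - 1) - shift[1]
    ys <- outer(seq_len(h) - 1, rep(1, w)) - shift[2]
    f <- matrix(0.5, h, w)
    for (k in seq_len(n_blobs)) {
      f <- f + ba[k] * exp(-((xs - bx[k])^2 + (ys - by[k])^2) /
                             (2 * bs[k]^2))
    }
    for (k in seq_len(n_waves)) {
      f <- f + am[k] * sin(fr[k, 1] * xs + fr[k, 2] * ys + ph[k])
    }
    f
  }
}

tiny_sim_config <- function(...) {
  args <- utils::modifyList(list(width = 64, height = 64, n_frames = 9,
                                 n_particles = 3, seed = 11), list(...))
  do.call(simulation_config, args)
}
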