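# independent oracles and small fixture builders used across tests

# a tracks tibble from raw vectors
make_track <- function(x, y, t = seq_along(x) - 1, id = 1L, frame = seq_along(x)) {
  tibble::tibble(track_id = id, frame = as.integer(frame), t_s = t,
                 x_um = x, y_um = y)
}

# straight-line track at constant velocity (um/s), dt in seconds
make_linear_track <- function(n, vx, vy = 0, dt = 1 / 17, x0 = 0, y0 = 0, id = 1L) {
  t <- (seq_len(n) - 1) * dt
  make_track(x0 + vx * t, y0 + vy * t, t, id = id)
}

# direct re-evaluation of the trajectory statistics from their definitions
oracle_track_stats <- function(x, y, t) {
  n <- length(x)
  d_net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  d_max <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d_max <- max(d_max, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
    }
  }
  s_net <- d_net / (t[n] - t[1])
  steps <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
  s_mean <- mean(steps)
  list(d_net = d_net, d_max = d_max, s_net = s_net, s_mean = s_mean,
       r_lin = s_net / s_mean)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) out <- c(out, list(append(p, n, after = k)))
  }
  out
}

# exhaustive minimum-cost perfect matching on a square matrix with Inf bans
oracle_lap <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  best_p <- NULL
  for (p in all_perms(n)) {
    v <- sum(cost[cbind(seq_len(n), p)])
    if (v < best) { best <- v; best_p <- p }
  }
  list(assignment = best_p, cost = best)
}

# exhaustive optimal one-frame linking cost over all link/birth/death choices:
# every subset of A may link to an injection into B
oracle_link_cost <- function(d2, max_d2, bd_cost) {
  n <- nrow(d2); m <- ncol(d2)
  best <- Inf
  idx_a <- seq_len(n)
  subsets <- list(integer(0))
  for (i in idx_a) subsets <- c(subsets, lapply(subsets, function(s) c(s, i)))
  for (s in subsets) {
    k <- length(s)
    if (k > m) next
    targets <- if (k == 0) list(integer(0)) else {
      combos <- utils::combn(m, k, simplify = FALSE)
      do.call(c, lapply(combos, function(cmb) lapply(all_perms(k), function(p) cmb[p])))
    }
    for (tg in targets) {
      link <- if (k > 0) sum(d2[cbind(s, tg)]) else 0
      if (k > 0 && any(d2[cbind(s, tg)] > max_d2)) next
      tot <- link + (n - k) * bd_cost + (m - k) * bd_cost
      best <- min(best, tot)
    }
  }
  best
}

# gain-calibration stack fixture: flat illumination through the EMCCD chain
make_flat_stack <- function(level, n_frames = 200, dim_px = 16,
                            cam = camera_model(roi = c(dim_px, dim_px))) {
  tr <- tibble::tibble(track_id = 1L, frame = 1L, t_s = 0,
                       x_um = -50, y_um = -50, visible = TRUE)
  render_movie(tr, cam, psf_sigma_px = 1.3, photons_per_frame = 100,
               bg_photons = level, roi = c(dim_px, dim_px),
               n_frames = n_frames)$frames
}
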