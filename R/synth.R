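#' Sample an alternating active/paused phase sequence
#'
#' Draws an alternating sequence of active and paused phases whose
#' durations follow gamma distributions matched by moments to the
#' (mean, sd) pairs in `params`. Gamma durations have positive support and
#' accommodate the heavy-tailed pause statistics (SD exceeding the mean)
#' seen in distal axons. The sequence starts with an active phase and is
#' truncated so that it exactly covers `total_time_s`; a zero pause mean
#' degenerates to a single active phase.
#'
#' @param params A [motion_params()] object.
#' @param total_time_s Total time to cover, in seconds.
#' @return A tibble with columns `phase`, `label`, `duration_s`,
#'   `t_start`, `t_end`; durations tile `[0, total_time_s]` exactly.
#' @examples
#' set.seed(1)
#' sample_phase_sequence(motion_preset("distal"), 120)
#' @export
sample_phase_sequence <- function(params, total_time_s) {
  abort_if(!inherits(params, "motion_params"), "`params` must be a motion_params object")
  check_positive(total_time_s, "total_time_s")
  abort_if(params$active_dur_mean <= 0, "`active_dur_mean` must be > 0")
  no_pause <- params$pause_dur_mean <= 0
  labels <- character(0)
  durs <- numeric(0)
  elapsed <- 0
  lab <- "active"
  while (elapsed < total_time_s) {
    d <- if (lab == "active") {
      if (no_pause) total_time_s else rgamma_ms(1, params$active_dur_mean, params$active_dur_sd)
    } else {
      rgamma_ms(1, params$pause_dur_mean, params$pause_dur_sd)
    }
    d <- max(d, 1e-9)
    labels <- c(labels, lab)
    durs <- c(durs, d)
    elapsed <- elapsed + d
    lab <- if (lab == "active") "paused" else "active"
  }
  durs[length(durs)] <- durs[length(durs)] - (elapsed - total_time_s)
  ends <- cumsum(durs)
  tibble::tibble(phase = seq_along(durs), label = labels, duration_s = durs,
                 t_start = c(0, head(ends, -1)), t_end = ends)
}

# frame times for a movie of total_time_s (frame 1 at t = 0)
frame_times <- function(total_time_s, camera) {
  n <- floor(total_time_s / camera$frame_interval_s) + 1L
  (seq_len(n) - 1L) * camera$frame_interval_s
}

#' Simulate a ground-truth trajectory
#'
#' Generates the true (noise-free) position of one particle sampled at
#' frame times. Active-transport particles ("AT") move along the axon path
#' toward the soma at a piecewise-constant run speed drawn per active
#' phase, with zero-mean positional jitter of SD `pause_jitter_sd` while
#' paused. "B&F" particles diffuse in one dimension along the path,
#' reflected inside a domain of `confinement_length_um`. "S" particles
#' jiggle isotropically about a fixed point. If the path is shorter than
#' the travel implied by the phase sequence the track stops at the path
#' end and the result carries attribute `truncated = TRUE`.
#'
#' @param params A [motion_params()] object.
#' @param path An [axon_path()].
#' @param camera A [camera_model()] (supplies the frame interval).
#' @param total_time_s Track duration in seconds.
#' @param start_s_um Starting arc-length position on the path.
#' @param track_id Identifier stored in the output.
#' @return A tibble (one row per frame): `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `s_um` (arc position), `visible`, `phase`,
#'   `motion_class`, `partner_id`.
#' @export
simulate_trajectory <- function(params, path = axon_path(), camera = camera_model(),
                                total_time_s = 120, start_s_um = 0,
                                track_id = 1L) {
  abort_if(!inherits(params, "motion_params"), "`params` must be a motion_params object")
  abort_if(!inherits(path, "axon_path"), "`path` must be an axon_path object")
  t <- frame_times(total_time_s, camera)
  n <- length(t)
  cls <- params$motion_class

  if (cls %in% c("AT", "AT_pair")) {
    ph <- sample_phase_sequence(params, total_time_s + camera$frame_interval_s)
    speeds <- ifelse(ph$label == "active",
                     rnorm_pos(nrow(ph), params$active_speed_mean, params$active_speed_sd),
                     0)
    # arc position at phase boundaries, then interpolate within phases
    s_bound <- start_s_um + c(0, cumsum(speeds * ph$duration_s))
    idx <- findInterval(t, ph$t_start, rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), nrow(ph))
    s <- s_bound[idx] + speeds[idx] * (t - ph$t_start[idx])
    truncated <- any(s > path$length_um)
    s <- pmin(s, path$length_um)
    xy <- path_point(path, s)
    lab <- ph$label[idx]
    paused <- lab == "paused"
    if (params$pause_jitter_sd > 0 && any(paused)) {
      xy[paused, 1] <- xy[paused, 1] + rnorm(sum(paused), 0, params$pause_jitter_sd)
      xy[paused, 2] <- xy[paused, 2] + rnorm(sum(paused), 0, params$pause_jitter_sd)
    }
    phase <- lab
  } else if (cls == "B&F") {
    L <- params$confinement_length_um
    abort_if(start_s_um + L > path$length_um + 1e-9,
             "confinement domain does not fit on the path")
    steps <- rnorm(n - 1L, 0, sqrt(2 * params$bf_diffusion_um2_s * camera$frame_interval_s))
    w <- cumsum(c(L / 2, steps))
    # reflect into [0, L] by folding over period 2L
    wm <- w %% (2 * L)
    w <- ifelse(wm > L, 2 * L - wm, wm)
    s <- start_s_um + w
    xy <- path_point(path, s)
    phase <- rep(NA_character_, n)
    truncated <- FALSE
  } else {  # stationary
    s <- rep(start_s_um, n)
    xy <- path_point(path, s)
    if (params$pause_jitter_sd > 0) {
      xy <- xy + matrix(rnorm(2 * n, 0, params$pause_jitter_sd), ncol = 2)
    }
    phase <- rep(NA_character_, n)
    truncated <- FALSE
  }

  out <- tibble::tibble(track_id = as.integer(track_id), frame = seq_len(n),
                        t_s = t, x_um = xy[, 1], y_um = xy[, 2], s_um = s,
                        visible = TRUE, phase = phase,
                        motion_class = cls, partner_id = NA_integer_)
  attr(out, "truncated") <- truncated
  out
}

#' Simulate a coordinated pair of actively transported particles
#'
#' The leader is an active-transport track; the follower trails it along
#' the path by a fluctuating tether whose offset is a stationary AR(1)
#' process with rest length `pair_coupling_rest_um` and SD
#' `pair_coupling_sd_um`, clipped so that the inter-particle distance
#' never reaches 2 um. Both members share phase boundaries by construction.
#'
#' @inheritParams simulate_trajectory
#' @param track_ids Length-2 identifiers for leader and follower.
#' @return A tibble with both tracks, `partner_id` cross-referenced.
#' @export
simulate_pair <- function(params, path = axon_path(), camera = camera_model(),
                          total_time_s = 40, start_s_um = 2,
                          track_ids = c(1L, 2L)) {
  abort_if(params$motion_class != "AT_pair", "`params$motion_class` must be \"AT_pair\"")
  leader <- simulate_trajectory(params, path, camera, total_time_s,
                                start_s_um = start_s_um, track_id = track_ids[1])
  n <- nrow(leader)
  rest <- params$pair_coupling_rest_um
  sdv <- params$pair_coupling_sd_um
  if (sdv > 0) {
    phi <- exp(-camera$frame_interval_s / 1)  # 1 s correlation time
    eps <- rnorm(n, 0, sdv * sqrt(1 - phi^2))
    off <- numeric(n)
    off[1] <- rest + rnorm(1, 0, sdv)
    for (i in 2:n) off[i] <- rest + phi * (off[i - 1] - rest) + eps[i]
  } else {
    off <- rep(rest, n)
  }
  off <- pmin(pmax(off, 0.05), 1.9)
  s_f <- pmax(leader$s_um - off, 0)
  xy <- path_point(path, s_f)
  follower <- leader
  follower$track_id <- as.integer(track_ids[2])
  follower$s_um <- s_f
  follower$x_um <- xy[, 1]
  follower$y_um <- xy[, 2]
  leader$partner_id <- as.integer(track_ids[2])
  follower$partner_id <- as.integer(track_ids[1])
  dplyr::bind_rows(leader, follower)
}

#' Apply quantum-dot blinking to a track
#'
#' Runs the two-state per-frame Markov chain of a [blink_model()] over each
#' track and updates the `visible` flag. Tracks start in the emitting
#' state; dark dwells are geometric with mean `1/p_on` frames.
#'
#' @param tracks A tracks tibble (as from [simulate_trajectory()]).
#' @param blink A [blink_model()].
#' @return The tracks tibble with `visible` updated.
#' @export
apply_blinking <- function(tracks, blink = blink_model()) {
  abort_if(!inherits(blink, "blink_model"), "`blink` must be a blink_model object")
  blink_one <- function(n) {
    on <- logical(n)
    state <- TRUE
    u <- runif(n)
    for (i in seq_len(n)) {
      on[i] <- state
      state <- if (state) u[i] >= blink$p_off else u[i] < blink$p_on
    }
    on
  }
  dplyr::mutate(dplyr::group_by(tracks, .data$track_id),
                visible = blink_one(dplyr::n())) |>
    dplyr::ungroup()
}

#' Simulate several independent tracks
#'
#' Convenience wrapper running [simulate_trajectory()] `n` times with
#' consecutive track ids and optional random start offsets along the path.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of tracks.
#' @param start_range_um Range from which starting arc positions are drawn.
#' @return A combined tracks tibble.
#' @export
simulate_tracks <- function(n, params, path = axon_path(), camera = camera_model(),
                            total_time_s = 120, start_range_um = c(0, 0)) {
  starts <- runif(n, start_range_um[1], start_range_um[2])
  purrr::map_dfr(seq_len(n), function(i) {
    simulate_trajectory(params, path, camera, total_time_s,
                        start_s_um = starts[i], track_id = i)
  })
}

#' Add localization noise to true positions
#'
#' Adds i.i.d. zero-mean Gaussian noise (per axis) to true positions,
#' emulating the localization error of the detection stage without
#' rendering a movie.
#'
#' @param tracks A tracks tibble.
#' @param sd_um Noise SD in micrometres per axis (default 0.02, i.e. 20 nm).
#' @return The tibble with perturbed `x_um`, `y_um` and a
#'   `precision_um` column recording the applied SD.
#' @export
add_localization_noise <- function(tracks, sd_um = 0.02) {
  abort_if(sd_um < 0, "`sd_um` must be >= 0")
  n <- nrow(tracks)
  dplyr::mutate(tracks,
                x_um = .data$x_um + rnorm(n, 0, sd_um),
                y_um = .data$y_um + rnorm(n, 0, sd_um),
                precision_um = sd_um)
}
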