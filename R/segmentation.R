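#' Segmentation and motion-classification configuration
#'
#' Thresholds for the whole-trajectory motion taxonomy and the
#' active/pause hysteresis segmentation. Segmentation enters the active
#' state when the smoothed instantaneous speed rises above `v_on_um_s` and
#' leaves it when the speed falls below `v_off_um_s` (`v_off < v_on`);
#' phases shorter than `min_phase_duration_s` are merged into their
#' neighbours. The taxonomy calls a track stationary ("S") when its
#' maximum displacement stays below `s_thresh_um`; active transport
#' ("AT") when the net displacement reaches `at_dnet_min_um`; confined
#' back-and-forth ("B&F") when the maximum displacement lies in
#' `bf_dmax_range_um`, the linearity ratio is below `bf_rlin_max`, and the
#' velocity along the principal axis reverses sign at least
#' `bf_min_reversals` times. Decision order: S, then AT, then B&F, then
#' unclassified.
#'
#' @param v_on_um_s,v_off_um_s Hysteresis thresholds, um/s.
#' @param min_phase_duration_s Minimum phase duration, s.
#' @param s_thresh_um Stationary d_max ceiling, um.
#' @param at_dnet_min_um Active-transport d_net floor, um.
#' @param bf_dmax_range_um Length-2 range of d_max for B&F, um.
#' @param bf_rlin_max Linearity ceiling for B&F.
#' @param bf_min_reversals Minimum principal-axis velocity reversals.
#' @param reversal_floor_um_s Speeds below this do not count toward
#'   reversals (noise floor).
#' @return A `segment_config` object.
#' @export
segment_config <- function(v_on_um_s = 0.5, v_off_um_s = 0.3,
                           min_phase_duration_s = 0.25,
                           s_thresh_um = 0.5, at_dnet_min_um = 5,
                           bf_dmax_range_um = c(2, 10), bf_rlin_max = 0.2,
                           bf_min_reversals = 3L, reversal_floor_um_s = 0.1) {
  abort_if(v_off_um_s >= v_on_um_s, "`v_off_um_s` must be < `v_on_um_s`")
  structure(list(v_on_um_s = v_on_um_s, v_off_um_s = v_off_um_s,
                 min_phase_duration_s = min_phase_duration_s,
                 s_thresh_um = s_thresh_um, at_dnet_min_um = at_dnet_min_um,
                 bf_dmax_range_um = bf_dmax_range_um, bf_rlin_max = bf_rlin_max,
                 bf_min_reversals = as.integer(bf_min_reversals),
                 reversal_floor_um_s = reversal_floor_um_s),
            class = "segment_config")
}

#' Classify whole trajectories into the motion taxonomy
#'
#' Assigns each track one of the motion classes observed for
#' quantum-dot labelled cargo on axons: stationary jiggle (`"S"`),
#' confined back-and-forth diffusion (`"B&F"`), active transport (`"AT"`),
#' or `"unclassified"`. Rules and decision order are documented in
#' [segment_config()].
#'
#' @param stats Output of [track_stats()].
#' @param velocity Output of [instantaneous_velocity()].
#' @param tracks The tracks tibble (positions, for the principal axis).
#' @param config A [segment_config()].
#' @return Tibble: `track_id`, `motion_class`, `n_reversals`.
#' @export
classify_motion <- function(stats, velocity, tracks, config = segment_config()) {
  rev_counts <- by_track(tracks, function(d) {
    tibble::tibble(n_reversals = principal_axis_reversals(
      d, velocity[velocity$track_id == d$track_id[1], ],
      config$reversal_floor_um_s))
  })
  out <- dplyr::left_join(stats, rev_counts, by = "track_id")
  out$motion_class <- with(out, dplyr::case_when(
    d_max_um < config$s_thresh_um ~ "S",
    d_net_um >= config$at_dnet_min_um ~ "AT",
    d_max_um >= config$bf_dmax_range_um[1] &
      d_max_um <= config$bf_dmax_range_um[2] &
      r_lin < config$bf_rlin_max &
      n_reversals >= config$bf_min_reversals ~ "B&F",
    TRUE ~ "unclassified"))
  out[, c("track_id", "motion_class", "n_reversals")]
}

# count sign reversals of the velocity projected on the principal axis
principal_axis_reversals <- function(track, vel, floor) {
  if (nrow(vel) == 0) return(0L)
  p <- cbind(track$x_um, track$y_um)
  p <- sweep(p, 2, colMeans(p))
  ax <- svd(p, nu = 0, nv = 1)$v[, 1]
  vproj <- vel$vx_um_s * ax[1] + vel$vy_um_s * ax[2]
  s <- sign(vproj[abs(vproj) > floor])
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Segment a trajectory into alternating active and paused phases
#'
#' Two-threshold hysteresis on the smoothed instantaneous speed (see
#' [segment_config()]): phases shorter than the minimum duration are
#' merged into their neighbours, so the output alternates labels and
#' tiles the trajectory exactly (phase boundaries are placed midway
#' between the adjacent localizations; the first and last phases extend
#' to the track ends). The `interior` flag marks phases bounded by
#' opposite-label phases on both sides — for an alternating sequence,
#' every phase except the first and last.
#'
#' Tracks too short for a velocity profile (fewer than 4 localizations)
#' become a single phase labelled by their mean speed.
#'
#' @param tracks Tracks tibble.
#' @param velocity Output of [instantaneous_velocity()] for the same
#'   tracks (recomputed when `NULL`).
#' @param config A [segment_config()].
#' @return Phase tibble: `track_id`, `phase_id`, `label`, `start_frame`,
#'   `end_frame`, `t_start`, `t_end`, `duration_s`, `n_locs`,
#'   `net_disp_um`, `net_speed_um_s`, `interior`.
#' @export
segment_phases <- function(tracks, velocity = NULL, config = segment_config()) {
  velocity <- velocity %||% instantaneous_velocity(tracks)
  one <- function(d) {
    d <- dplyr::arrange(d, .data$t_s)
    v <- velocity[velocity$track_id == d$track_id[1], ]
    n <- nrow(d)
    if (nrow(v) == 0) {
      lab <- if (nrow(d) >= 2 &&
                 mean(track_stats(d)$s_mean_um_s, na.rm = TRUE) >
                 (config$v_on_um_s + config$v_off_um_s) / 2) "active" else "paused"
      state <- rep(lab, n)
    } else {
      sp <- v$speed_um_s
      state <- character(n)
      cur <- if (sp[1] >= (config$v_on_um_s + config$v_off_um_s) / 2) "active" else "paused"
      for (i in seq_len(n)) {
        if (cur == "active" && sp[i] < config$v_off_um_s) cur <- "paused"
        else if (cur == "paused" && sp[i] > config$v_on_um_s) cur <- "active"
        state[i] <- cur
      }
    }
    build_phases(d, state, config$min_phase_duration_s)
  }
  by_track(tracks, one)
}

# run-length phases from per-localization states, with short-phase merging
# and exact tiling of [t_1, t_N]
build_phases <- function(d, state, min_dur) {
  n <- nrow(d)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  labels <- r$values
  dur_of <- function(starts, ends) {
    t_lo <- ifelse(starts == 1L, d$t_s[1],
                   (d$t_s[starts] + d$t_s[pmax(starts - 1L, 1L)]) / 2)
    t_hi <- ifelse(ends == n, d$t_s[n], (d$t_s[ends] + d$t_s[pmin(ends + 1L, n)]) / 2)
    cbind(t_lo, t_hi)
  }
  repeat {
    if (length(labels) <= 1L) break
    b <- dur_of(starts, ends)
    durs <- b[, 2] - b[, 1]
    short <- which(durs < min_dur)
    if (length(short) == 0) break
    k <- short[which.min(durs[short])]
    if (k == 1L) {                       # absorb into the following phase
      starts <- starts[-1]; ends <- ends[-1]; labels <- labels[-1]
      starts[1] <- 1L
    } else if (k == length(labels)) {    # absorb into the preceding phase
      starts <- starts[-k]; ends <- ends[-k]; labels <- labels[-k]
      ends[length(ends)] <- n
    } else {                             # merge prev + short + next
      starts <- starts[-c(k, k + 1L)]
      ends <- ends[-c(k - 1L, k)]
      labels <- labels[-c(k, k + 1L)]
    }
  }
  b <- dur_of(starts, ends)
  m <- length(labels)
  duration <- unname(b[, 2] - b[, 1])
  net_disp <- sqrt((d$x_um[ends] - d$x_um[starts])^2 +
                     (d$y_um[ends] - d$y_um[starts])^2)
  tibble::tibble(
    phase_id = seq_len(m), label = labels,
    start_frame = d$frame[starts], end_frame = d$frame[ends],
    t_start = b[, 1], t_end = b[, 2], duration_s = duration,
    n_locs = ends - starts + 1L,
    net_disp_um = net_disp,
    net_speed_um_s = net_disp / duration,
    interior = seq_len(m) > 1L & seq_len(m) < m)
}

#' Phase-level kinetics and aggregates
#'
#' Summarizes segmented phases: per label, the mean and SEM of duration,
#' net displacement and net speed, separately over interior phases only
#' (phases with known beginning and end, i.e. bounded by opposite-label
#' phases) and over all phases. Pause net displacement doubles as a QC
#' check that paused cargo stays confined to the track.
#'
#' @param phases Output of [segment_phases()].
#' @return Tibble: `label`, `scope` (`"interior"` or `"all"`), `n`,
#'   `mean_duration_s`, `sem_duration_s`, `mean_net_disp_um`,
#'   `mean_net_speed_um_s`, `sem_net_speed_um_s`.
#' @export
phase_kinetics <- function(phases) {
  sem <- function(x) sd(x) / sqrt(length(x))
  summarise_scope <- function(d, scope) {
    dplyr::summarise(dplyr::group_by(d, .data$label),
                     scope = scope, n = dplyr::n(),
                     mean_duration_s = mean(.data$duration_s),
                     sem_duration_s = sem(.data$duration_s),
                     mean_net_disp_um = mean(.data$net_disp_um),
                     mean_net_speed_um_s = mean(.data$net_speed_um_s),
                     sem_net_speed_um_s = sem(.data$net_speed_um_s),
                     .groups = "drop")
  }
  dplyr::bind_rows(summarise_scope(dplyr::filter(phases, .data$interior), "interior"),
                   summarise_scope(phases, "all"))
}
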