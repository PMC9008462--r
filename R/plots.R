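#' Plot trajectories coloured by instantaneous speed
#'
#' @param tracks Tracks tibble.
#' @param velocity Optional output of [instantaneous_velocity()]; when
#'   supplied, points are coloured by smoothed speed.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(tracks, velocity = NULL) {
  p <- ggplot2::ggplot(tracks, ggplot2::aes(.data$x_um, .data$y_um,
                                            group = .data$track_id))
  if (!is.null(velocity)) {
    d <- dplyr::left_join(tracks, velocity, by = c("track_id", "frame", "t_s"))
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um,
                                         group = .data$track_id,
                                         colour = .data$speed_um_s)) +
      ggplot2::scale_colour_viridis_c(name = "speed (µm/s)")
  }
  p + ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Kymograph-style view of one track with its phases
#'
#' Position along the direction of travel against time, with active and
#' paused phases shaded.
#'
#' @param track Single-track tibble.
#' @param phases Output of [segment_phases()] for the same track.
#' @return A ggplot object.
#' @export
plot_phases <- function(track, phases) {
  phases <- phases[phases$track_id == track$track_id[1], ]
  axis_um <- if ("s_um" %in% names(track)) track$s_um else {
    p <- cbind(track$x_um, track$y_um)
    p <- sweep(p, 2, p[1, ])
    drop(p %*% svd(p, nu = 0, nv = 1)$v[, 1])
  }
  d <- dplyr::mutate(track, axis_um = axis_um)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(data = phases,
                       ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                    ymin = -Inf, ymax = Inf, fill = .data$label),
                       alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(.data$t_s, .data$axis_um)) +
    ggplot2::scale_fill_manual(values = c(active = "#2b8cbe", paused = "#fdae61")) +
    ggplot2::labs(x = "time (s)", y = "position along axon (µm)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a spatial histogram of cargo spread
#'
#' @param hist Output of [spatial_histogram()].
#' @param channel_range_um Optional `c(lo, hi)` marking the microchannel.
#' @return A ggplot object.
#' @export
plot_spatial_histogram <- function(hist, channel_range_um = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(.data$bin_start_um + diff(c(.data$bin_start_um[1], .data$bin_end_um[1])) / 2,
                                          .data$mean_count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_count - .data$sem,
                                        ymax = .data$mean_count + .data$sem),
                           width = 40, na.rm = TRUE) +
    ggplot2::labs(x = "distance from point of addition (µm)",
                  y = "QDs per bin (mean ± SEM)") +
    ggplot2::theme_minimal()
  if (!is.null(channel_range_um)) {
    p <- p + ggplot2::annotate("rect", xmin = channel_range_um[1],
                               xmax = channel_range_um[2], ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "steelblue")
  }
  p
}
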