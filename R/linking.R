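#' Linking configuration
#'
#' Parameters of the frame-to-frame assignment and gap-closing passes.
#' Birth and death costs are derived from the blinking model:
#' `death = birth = -log(p_off + p_miss)`, where `p_miss` allows for
#' detection failures, so a link is preferred whenever its squared
#' displacement is below `birth + death`. Gap closing joins a track end to
#' a later track start across up to `max_gap` dark frames, with the
#' allowed distance growing as `max_link_distance_um * sqrt(gap)` (diffusive
#' part) plus `gap_speed_um_s * gap * frame_interval` (transport part).
#'
#' @param max_link_distance_um Hard frame-to-frame link radius (um).
#' @param max_gap Maximum number of missed frames bridged by gap closing.
#' @param p_miss Detection-failure allowance added to `p_off`.
#' @param gap_speed_um_s Transport allowance used in the gap radius.
#' @param min_track_length Minimum localizations per final track.
#' @return A `link_config` object.
#' @export
link_config <- function(max_link_distance_um = 0.5, max_gap = 8L,
                        p_miss = 0.05, gap_speed_um_s = 2,
                        min_track_length = 10L) {
  check_positive(max_link_distance_um, "max_link_distance_um")
  abort_if(max_gap < 0, "`max_gap` must be >= 0")
  check_prob(p_miss, "p_miss")
  structure(list(max_link_distance_um = max_link_distance_um,
                 max_gap = as.integer(max_gap), p_miss = p_miss,
                 gap_speed_um_s = gap_speed_um_s,
                 min_track_length = as.integer(min_track_length)),
            class = "link_config")
}

blink_costs <- function(blink, config) {
  p <- min(blink$p_off + config$p_miss, 0.999)
  p <- max(p, 1e-6)
  -log(p)
}

#' Build the augmented cost matrix for one frame transition
#'
#' Standard LAP augmentation: the upper-left block holds squared
#' displacements (um^2) for candidate links, with links beyond
#' `max_link_distance_um` forbidden (`Inf`); the diagonal upper-right and
#' lower-left blocks carry the death and birth costs derived from the
#' blinking model; the lower-right block is zero wherever the transposed
#' link is feasible, completing the matching.
#'
#' @param locs_a,locs_b Tibbles with `x_um`, `y_um` at frames t and t+1.
#' @param config A [link_config()].
#' @param blink A [blink_model()].
#' @return A square `(n + m)` cost matrix with attributes `n` and `m`.
#' @export
build_cost_matrix <- function(locs_a, locs_b, config = link_config(),
                              blink = blink_model()) {
  n <- nrow(locs_a)
  m <- nrow(locs_b)
  bc <- blink_costs(blink, config)
  link <- matrix(Inf, n, m)
  if (n > 0 && m > 0) {
    d2 <- outer(locs_a$x_um, locs_b$x_um, "-")^2 +
      outer(locs_a$y_um, locs_b$y_um, "-")^2
    link <- ifelse(d2 <= config$max_link_distance_um^2, d2, Inf)
  }
  cost <- matrix(Inf, n + m, n + m)
  if (n > 0 && m > 0) cost[seq_len(n), seq_len(m)] <- link
  if (n > 0) cost[cbind(seq_len(n), m + seq_len(n))] <- bc       # deaths
  if (m > 0) cost[cbind(n + seq_len(m), seq_len(m))] <- bc       # births
  if (n > 0 && m > 0) {
    lr <- t(link)
    lr[is.finite(lr)] <- 0
    cost[n + seq_len(m), m + seq_len(n)] <- lr
  }
  structure(cost, n = n, m = m)
}

#' Solve a linear assignment problem
#'
#' Minimum-cost perfect matching by shortest augmenting paths
#' (Jonker-Volgenant), with deterministic tie-breaking. Entries of `Inf`
#' are forbidden; an error is raised if no finite-cost perfect matching
#' exists.
#'
#' @param cost Square numeric matrix; `Inf` marks forbidden assignments.
#' @return Integer vector: `assignment[i]` is the column matched to row
#'   `i`, with the total cost as attribute `cost`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  abort_if(nrow(cost) != ncol(cost), "cost matrix must be square")
  if (nrow(cost) == 0) return(structure(integer(0), cost = 0))
  finite <- cost[is.finite(cost)]
  abort_if(length(finite) == 0, "infeasible assignment problem (no finite costs)")
  big <- sum(abs(finite)) + max(abs(finite)) * nrow(cost) + 1
  sol <- .lap_cpp(cost, big)
  abort_if(sol$cost >= big, "infeasible assignment problem")
  structure(as.integer(sol$assignment), cost = sol$cost)
}

#' Link per-frame localizations into trajectories
#'
#' Two passes. First, frame-to-frame assignment: localizations of
#' consecutive frames are matched through the blinking-aware augmented
#' cost matrix. Second, gap closing: ends of track segments are joined to
#' later starts across up to `max_gap` missed frames within the gap-scaled
#' radius. Track ids are renumbered by first frame, so identical input
#' yields identical output.
#'
#' @param locs Localization tibble (accepted records only are used) with
#'   `frame`, `t_s`, `x_um`, `y_um` and optional `photons`,
#'   `precision_x_um`, `precision_y_um`.
#' @param config A [link_config()].
#' @param blink A [blink_model()].
#' @return Tracks tibble: `track_id`, `frame`, `t_s`, coordinates and any
#'   carried columns, ordered by track and frame. Tracks shorter than
#'   `min_track_length` localizations are dropped.
#' @export
link_movie <- function(locs, config = link_config(), blink = blink_model()) {
  if ("accepted" %in% names(locs)) locs <- dplyr::filter(locs, .data$accepted)
  if (nrow(locs) == 0) {
    return(dplyr::mutate(locs, track_id = integer(0), .before = 1))
  }
  locs <- dplyr::arrange(locs, .data$frame, .data$x_um, .data$y_um)
  locs$.row <- seq_len(nrow(locs))
  by_frame <- split(locs, locs$frame)
  frames <- as.integer(names(by_frame))
  track_of <- integer(nrow(locs))
  n_tracks <- 0L
  # live tracks: id -> row index of their last localization
  first <- by_frame[[1]]
  track_of[first$.row] <- n_tracks + seq_len(nrow(first))
  n_tracks <- n_tracks + nrow(first)
  last_rows <- first$.row
  if (length(by_frame) > 1) {
    for (k in 2:length(by_frame)) {
      a <- locs[last_rows, ]
      b <- by_frame[[k]]
      if (frames[k] != frames[k - 1] + 1L || nrow(a) == 0) {
        assign_b <- rep(NA_integer_, nrow(b))
      } else if (nrow(a) == 1 && nrow(b) == 1) {
        # single-particle fast path: link iff within radius and cheaper
        # than a death plus a birth
        d2 <- (a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2
        ok <- d2 <= config$max_link_distance_um^2 &&
          d2 < 2 * blink_costs(blink, config)
        assign_b <- if (ok) 1L else NA_integer_
      } else {
        cm <- build_cost_matrix(a, b, config, blink)
        sol <- solve_assignment(cm)
        n <- attr(cm, "n")
        m <- attr(cm, "m")
        assign_b <- rep(NA_integer_, m)
        linked <- which(sol[seq_len(n)] <= m)
        assign_b[sol[linked]] <- linked  # index into rows of a
      }
      for (j in seq_len(nrow(b))) {
        if (!is.na(assign_b[j])) {
          track_of[b$.row[j]] <- track_of[a$.row[assign_b[j]]]
        } else {
          n_tracks <- n_tracks + 1L
          track_of[b$.row[j]] <- n_tracks
        }
      }
      # tracks not extended die here; gap closing may resurrect them
      last_rows <- b$.row
    }
  }
  locs$track_id <- track_of
  locs <- close_gaps(locs, config, blink)
  locs <- dplyr::group_by(locs, .data$track_id) |>
    dplyr::filter(dplyr::n() >= config$min_track_length) |>
    dplyr::ungroup()
  # renumber by first frame (then by position for determinism)
  key <- dplyr::summarise(dplyr::group_by(locs, .data$track_id),
                          f0 = min(.data$frame), x0 = .data$x_um[1])
  key <- dplyr::arrange(key, .data$f0, .data$x0)
  key$new_id <- seq_len(nrow(key))
  locs <- dplyr::left_join(locs, key[, c("track_id", "new_id")], by = "track_id")
  locs$track_id <- locs$new_id
  locs$new_id <- NULL
  locs$.row <- NULL
  dplyr::arrange(dplyr::relocate(locs, "track_id"), .data$track_id, .data$frame)
}

# join track ends to later track starts across blink gaps
close_gaps <- function(locs, config, blink) {
  if (config$max_gap < 1) return(locs)
  repeat {
    idx <- split(seq_len(nrow(locs)), locs$track_id)
    first <- vapply(idx, function(i) i[which.min(locs$frame[i])], 1L)
    last <- vapply(idx, function(i) i[which.max(locs$frame[i])], 1L)
    seg <- data.frame(track_id = locs$track_id[first],
                      f_start = locs$frame[first], f_end = locs$frame[last],
                      x_start = locs$x_um[first], y_start = locs$y_um[first],
                      x_end = locs$x_um[last], y_end = locs$y_um[last])
    n_seg <- nrow(seg)
    if (n_seg < 2) return(locs)
    # candidate joins: end of u -> start of w, 1..max_gap missed frames
    gap <- outer(seg$f_end, seg$f_start, function(e, s) s - e - 1L)
    d <- sqrt(outer(seg$x_end, seg$x_start, "-")^2 +
                outer(seg$y_end, seg$y_start, "-")^2)
    dt_frame <- attr(locs, "frame_interval_s") %||%
      (if (nrow(locs) > 1) min(diff(sort(unique(locs$t_s)))) else 1)
    allowed <- config$max_link_distance_um * sqrt(pmax(gap + 1, 1)) +
      config$gap_speed_um_s * (gap + 1) * dt_frame
    feasible <- gap >= 1 & gap <= config$max_gap & d <= allowed
    if (!any(feasible)) return(locs)
    cost <- ifelse(feasible, d^2, Inf)
    bc <- 2 * blink_costs(blink, config)
    aug <- matrix(Inf, 2 * n_seg, 2 * n_seg)
    aug[seq_len(n_seg), seq_len(n_seg)] <- cost
    aug[cbind(seq_len(n_seg), n_seg + seq_len(n_seg))] <- bc
    aug[cbind(n_seg + seq_len(n_seg), seq_len(n_seg))] <- bc
    lr <- t(cost)
    lr[is.finite(lr)] <- 0
    aug[n_seg + seq_len(n_seg), n_seg + seq_len(n_seg)] <- lr
    sol <- solve_assignment(aug)
    joins <- which(sol[seq_len(n_seg)] <= n_seg)
    if (length(joins) == 0) return(locs)
    # apply joins; chains resolve over the repeat iterations
    for (u in joins) {
      w <- sol[u]
      from <- seg$track_id[w]
      to <- seg$track_id[u]
      locs$track_id[locs$track_id == from] <- to
    }
  }
}
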