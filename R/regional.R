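#' Assign chamber regions to localizations or track points
#'
#' Labels each record with the chamber region containing it — axonal
#' compartment (`"Ac"`), microchannel (`"distal"`), axonal stretch of the
#' cell-body compartment (`"proximal"`), or `"soma"` — based on its
#' arc-length distance from the point of cargo addition. Region intervals
#' are half-open on the axonal (upstream) side, `[lo, hi)`, so boundary
#' points are assigned deterministically. Points beyond the modelled
#' geometry are labelled `"outside"`.
#'
#' If the data carry no `dist_um` column, distances are computed by
#' projecting `(x_um, y_um)` onto the axon `path`.
#'
#' @param data Tibble with `dist_um`, or `x_um`/`y_um` plus a `path`.
#' @param geometry A [chamber_geometry()].
#' @param path Optional [axon_path()] used to compute `dist_um`.
#' @return `data` with `dist_um` and `region` columns.
#' @export
assign_region <- function(data, geometry = chamber_geometry(), path = NULL) {
  abort_if(!inherits(geometry, "chamber_geometry"), "`geometry` must be a chamber_geometry")
  if (!"dist_um" %in% names(data)) {
    abort_if(is.null(path), "supply `path` when `data` has no dist_um column")
    pr <- path_project(path, data$x_um, data$y_um)
    data$dist_um <- pr$s
  }
  br <- geometry$breaks_um
  labels <- c("Ac", "distal", "proximal", "soma")
  idx <- findInterval(data$dist_um, br, left.open = FALSE, rightmost.closed = FALSE)
  region <- ifelse(idx >= 1 & idx <= 4, labels[pmin(pmax(idx, 1), 4)], "outside")
  region[data$dist_um < 0 | data$dist_um >= br[5]] <- "outside"
  data$region <- region
  data
}

#' Spatial histogram of cargo positions
#'
#' Bins distances from the point of cargo addition into fixed-width,
#' left-closed bins (200 um by default) and summarizes counts per bin as
#' mean +/- SEM across replicates (cultures or simulation runs). Bin
#' counts sum exactly to the number of records.
#'
#' @param data Tibble with `dist_um` and (optionally) a replicate column.
#' @param bin_um Bin width in micrometres.
#' @param replicate Name of the replicate column; when absent the data are
#'   treated as one replicate and the SEM is `NA` (flagged by
#'   `n_replicates = 1`).
#' @param max_dist_um Histogram upper edge (defaults to cover the data).
#' @return Tibble: `bin_start_um`, `bin_end_um`, `mean_count`, `sem`,
#'   `n_replicates`, `total_count`.
#' @export
spatial_histogram <- function(data, bin_um = 200, replicate = NULL,
                              max_dist_um = NULL) {
  check_positive(bin_um, "bin_um")
  abort_if(!"dist_um" %in% names(data), "`data` must have a dist_um column")
  rep_vec <- if (!is.null(replicate)) data[[replicate]] else rep(1L, nrow(data))
  max_dist_um <- max_dist_um %||% (max(data$dist_um, 0) + 1e-9)
  n_bins <- max(ceiling(max_dist_um / bin_um), 1)
  bin <- pmin(floor(data$dist_um / bin_um), n_bins - 1)
  reps <- unique(rep_vec)
  grid <- tidyr::expand_grid(replicate = reps, bin = 0:(n_bins - 1))
  counts <- dplyr::count(tibble::tibble(replicate = rep_vec, bin = bin),
                         .data$replicate, .data$bin)
  counts <- dplyr::left_join(grid, counts, by = c("replicate", "bin"))
  counts$n[is.na(counts$n)] <- 0L
  out <- dplyr::summarise(dplyr::group_by(counts, .data$bin),
                          mean_count = mean(.data$n),
                          sem = if (length(reps) > 1) sd(.data$n) / sqrt(length(reps)) else NA_real_,
                          n_replicates = length(reps),
                          total_count = sum(.data$n), .groups = "drop")
  dplyr::transmute(out, bin_start_um = .data$bin * bin_um,
                   bin_end_um = (.data$bin + 1) * bin_um,
                   mean_count = .data$mean_count, sem = .data$sem,
                   n_replicates = .data$n_replicates,
                   total_count = .data$total_count)
}

#' Majority region of each track
#'
#' A track's region is the region containing the majority of its
#' localizations (ties go to the more proximal region).
#'
#' @param tracks Tracks tibble with a `region` column (see
#'   [assign_region()]).
#' @return Tibble `track_id`, `region`.
#' @export
track_region <- function(tracks) {
  order_key <- c(Ac = 1, distal = 2, proximal = 3, soma = 4, outside = 5)
  dplyr::summarise(dplyr::group_by(tracks, .data$track_id),
                   region = {
                     tab <- table(.data$region)
                     cand <- names(tab)[tab == max(tab)]
                     cand[which.max(order_key[cand])]
                   }, .groups = "drop")
}

#' Split tracks where they cross the distal/proximal boundary
#'
#' For regional statistics, a trajectory that crosses from the
#' microchannel into the cell-body compartment is split at the crossing
#' into region-pure sub-tracks (ids get a `.1`, `.2`, ... suffix and
#' become character).
#'
#' @param tracks Tracks tibble with a `region` column.
#' @param min_length Minimum localizations per sub-track kept.
#' @return The tibble with `track_id` replaced by split ids.
#' @export
split_tracks_at_boundary <- function(tracks, min_length = 2L) {
  out <- by_track(tracks, function(d) {
    d <- dplyr::arrange(d, .data$frame)
    piece <- cumsum(c(1L, diff(match(d$region, unique(d$region))) != 0))
    d$track_id_new <- paste0(d$track_id[1], ".", piece)
    d[, setdiff(names(d), "track_id")]
  })
  out$track_id <- out$track_id_new
  out$track_id_new <- NULL
  out <- dplyr::group_by(out, .data$track_id) |>
    dplyr::filter(dplyr::n() >= min_length) |> dplyr::ungroup()
  out
}

#' Region-stratified kinetic summary
#'
#' Emits the regional comparison grid: for each region, the mean +/- SEM
#' and n of the active-phase net speed, active-phase duration and
#' paused-phase duration (interior phases only, i.e. phases with known
#' beginning and end), plus the trajectory-level net speed and linearity
#' ratio. Empty region cells are reported with `n = 0` rather than
#' dropped.
#'
#' @param phases Output of [segment_phases()].
#' @param stats Output of [track_stats()].
#' @param regions Output of [track_region()] (track-level region labels).
#' @param regions_keep Regions to report (rows of the grid).
#' @return Tibble: `region`, `metric`, `mean`, `sem`, `n`.
#' @export
summarize_by_region <- function(phases, stats, regions,
                                regions_keep = c("distal", "proximal", "soma")) {
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  ph <- dplyr::left_join(phases, regions, by = "track_id") |>
    dplyr::filter(.data$interior, .data$region %in% regions_keep)
  st <- dplyr::left_join(stats, regions, by = "track_id") |>
    dplyr::filter(.data$region %in% regions_keep)
  phase_metric <- function(d, lab, col, name) {
    d <- d[d$label == lab, ]
    tibble::tibble(metric = name,
                   mean = if (nrow(d)) mean(d[[col]]) else NA_real_,
                   sem = if (nrow(d)) sem(d[[col]]) else NA_real_,
                   n = nrow(d))
  }
  track_metric <- function(d, col, name) {
    tibble::tibble(metric = name,
                   mean = if (nrow(d)) mean(d[[col]]) else NA_real_,
                   sem = if (nrow(d)) sem(d[[col]]) else NA_real_,
                   n = nrow(d))
  }
  purrr::map_dfr(regions_keep, function(rg) {
    p <- ph[ph$region == rg, ]
    s <- st[st$region == rg, ]
    dplyr::bind_rows(
      phase_metric(p, "active", "net_speed_um_s", "active_speed_um_s"),
      phase_metric(p, "active", "duration_s", "active_duration_s"),
      phase_metric(p, "paused", "duration_s", "paused_duration_s"),
      track_metric(s, "s_net_um_s", "s_net_um_s"),
      track_metric(s, "r_lin", "r_lin")) |>
      dplyr::mutate(region = rg, .before = 1)
  })
}

#' Detect coordinated multi-particle transport
#'
#' Finds pairs of co-temporal trajectories whose mean inter-particle
#' distance stays below `max_mean_dist_um` over an overlap of at least
#' `min_overlap_s`. Triplets appear as all of their pairwise records. The
#' observed maximum inter-distance and the co-travel distance (net
#' displacement of the pair midpoint over the overlap) are recorded.
#'
#' @param tracks Tracks tibble.
#' @param max_mean_dist_um Mean inter-distance criterion (2 um default).
#' @param min_overlap_s Minimum temporal overlap in seconds.
#' @return Tibble: `track_a`, `track_b`, `n_overlap`, `overlap_s`,
#'   `mean_dist_um`, `max_dist_um`, `co_travel_um`, plus a `dist_series`
#'   list-column of per-frame inter-distances.
#' @export
detect_pairs <- function(tracks, max_mean_dist_um = 2, min_overlap_s = 5) {
  ids <- unique(tracks$track_id)
  if (length(ids) < 2) {
    return(tibble::tibble(track_a = ids[0], track_b = ids[0],
                          n_overlap = integer(), overlap_s = numeric(),
                          mean_dist_um = numeric(), max_dist_um = numeric(),
                          co_travel_um = numeric(), dist_series = list()))
  }
  combos <- utils::combn(seq_along(ids), 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- tracks[tracks$track_id == ids[combos[1, k]], ]
    b <- tracks[tracks$track_id == ids[combos[2, k]], ]
    j <- dplyr::inner_join(a, b, by = "frame", suffix = c("_a", "_b"))
    if (nrow(j) < 2) return(NULL)
    overlap_s <- max(j$t_s_a) - min(j$t_s_a)
    if (overlap_s < min_overlap_s) return(NULL)
    dist <- sqrt((j$x_um_a - j$x_um_b)^2 + (j$y_um_a - j$y_um_b)^2)
    if (mean(dist) >= max_mean_dist_um) return(NULL)
    mx <- cbind((j$x_um_a + j$x_um_b) / 2, (j$y_um_a + j$y_um_b) / 2)
    tibble::tibble(track_a = ids[combos[1, k]], track_b = ids[combos[2, k]],
                   n_overlap = nrow(j), overlap_s = overlap_s,
                   mean_dist_um = mean(dist), max_dist_um = max(dist),
                   co_travel_um = sqrt(sum((mx[nrow(mx), ] - mx[1, ])^2)),
                   dist_series = list(tibble::tibble(frame = j$frame, dist_um = dist)))
  })
  res
}

#' Compare kinetic quantities between groups
#'
#' Reporting layer for two-group and multi-group comparisons: Welch's
#' two-sample t-test for two groups; one-way ANOVA with
#' multiplicity-adjusted pairwise post-hoc tests (Bonferroni by default)
#' for three or more. Zero-variance degenerate input takes an
#' exact-equality fast path.
#'
#' @param data Tibble in long format.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor.
#' @param adjust Multiple-comparison adjustment passed to
#'   [stats::pairwise.t.test()].
#' @return An object of class `group_comparison` with `summary` (per-group
#'   n/mean/SEM), `overall` (test statistic and p), and `pairwise`
#'   tibbles; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
compare_groups <- function(data, value, group, adjust = "bonferroni") {
  x <- data[[value]]
  g <- factor(data[[group]])
  abort_if(nlevels(g) < 2, "need at least two groups")
  abort_if(any(table(g) < 2), "need at least two observations per group")
  summ <- dplyr::summarise(dplyr::group_by(tibble::tibble(x = x, g = g), .data$g),
                           n = dplyr::n(), mean = mean(.data$x),
                           sem = sd(.data$x) / sqrt(dplyr::n()), .groups = "drop")
  degenerate <- all(tapply(x, g, var) == 0)
  if (degenerate) {
    same <- length(unique(tapply(x, g, mean))) == 1
    overall <- tibble::tibble(test = "degenerate", statistic = NA_real_,
                              p_value = if (same) 1 else 0)
    pairwise <- NULL
  } else if (nlevels(g) == 2) {
    tt <- t.test(x ~ g)
    overall <- tibble::tibble(test = "welch_t", statistic = unname(tt$statistic),
                              p_value = tt$p.value)
    pairwise <- tibble::tibble(group1 = levels(g)[1], group2 = levels(g)[2],
                               p_adj = tt$p.value)
  } else {
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    overall <- tibble::tibble(test = "anova_f", statistic = an$`F value`[1],
                              p_value = an$`Pr(>F)`[1])
    pw <- pairwise.t.test(x, g, p.adjust.method = adjust)
    pm <- pw$p.value
    pairwise <- purrr::map_dfr(rownames(pm), function(r) {
      purrr::map_dfr(colnames(pm), function(cc) {
        if (is.na(pm[r, cc])) return(NULL)
        tibble::tibble(group1 = cc, group2 = r, p_adj = pm[r, cc])
      })
    })
  }
  structure(list(summary = summ, overall = overall, pairwise = pairwise,
                 adjust = adjust), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$summary)
  print(x$overall)
  invisible(x)
}

#' Tidy pairwise comparisons
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise adjusted p-values.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise %||% tibble::tibble(group1 = character(), group2 = character(),
                                 p_adj = numeric())
}

#' Glance at a group comparison
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the overall test.
#' @export
glance.group_comparison <- function(x, ...) x$overall
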