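#' Simulate a movie of one or more particles on an axon strip
#'
#' End-to-end forward model: ground-truth trajectories from a motion
#' preset, quantum-dot blinking, and EMCCD rendering of a narrow strip of
#' pixels along a straight axon. The strip is just tall enough for
#' detection windows and long enough for the expected travel, which keeps
#' full movies tractable; the camera model (pixel size, frame rate,
#' noise) is unchanged.
#'
#' @param params A [motion_params()] or preset name for [motion_preset()].
#' @param n_tracks Number of particles (well separated along the axon).
#' @param total_time_s Movie duration, seconds.
#' @param camera A [camera_model()].
#' @param blink A [blink_model()], or `NULL` to disable blinking.
#' @param photons_per_frame,bg_photons Rendering photon budget.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param strip_height_px Strip height in pixels.
#' @param track_spacing_um Along-axon spacing between particle starts.
#' @return A list: `movie` (a `qd_movie` in ADU with `$truth`), `truth`
#'   (tracks tibble in strip coordinates), `path`.
#' @export
simulate_movie <- function(params = "proximal", n_tracks = 1L,
                           total_time_s = 120, camera = camera_model(),
                           blink = blink_model(), photons_per_frame = 400,
                           bg_photons = 5, psf_sigma_px = 1.3,
                           strip_height_px = 12L, track_spacing_um = 10) {
  if (is.character(params)) params <- motion_preset(params)
  px <- camera$pixel_size_um
  # expected travel plus margin decides the strip length
  frac_active <- params$active_dur_mean /
    (params$active_dur_mean + max(params$pause_dur_mean, 1e-9))
  travel_um <- params$active_speed_mean * frac_active * total_time_s * 1.6 +
    (n_tracks - 1) * track_spacing_um + 10
  margin_um <- 8 * px
  y0 <- strip_height_px / 2 * px
  path <- axon_path(length_um = travel_um, origin_um = c(margin_um, y0))
  tracks <- purrr::map_dfr(seq_len(n_tracks), function(i) {
    simulate_trajectory(params, path, camera, total_time_s,
                        start_s_um = (i - 1) * track_spacing_um, track_id = i)
  })
  if (!is.null(blink)) tracks <- apply_blinking(tracks, blink)
  ncol_px <- ceiling((travel_um + 2 * margin_um) / px)
  movie <- render_movie(tracks, camera, psf_sigma_px, photons_per_frame,
                        bg_photons, roi = c(strip_height_px, ncol_px),
                        n_frames = length(frame_times(total_time_s, camera)))
  list(movie = movie, truth = tracks, path = path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    camera = list(pixel_size_um = 0.127, frame_interval_s = 1 / 17, gain = 0.13,
                  offset = 100, read_noise = 0.65, em_excess = 2),
    simulation = list(preset = "proximal", n_tracks = 3L, total_time_s = 60,
                      photons_per_frame = 400, bg_photons = 5,
                      p_off = 0.1, p_on = 0.5,
                      strip_height_px = 12L, track_spacing_um = 15),
    detection = list(dog_sigma_small = 1, dog_sigma_large = 2,
                     threshold_sigma = 5, fit_window = 9L, psf_sigma_px = 1.3,
                     min_photons = 100),
    linking = list(max_link_distance_um = 0.5, max_gap = 8L, p_miss = 0.05,
                   gap_speed_um_s = 2, min_track_length = 10L),
    segmentation = list(v_on_um_s = 0.5, v_off_um_s = 0.3,
                        min_phase_duration_s = 0.5),
    regional = list(axonal_len_um = 100, channel_len_um = 450,
                    proximal_len_um = 500, soma_len_um = 100)
  )
}

#' Pipeline configuration
#'
#' Builds a validated nested configuration for [run_pipeline()], starting
#' from the package defaults and overriding with a YAML file or a nested
#' list. Unknown keys are rejected with their full path, so typos cannot
#' silently fall back to defaults.
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a nested
#'   list of overrides.
#' @return A `pipeline_config` (nested list).
#' @export
pipeline_config <- function(config = NULL) {
  base <- pipeline_defaults()
  if (is.null(config)) return(structure(base, class = "pipeline_config"))
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "`config` must be NULL, a YAML path, or a list")
  merged <- merge_checked(base, config, path = character())
  structure(merged, class = "pipeline_config")
}

merge_checked <- function(base, override, path) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = ".")
    abort_if(!key %in% names(base), sprintf("unknown configuration key: %s", full))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      abort_if(!is.list(override[[key]]),
               sprintf("configuration key %s must be a section", full))
      base[[key]] <- merge_checked(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Run the full tracking pipeline on a simulated or recorded movie
#'
#' Executes simulate (or load) - calibrate - detect - link - metrics -
#' classify - segment - regional summary, writing every intermediate
#' table as CSV together with a run manifest (configuration, seed,
#' package version). Identical configuration and seed give identical
#' outputs.
#'
#' @param config A [pipeline_config()], YAML path, or `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @param movie Optional `qd_movie` or TIFF path; when `NULL` a movie is
#'   simulated from the configuration's simulation section.
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config = NULL, out_dir, movie = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  camera <- do.call(camera_model, cfg$camera)
  blink <- blink_model(cfg$simulation$p_off, cfg$simulation$p_on)

  if (is.null(movie)) {
    sim <- simulate_movie(cfg$simulation$preset, cfg$simulation$n_tracks,
                          cfg$simulation$total_time_s, camera, blink,
                          cfg$simulation$photons_per_frame,
                          cfg$simulation$bg_photons,
                          cfg$detection$psf_sigma_px,
                          cfg$simulation$strip_height_px,
                          cfg$simulation$track_spacing_um)
    movie <- sim$movie
    readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
  } else if (is.character(movie)) {
    movie <- read_movie_tiff(movie)
  }

  calib <- calibration_result(camera$gain, camera$offset, camera$read_noise,
                              camera$em_excess)
  photons <- if (identical(movie$units, "ADU")) gain_calibrate(movie, calib) else movie
  det_cfg <- do.call(detection_config, cfg$detection)
  locs <- detect_spots(photons, det_cfg)
  readr::write_csv(locs, file.path(out_dir, "localizations.csv"))

  link_cfg <- do.call(link_config, cfg$linking)
  tracks <- link_movie(locs, link_cfg, blink)
  readr::write_csv(tracks, file.path(out_dir, "tracks.csv"))

  results <- list(locs = locs, tracks = tracks)
  if (nrow(tracks) > 0) {
    stats <- track_stats(tracks, max_gap = link_cfg$max_gap, diffusion = TRUE)
    vel <- instantaneous_velocity(tracks)
    seg_cfg <- do.call(segment_config, cfg$segmentation)
    classes <- classify_motion(stats, vel, tracks, seg_cfg)
    at_ids <- classes$track_id[classes$motion_class == "AT"]
    phases <- segment_phases(dplyr::filter(tracks, .data$track_id %in% at_ids),
                             dplyr::filter(vel, .data$track_id %in% at_ids), seg_cfg)
    geometry <- do.call(chamber_geometry, cfg$regional)
    reg_tracks <- assign_region(tracks, geometry,
                                path = axon_path(length_um = sum(unlist(cfg$regional))))
    regions <- track_region(reg_tracks)
    regional <- summarize_by_region(phases, stats, regions)
    pairs <- detect_pairs(tracks)
    readr::write_csv(stats, file.path(out_dir, "track_stats.csv"))
    readr::write_csv(vel, file.path(out_dir, "velocity.csv"))
    readr::write_csv(classes, file.path(out_dir, "motion_classes.csv"))
    readr::write_csv(phases, file.path(out_dir, "phases.csv"))
    readr::write_csv(regional, file.path(out_dir, "regional_summary.csv"))
    if (nrow(pairs)) {
      readr::write_csv(dplyr::select(pairs, -"dist_series"),
                       file.path(out_dir, "pairs.csv"))
    }
    results <- c(results, list(stats = stats, velocity = vel, classes = classes,
                               phases = phases, regional = regional, pairs = pairs))
  }
  manifest <- list(package = "axodyn",
                   version = as.character(utils::packageVersion("axodyn")),
                   seed = cfg$seed, config = unclass(cfg))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
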