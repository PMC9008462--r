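test_that("phase sequences alternate, tile the requested time, and are reproducible", {
  set.seed(1)
  params <- motion_preset("distal")
  ph <- sample_phase_sequence(params, 120)
  expect_true(all(ph$label[c(TRUE, FALSE)] == "active"))
  expect_true(all(ph$label[c(FALSE, TRUE)] == "paused"))
  expect_equal(sum(ph$duration_s), 120)
  expect_equal(ph$t_end[nrow(ph)], 120)

  set.seed(42)
  a <- sample_phase_sequence(params, 120)
  set.seed(42)
  b <- sample_phase_sequence(params, 120)
  expect_identical(a, b)

  # renewal theory: expected phase count ~ total / (mean cycle / 2 phases)
  set.seed(2)
  counts <- replicate(400, nrow(sample_phase_sequence(params, 120)))
  expected <- 2 * 120 / (params$active_dur_mean + params$pause_dur_mean)
  expect_gt(mean(counts), expected * 0.8)
  expect_lt(mean(counts), expected * 1.3)
})

test_that("a vanishing pause mean degenerates to a single active phase", {
  p <- motion_params("AT", pause_dur_mean = 0)
  ph <- sample_phase_sequence(p, 60)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$label, "active")
  expect_equal(ph$duration_s, 60)
  expect_error(sample_phase_sequence(motion_params("AT"), -5), "positive")
  expect_error(motion_params("AT", active_dur_mean = -1), "positive")
})

test_that("active-transport kinematics follow the drawn phase plan", {
  # one active phase at fixed speed: net displacement = speed * time
  p <- motion_params("AT", active_speed_mean = 1.5, active_speed_sd = 0,
                     pause_dur_mean = 0, pause_jitter_sd = 0)
  tr <- simulate_trajectory(p, axon_path(50), camera_model(), total_time_s = 10)
  expect_equal(max(tr$s_um) - min(tr$s_um), 1.5 * 10, tolerance = 1e-6)
  expect_true(all(tr$phase == "active"))

  # stationary particle with zero jitter does not move
  s <- motion_params("S", pause_jitter_sd = 0)
  tr_s <- simulate_trajectory(s, axon_path(50), camera_model(), 5, start_s_um = 10)
  expect_equal(var(tr_s$x_um), 0)
  expect_equal(var(tr_s$y_um), 0)
})

test_that("confined back-and-forth motion stays inside its domain and fills it", {
  set.seed(3)
  p <- motion_params("B&F", confinement_length_um = 5, bf_diffusion_um2_s = 0.15)
  tr <- simulate_trajectory(p, axon_path(50), camera_model(), 600, start_s_um = 10)
  expect_gte(min(tr$s_um), 10)
  expect_lte(max(tr$s_um), 15)
  expect_lte(max(tr$s_um) - min(tr$s_um), 5)
  # stationary occupancy of reflected diffusion is uniform on the domain:
  # check its first two moments (mixing is slow, so exact-distribution
  # tests on correlated samples would be anticonservative)
  expect_equal(mean(tr$s_um), 12.5, tolerance = 0.05)
  expect_equal(sd(tr$s_um), 5 / sqrt(12), tolerance = 0.15)
  expect_gt(max(tr$s_um), 14)
  expect_lt(min(tr$s_um), 11)
})

test_that("coordinated pairs share phases and never separate by 2 um", {
  set.seed(4)
  p <- motion_preset("pair")
  pair <- simulate_pair(p, axon_path(300), camera_model(), total_time_s = 40,
                        start_s_um = 5)
  wide <- tidyr::pivot_wider(pair[, c("track_id", "frame", "s_um", "phase")],
                             names_from = "track_id",
                             values_from = c("s_um", "phase"))
  expect_true(all(abs(wide$s_um_1 - wide$s_um_2) < 2))
  expect_identical(wide$phase_1, wide$phase_2)

  # rigid tether: constant separation
  p0 <- motion_params("AT_pair", pair_coupling_rest_um = 0.5, pair_coupling_sd_um = 0)
  pr <- simulate_pair(p0, axon_path(300), camera_model(), 20, start_s_um = 5)
  d <- abs(pr$s_um[pr$track_id == 1] - pr$s_um[pr$track_id == 2])
  expect_true(all(abs(d - 0.5) < 1e-9))

  expect_error(motion_params("AT_pair", pair_coupling_rest_um = 1.9,
                             pair_coupling_sd_um = 0.5), "2 um")
})

test_that("blinking is a two-state chain with geometric dark dwells", {
  tr <- make_linear_track(60, 1)
  tr$visible <- TRUE
  expect_true(all(apply_blinking(tr, blink_model(p_off = 0, p_on = 0.5))$visible))

  set.seed(5)
  long <- make_linear_track(40000, 0)
  long$visible <- TRUE
  b <- apply_blinking(long, blink_model(p_off = 0.05, p_on = 0.5))
  r <- rle(b$visible)
  dark <- r$lengths[!r$values]
  expect_gt(length(dark), 500)
  expect_equal(mean(dark), 2, tolerance = 0.1)  # geometric mean 1/p_on

  set.seed(9); m1 <- apply_blinking(long, blink_model())$visible
  set.seed(9); m2 <- apply_blinking(long, blink_model())$visible
  expect_identical(m1, m2)
})

test_that("renewal property: long-run net speed approaches the closed form", {
  set.seed(6)
  params <- motion_preset("distal")
  speeds <- purrr::map_dbl(1:40, function(i) {
    tr <- simulate_trajectory(params, axon_path(2000), camera_model(), 1000)
    (tr$s_um[nrow(tr)] - tr$s_um[1]) / (tr$t_s[nrow(tr)] - tr$t_s[1])
  })
  closed <- params$active_speed_mean * params$active_dur_mean /
    (params$active_dur_mean + params$pause_dur_mean)
  expect_equal(mean(speeds), closed, tolerance = 0.02)
})

test_that("rendering reproduces the camera model", {
  cam <- camera_model(roi = c(24, 24), read_noise = 0)
  empty <- tibble::tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                          x_um = numeric(), y_um = numeric(), visible = logical())
  set.seed(7)
  mv0 <- render_movie(empty, cam, bg_photons = 0, n_frames = 5)
  expect_true(all(mv0$frames == cam$offset))

  # photon conservation: calibrated sum over an isolated spot ~ photons + bg*area
  set.seed(8)
  tr <- tibble::tibble(track_id = 1L, frame = 1:300, t_s = (0:299) / 17,
                       x_um = 12 * cam$pixel_size_um, y_um = 12 * cam$pixel_size_um,
                       visible = TRUE)
  mv <- render_movie(tr, cam, 1.3, photons_per_frame = 500, bg_photons = 4)
  ph <- gain_calibrate(mv, calibration_result(cam$gain, cam$offset, 0))
  sums <- apply(ph$frames, 3, sum)
  expect_equal(mean(sums), 500 + 4 * 24 * 24, tolerance = 0.01)

  # bit-identical movies from the same seed
  set.seed(11); a <- render_movie(tr, cam, 1.3, 500, 4)
  set.seed(11); b <- render_movie(tr, cam, 1.3, 500, 4)
  expect_identical(a$frames, b$frames)

  expect_error(render_movie(tr, cam, 1.3, photons_per_frame = 0), "> 0")
})

test_that("fixed-field rendering produces countable ground truth", {
  set.seed(10)
  f0 <- render_fixed_field(0)
  expect_equal(f0$n_spots, 0)
  expect_equal(nrow(f0$truth), 0)
  f <- render_fixed_field(20, field_px = c(256, 256))
  expect_equal(nrow(f$truth), 20)
  expect_equal(nrow(count_fixed_stack(f$stack)), 20)
  expect_error(render_fixed_field(500, field_px = c(64, 64)), "density")
})
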