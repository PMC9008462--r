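test_that("region assignment partitions points with half-open boundaries", {
  geom <- chamber_geometry(axonal_len_um = 100, channel_len_um = 450,
                           proximal_len_um = 500, soma_len_um = 100)
  pts <- tibble::tibble(dist_um = c(50, 100, 325, 549.999, 550, 800, 1050, 1200, -5))
  out <- assign_region(pts, geom)
  expect_equal(out$region, c("Ac", "distal", "distal", "distal", "proximal",
                             "proximal", "soma", "outside", "outside"))
  # every point gets exactly one label, stable under re-run
  expect_identical(assign_region(pts, geom)$region, out$region)

  # from coordinates via path projection
  path <- axon_path(1200)
  xy <- tibble::tibble(x_um = c(150, 700), y_um = c(0.2, -0.1))
  got <- assign_region(xy, geom, path)
  expect_equal(got$region, c("distal", "proximal"))
  expect_equal(got$dist_um, c(150, 700), tolerance = 1e-6)
})

test_that("spatial histograms conserve counts and recover uniformity", {
  d <- tibble::tibble(dist_um = c(50, 50, 50))
  h <- spatial_histogram(d)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_start_um, 0)
  expect_equal(h$total_count, 3L)
  expect_true(is.na(h$sem))

  set.seed(71)
  u <- tibble::tibble(dist_um = runif(5000, 0, 1000),
                      culture = rep(1:5, each = 1000))
  hu <- spatial_histogram(u, bin_um = 200, replicate = "culture")
  expect_equal(sum(hu$total_count), 5000L)
  expect_equal(nrow(hu), 5)
  # multinomial: each bin near n/5 within a few binomial SDs
  expect_true(all(abs(hu$total_count - 1000) < 4 * sqrt(5000 * 0.2 * 0.8)))
  expect_equal(hu$n_replicates, rep(5L, 5))
})

test_that("the regional summary grid reproduces generative kinetics", {
  set.seed(72)
  cam <- camera_model()
  geom <- chamber_geometry()
  path <- axon_path(1150)
  mk <- function(preset, start, ids) {
    purrr::map_dfr(ids, function(i) {
      add_localization_noise(
        simulate_trajectory(motion_preset(preset), path, cam, 120,
                            start_s_um = start, track_id = i), 0.02)
    })
  }
  distal <- mk("distal", 150, 1:8)
  proximal <- mk("proximal", 600, 9:16)
  tracks <- dplyr::bind_rows(distal, proximal)
  tracks <- assign_region(tracks, geom, path)
  regions <- track_region(tracks)
  stats <- track_stats(tracks)
  phases <- segment_phases(tracks)
  grid <- summarize_by_region(phases, stats, regions)
  expect_setequal(unique(grid$region), c("distal", "proximal", "soma"))
  expect_setequal(unique(grid$metric),
                  c("active_speed_um_s", "active_duration_s", "paused_duration_s",
                    "s_net_um_s", "r_lin"))
  expect_equal(nrow(grid), 15)
  # empty soma cells are reported, not dropped
  expect_true(all(grid$n[grid$region == "soma"] == 0))
  g <- function(r, m) grid$mean[grid$region == r & grid$metric == m]
  expect_equal(g("distal", "active_speed_um_s"), 1.531, tolerance = 0.15)
  expect_equal(g("proximal", "active_speed_um_s"), 1.544, tolerance = 0.15)
  expect_equal(g("proximal", "paused_duration_s"), 1.931, tolerance = 0.2)
  # distal tracks are slower overall than proximal ones (longer pauses)
  expect_lt(g("distal", "s_net_um_s"), g("proximal", "s_net_um_s"))
})

test_that("coordinated pairs are detected and characterized", {
  set.seed(73)
  cam <- camera_model()
  far_a <- make_linear_track(120, 1, id = 1L)
  far_b <- make_linear_track(120, 1, y0 = 50, id = 2L)
  expect_equal(nrow(detect_pairs(dplyr::bind_rows(far_a, far_b))), 0)

  pair <- simulate_pair(motion_preset("pair"), axon_path(300), cam,
                        total_time_s = 40, start_s_um = 5)
  pr <- detect_pairs(pair)
  expect_equal(nrow(pr), 1)
  expect_lt(pr$max_dist_um, 2)
  expect_gt(pr$overlap_s, 39)
  # proximal kinetics sustain tens of micrometres of co-travel over 40 s
  expect_gt(pr$co_travel_um, 20)
})

test_that("group comparisons report means, tests and corrected post-hocs", {
  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  cmp0 <- compare_groups(same, "v", "g")
  expect_gt(glance(cmp0)$p_value, 0.9)

  set.seed(74)
  shift <- tibble::tibble(v = c(rnorm(50), rnorm(50, 1)),
                          g = rep(c("a", "b"), each = 50))
  cmp1 <- compare_groups(shift, "v", "g")
  expect_lt(glance(cmp1)$p_value, 0.05)

  # closed-form power at delta = 1 SD, n = 50: essentially certain detection
  power <- stats::power.t.test(n = 50, delta = 1, sd = 1)$power
  expect_gt(power, 0.99)

  set.seed(75)
  k3 <- tibble::tibble(v = c(rnorm(30), rnorm(30, 2), rnorm(30)),
                       g = rep(c("a", "b", "c"), each = 30))
  cmp3 <- compare_groups(k3, "v", "g")
  expect_equal(glance(cmp3)$test, "anova_f")
  pw <- tidy(cmp3)
  expect_equal(nrow(pw), 3)
  expect_lt(pw$p_adj[pw$group1 == "a" & pw$group2 == "b"], 0.01)

  # ANOVA type-I error control on null data
  set.seed(76)
  pvals <- replicate(400, {
    d <- tibble::tibble(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
    glance(compare_groups(d, "v", "g"))$p_value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)

  deg <- tibble::tibble(v = rep(1, 6), g = rep(c("a", "b"), each = 3))
  expect_equal(glance(compare_groups(deg, "v", "g"))$p_value, 1)
})

test_that("tracks crossing the compartment boundary are split for regional stats", {
  geom <- chamber_geometry()
  tr <- make_linear_track(200, vx = 2, dt = 1, x0 = 400)  # crosses 550 um
  tr <- assign_region(tr, geom, axon_path(1200))
  split <- split_tracks_at_boundary(tr)
  expect_equal(length(unique(split$track_id)), 2)
  expect_true(all(table(split$track_id, split$region) %in%
                    c(0, table(tr$region))))
})
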