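loc_tbl <- function(x, y) tibble::tibble(x_um = x, y_um = y)

test_that("cost matrices encode links, births and deaths correctly", {
  cfg <- link_config()
  blink <- blink_model()
  bc <- -log(blink$p_off + cfg$p_miss)

  cm <- build_cost_matrix(loc_tbl(0, 0), loc_tbl(0, 0), cfg, blink)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(cm[1, 1], 0)          # zero displacement
  expect_equal(cm[1, 2], bc)         # death
  expect_equal(cm[2, 1], bc)         # birth
  sol <- solve_assignment(cm)
  expect_equal(sol[1], 1L)           # linked: 0 < birth + death

  far <- build_cost_matrix(loc_tbl(0, 0), loc_tbl(10, 0), cfg, blink)
  expect_true(is.infinite(far[1, 1]))
  sol2 <- solve_assignment(far)
  expect_equal(sol2[1], 2L)          # dies; new particle born
})

test_that("assignment solver matches exhaustive search", {
  set.seed(41)
  for (n in 2:4) {
    for (rep in 1:20) {
      cost <- matrix(runif(n * n), n, n)
      cost[runif(n * n) < 0.2] <- Inf
      oracle <- oracle_lap(cost)
      if (!is.finite(oracle$cost)) next
      sol <- solve_assignment(cost)
      expect_equal(attr(sol, "cost"), oracle$cost, tolerance = 1e-12)
    }
  }
  diag_cost <- matrix(1, 3, 3); diag(diag_cost) <- 0
  expect_equal(as.integer(solve_assignment(diag_cost)), 1:3)
  # permuting rows permutes the matching
  set.seed(42)
  cost <- matrix(runif(16), 4, 4)
  base <- solve_assignment(cost)
  perm <- c(3, 1, 4, 2)
  permuted <- solve_assignment(cost[perm, ])
  expect_equal(as.integer(permuted), as.integer(base)[perm])
  expect_error(solve_assignment(matrix(Inf, 2, 2)), "infeasible")
})

test_that("frame-transition linking cost is optimal versus brute force", {
  set.seed(43)
  cfg <- link_config(max_link_distance_um = 1)
  blink <- blink_model()
  bc <- -log(blink$p_off + cfg$p_miss)
  for (rep in 1:10) {
    a <- loc_tbl(runif(3), runif(3))
    b <- loc_tbl(runif(3), runif(3))
    d2 <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
    cm <- build_cost_matrix(a, b, cfg, blink)
    sol <- solve_assignment(cm)
    expect_equal(attr(sol, "cost"), oracle_link_cost(d2, 1, bc), tolerance = 1e-10)
  }
})

test_that("a steady particle yields one trajectory covering all frames", {
  tr <- make_linear_track(60, 1)
  locs <- dplyr::mutate(tr, accepted = TRUE)
  tracks <- link_movie(locs)
  expect_equal(length(unique(tracks$track_id)), 1)
  expect_equal(nrow(tracks), 60)
  expect_equal(tracks$frame, 1:60)
})

test_that("blink gaps are bridged up to max_gap and split beyond it", {
  tr <- make_linear_track(80, 1)
  dark <- c(20:22, 50:52)                 # two 3-frame dark dwells
  locs <- dplyr::mutate(tr[-dark, ], accepted = TRUE)
  bridged <- link_movie(locs, link_config(max_gap = 5))
  expect_equal(length(unique(bridged$track_id)), 1)
  split <- link_movie(locs, link_config(max_gap = 1, min_track_length = 5))
  expect_equal(length(unique(split$track_id)), 3)
})

test_that("well-separated particles never swap identity", {
  a <- make_linear_track(60, 1, id = 1L)
  b <- make_linear_track(60, 1, y0 = 30, id = 2L)
  locs <- dplyr::bind_rows(a, b)
  locs$true_id <- locs$track_id
  tracks <- link_movie(dplyr::mutate(locs, accepted = TRUE))
  purity <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(p = max(table(.data$true_id)) / dplyr::n())
  expect_equal(length(unique(tracks$track_id)), 2)
  expect_true(all(purity$p == 1))
})

test_that("linking is invariant to global translation", {
  set.seed(44)
  tr <- make_linear_track(40, 1.2)
  tr$x_um <- tr$x_um + rnorm(40, 0, 0.02)
  locs <- dplyr::mutate(tr, accepted = TRUE)
  base <- link_movie(locs)
  shifted <- dplyr::mutate(locs, x_um = .data$x_um + 100, y_um = .data$y_um - 55)
  moved <- link_movie(shifted)
  expect_equal(moved$track_id, base$track_id)
  expect_equal(moved$x_um - 100, base$x_um)
})

test_that("purity and completeness stay high under blinking at default density", {
  set.seed(45)
  cam <- camera_model()
  path <- axon_path(250)
  truth <- purrr::map_dfr(1:5, function(i) {
    simulate_trajectory(motion_preset("proximal"), path, cam, 60,
                        start_s_um = (i - 1) * 40, track_id = i)
  })
  truth <- apply_blinking(truth, blink_model())
  noisy <- add_localization_noise(truth, 0.02)
  locs <- dplyr::mutate(noisy[noisy$visible, ],
                        true_id = .data$track_id, accepted = TRUE)
  locs$track_id <- NULL
  tracks <- link_movie(locs)
  by_tr <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(n = dplyr::n(), purity = max(table(.data$true_id)) / dplyr::n())
  purity <- sum(by_tr$purity * by_tr$n) / sum(by_tr$n)
  # association-level completeness: consecutive detections of one particle
  # should stay in one recovered track (dark dwells longer than max_gap
  # legitimately split a track and are governed by the gap-closing radius)
  completeness <- purrr::map_dbl(1:5, function(i) {
    d <- dplyr::arrange(tracks[tracks$true_id == i, ], .data$frame)
    mean(d$track_id[-1] == d$track_id[-nrow(d)])
  })
  expect_gte(purity, 0.95)
  expect_gte(mean(completeness), 0.95)
})
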