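ideal_spot <- function(nrow = 21, ncol = 21, x = 10.5, y = 10.5,
                       photons = 500, bg = 0, sigma = 1.3) {
  axodyn:::.render_frame_ideal_cpp(nrow, ncol, x, y, photons, sigma, bg)
}

test_that("difference-of-Gaussians filter rejects DC and is linear", {
  const <- matrix(7, 16, 16)
  expect_lt(max(abs(dog_filter(const))), 1e-10)

  set.seed(31)
  a <- matrix(runif(256), 16, 16)
  b <- matrix(runif(256), 16, 16)
  expect_equal(dog_filter(2 * a + 3 * b), 2 * dog_filter(a) + 3 * dog_filter(b),
               tolerance = 1e-12)

  img <- ideal_spot(x = 9.3, y = 12.8)
  resp <- dog_filter(img)
  peak <- which(resp == max(resp), arr.ind = TRUE)
  # pixel (r, c) spans [c-1, c) x [r-1, r): the peak pixel contains the spot
  expect_lt(abs(peak[1, "col"] - 0.5 - 9.3), 1)
  expect_lt(abs(peak[1, "row"] - 0.5 - 12.8), 1)
  expect_error(dog_filter(img, 2, 1), "sigma")
})

test_that("candidate finding returns strict local maxima above threshold", {
  img <- ideal_spot(31, 31, x = 8.5, y = 8.5) + ideal_spot(31, 31, x = 22.5, y = 22.5)
  resp <- dog_filter(img)
  cand <- find_candidates(resp, max(resp) / 4)
  expect_equal(nrow(cand), 2)
  expect_equal(nrow(find_candidates(resp, max(resp) + 1)), 0)
  expect_equal(nrow(find_candidates(matrix(0, 8, 8), 0.5)), 0)
  # plateau tie broken toward the smallest (row, col)
  plat <- matrix(0, 7, 7); plat[3:4, 4] <- 5
  got <- find_candidates(plat, 1)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$row, got$col), c(3, 4))
})

test_that("noiseless spots are localized to sub-millipixel accuracy", {
  cfg <- detection_config()
  for (dx in c(0, 0.27, -0.41)) {
    for (dy in c(0, 0.33)) {
      img <- ideal_spot(x = 10.5 + dx, y = 10.5 + dy, bg = 2)
      fit <- fit_spot_mle(img, tibble::tibble(row = 11, col = 11), cfg)
      expect_lt(abs(fit$x_px - (10.5 + dx)), 1e-3)
      expect_lt(abs(fit$y_px - (10.5 + dy)), 1e-3)
      expect_equal(fit$photons, 500, tolerance = 1e-3)
      expect_equal(fit$background, 2, tolerance = 1e-3)
    }
  }
})

test_that("localization error reaches the Cramer-Rao bound under Poisson noise", {
  set.seed(32)
  cfg <- detection_config()
  for (N in c(200, 500, 2000)) {
    truth <- c(7.43, 8.11)
    model <- ideal_spot(15, 15, x = truth[1], y = truth[2], photons = N, bg = 5)
    fits <- purrr::map_dfr(1:300, function(i) {
      noisy <- matrix(rpois(225, model), 15, 15)
      fit_spot_mle(noisy, tibble::tibble(row = 9, col = 8), cfg)
    })
    rmse <- sqrt(mean((fits$x_px - truth[1])^2))
    crlb <- mean(fits$precision_x_px)
    expect_lt(abs(rmse / crlb - 1), 0.15)
  }
})

test_that("intensity and fit-quality filters reject what they should", {
  cfg <- detection_config()
  img <- ideal_spot(x = 10.5, y = 10.5, photons = 500, bg = 5)
  set.seed(33)
  noisy <- matrix(rpois(441, img), 21, 21)
  # a cosmic-ray single-pixel spike is a terrible Gaussian fit
  spike <- noisy
  spike[4, 16] <- 4000
  locs <- fit_spot_mle(spike, tibble::tibble(row = c(11, 4), col = c(11, 16)), cfg)
  out <- filter_localizations(locs, cfg)
  expect_true(out$accepted[1])
  expect_false(out$accepted[2])
  expect_true(out$reject_reason[2] %in% c("poor_fit", "not_converged"))
  # a converged fit of a smaller spike is rejected on its deviance
  spike2 <- noisy
  spike2[4, 16] <- 600
  l2 <- fit_spot_mle(spike2, tibble::tibble(row = 4, col = 16), cfg)
  if (l2$converged) expect_gt(l2$fit_quality, 3 * (l2$n_px - 4))

  # an empty window fits ~zero photons and fails the intensity filter
  empty <- matrix(rpois(441, 5), 21, 21)
  lo <- filter_localizations(fit_spot_mle(empty, tibble::tibble(row = 11, col = 11), cfg), cfg)
  expect_false(lo$accepted[1])

  # thresholds wide open keep everything that converged
  loose <- detection_config(min_photons = 0, max_fit_quality = Inf)
  all_in <- filter_localizations(locs, loose)
  expect_true(all(all_in$accepted[all_in$converged]))
})

test_that("fixed-stack counting is accurate and photon-budget invariant", {
  set.seed(34)
  f <- render_fixed_field(50, field_px = c(384, 384))
  cnt <- count_fixed_stack(f$stack)
  expect_lt(abs(nrow(cnt) - 50) / 50, 0.05)
  # positions match the truth
  d <- as.matrix(stats::dist(rbind(cbind(f$truth$x_um, f$truth$y_um),
                                   cbind(cnt$x_um, cnt$y_um))))
  nearest <- apply(d[1:50, -(1:50), drop = FALSE], 1, min)
  expect_lt(median(nearest), 0.1)

  set.seed(35)
  f0 <- render_fixed_field(0, field_px = c(128, 128))
  expect_equal(nrow(count_fixed_stack(f0$stack)), 0)
})

test_that("detection on movies achieves high recall and precision", {
  set.seed(36)
  sim <- simulate_movie("proximal", total_time_s = 12)
  ph <- gain_calibrate(sim$movie, calibration_result(0.13, 100, 0.65))
  locs <- detect_spots(ph)
  acc <- locs[locs$accepted, ]
  truth <- sim$truth[sim$truth$visible, ]
  j <- dplyr::inner_join(acc, truth, by = "frame", suffix = c("", "_t"))
  hit <- sqrt((j$x_um - j$x_um_t)^2 + (j$y_um - j$y_um_t)^2) < 0.25
  recall <- sum(hit) / nrow(truth)
  precision <- sum(hit) / nrow(acc)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
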