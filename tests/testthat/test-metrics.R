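test_that("trajectory statistics match their closed-form examples", {
  # 3-4-5 triangle over 5 s
  st <- track_stats(make_track(c(0, 3), c(0, 4), c(0, 5)))
  expect_equal(st$d_net_um, 5)
  expect_equal(st$s_net_um_s, 1)
  expect_equal(st$r_lin, 1)

  # out-and-back: zero net motion, unit mean speed
  st2 <- track_stats(make_track(c(0, 1, 0), c(0, 0, 0), c(0, 1, 2)))
  expect_equal(st2$d_net_um, 0)
  expect_equal(st2$s_net_um_s, 0)
  expect_equal(st2$s_mean_um_s, 1)
  expect_equal(st2$r_lin, 0)
  expect_equal(st2$d_max_um, 1)

  expect_error(track_stats(make_track(c(0, 1), c(0, 0), c(1, 1))), "duplicate")
  expect_error(track_stats(make_track(0, 0, 0)), "at least 2")
})

test_that("all six statistics equal a brute-force oracle on random tracks", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    t <- cumsum(runif(n, 0.01, 0.2))
    x <- cumsum(rnorm(n, 0.05, 0.3))
    y <- cumsum(rnorm(n, 0, 0.3))
    st <- track_stats(make_track(x, y, t))
    or <- oracle_track_stats(x, y, t)
    expect_equal(st$d_net_um, or$d_net, tolerance = 1e-12)
    expect_equal(st$d_max_um, or$d_max, tolerance = 1e-12)
    expect_equal(st$s_net_um_s, or$s_net, tolerance = 1e-12)
    expect_equal(st$s_mean_um_s, or$s_mean, tolerance = 1e-12)
    expect_equal(st$r_lin, min(or$r_lin, 1), tolerance = 1e-12)
  }
})

test_that("statistics respect rigid-motion invariance and r_lin bounds", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    t <- cumsum(runif(n, 0.02, 0.2))
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    st <- track_stats(make_track(x, y, t))
    expect_gte(st$r_lin, 0)
    expect_lte(st$r_lin, 1)
    th <- runif(1, 0, 2 * pi)
    xr <- cos(th) * x - sin(th) * y + 5
    yr <- sin(th) * x + cos(th) * y - 3
    str <- track_stats(make_track(xr, yr, t))
    expect_equal(str$d_net_um, st$d_net_um, tolerance = 1e-9)
    expect_equal(str$d_max_um, st$d_max_um, tolerance = 1e-9)
    expect_equal(str$s_mean_um_s, st$s_mean_um_s, tolerance = 1e-9)
    # spatial rescaling scales the speeds linearly
    sts <- track_stats(make_track(3 * x, 3 * y, t))
    expect_equal(sts$s_net_um_s, 3 * st$s_net_um_s, tolerance = 1e-9)
    expect_equal(sts$s_mean_um_s, 3 * st$s_mean_um_s, tolerance = 1e-9)
  }
})

test_that("windowed velocity is exact on linear motion and truncates at ends", {
  tr <- make_linear_track(30, vx = 1, vy = 0)
  v <- instantaneous_velocity(tr)
  expect_equal(nrow(v), 30)
  expect_true(all(abs(v$vx_um_s - 1) < 1e-10))
  expect_true(all(abs(v$speed_um_s - 1) < 1e-10))

  v7 <- instantaneous_velocity(make_linear_track(7, 1))
  expect_equal(v7$support[4], 7L)       # centre has the full window
  expect_true(all(v7$support >= 4L))
  expect_equal(v7$support[1], 4L)

  expect_equal(nrow(instantaneous_velocity(make_linear_track(3, 1))), 0)
})

test_that("slope-estimate variance matches the closed form", {
  # equally spaced LS slope variance: 12 sigma^2 / (dt^2 w (w^2 - 1))
  set.seed(53)
  dt <- 0.06; w <- 7; sigma <- 0.03
  closed <- 12 * sigma^2 / (dt^2 * w * (w^2 - 1))
  t <- (0:(w - 1)) * dt
  slopes <- replicate(10000, axodyn:::ls_slope(t, rnorm(w, 0, sigma)))
  expect_equal(var(slopes), closed, tolerance = 0.05)
  # interior full-window velocity estimates reproduce it too
  tr <- make_linear_track(2000, vx = 1, dt = dt)
  tr$x_um <- tr$x_um + rnorm(2000, 0, sigma)
  v <- instantaneous_velocity(tr)
  interior <- v$support == 7
  expect_equal(var(v$vx_um_s[interior]), closed, tolerance = 0.1)
})

test_that("diffusion MLE matches a grid-search oracle and handles edge cases", {
  set.seed(54)
  D <- 0.1; dt <- 0.06; n <- 400; sig <- 0.02
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
  tr <- dplyr::mutate(make_track(x, y, (0:(n - 1)) * dt), precision_um = sig)
  est <- estimate_diffusion(tr)
  # independent oracle: dense grid over the same likelihood, written out here
  nll <- function(D) {
    v <- 2 * D * dt + 2 * sig^2
    0.5 * sum(log(2 * pi * v) + diff(x)^2 / v) +
      0.5 * sum(log(2 * pi * v) + diff(y)^2 / v)
  }
  grid <- seq(1e-4, 0.5, by = 1e-4)
  d_grid <- grid[which.min(vapply(grid, nll, 0))]
  expect_equal(est$D_um2_s, d_grid, tolerance = 1e-3)
  expect_lt(est$D_conf_low, est$D_um2_s)
  expect_gt(est$D_conf_high, est$D_um2_s)

  # static track with zero precision collapses to zero
  still <- dplyr::mutate(make_track(rep(1, 20), rep(2, 20)), precision_um = 0)
  est0 <- estimate_diffusion(still)
  expect_equal(est0$D_um2_s, 0)
  expect_true(est0$degenerate)
})

test_that("diffusion MLE stays unbiased with heterogeneous precision", {
  set.seed(55)
  D <- 0.1; dt <- 0.06; n <- 300
  res <- purrr::map_dfr(1:60, function(i) {
    sig <- rep(c(0.02, 0.2), length.out = n)   # half the points 10x worse
    x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
    y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
    tr <- dplyr::mutate(make_track(x, y, (0:(n - 1)) * dt), precision_um = sig)
    naive <- mean((diff(x)^2 + diff(y)^2) / (4 * dt))
    tibble::tibble(mle = estimate_diffusion(tr)$D_um2_s, naive = naive)
  })
  expect_equal(mean(res$mle), D, tolerance = 0.1)
  expect_gt(mean(res$naive), 2 * D)   # the naive MSD estimator is badly inflated
})

test_that("diffusion bias is below 5 percent across three decades", {
  set.seed(56)
  dt <- 0.06; n <- 1000; sig <- 0.02
  for (D in c(0.01, 0.1, 1)) {
    ests <- purrr::map_dbl(1:25, function(i) {
      x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
      y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))) + rnorm(n, 0, sig)
      tr <- dplyr::mutate(make_track(x, y, (0:(n - 1)) * dt), precision_um = sig)
      estimate_diffusion(tr)$D_um2_s
    })
    expect_lt(abs(mean(ests) - D) / D, 0.05)
  }
})

test_that("the tridiagonal-covariance option behaves like the default when noise is small", {
  set.seed(57)
  D <- 0.2; dt <- 0.06; n <- 300
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt))))
  tr <- dplyr::mutate(make_track(x, y, (0:(n - 1)) * dt), precision_um = 1e-4)
  a <- estimate_diffusion(tr, method = "independent")$D_um2_s
  b <- estimate_diffusion(tr, method = "tridiagonal")$D_um2_s
  expect_equal(a, b, tolerance = 1e-3)
})
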