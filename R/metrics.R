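#' Per-trajectory summary statistics
#'
#' Computes, for each track, the standard trajectory statistics used to
#' characterize particle motion: net displacement
#' `d_net = ||p_N - p_1||`, maximum displacement
#' `d_max = max_{i,j} ||p_i - p_j||`, net speed
#' `s_net = d_net / (t_N - t_1)`, mean curvilinear speed
#' `s_mean = mean(||p_{i+1} - p_i|| / (t_{i+1} - t_i))`, and the linearity
#' of forward progression `r_lin = s_net / s_mean` (1 for perfectly
#' directed motion, near 0 for random motion). Increments spanning more
#' than `max_gap` frames (blink gaps) are excluded from `s_mean` so that
#' long dark dwells do not dilute the speed estimate; all other statistics
#' use the actual time differences.
#'
#' @param tracks Tracks tibble with `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`.
#' @param max_gap Increments spanning more than this many frames are
#'   excluded from the mean curvilinear speed (`Inf` keeps all).
#' @param diffusion If `TRUE`, adds the maximum-likelihood diffusion
#'   constant and its confidence interval via [estimate_diffusion()].
#' @return One row per track: `track_id`, `n_locs`, `duration_s`,
#'   `d_net_um`, `d_max_um`, `s_net_um_s`, `s_mean_um_s`, `r_lin` (and
#'   diffusion columns when requested).
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 1:2, t_s = c(0, 5),
#'                      x_um = c(0, 3), y_um = c(0, 4))
#' track_stats(tr)  # d_net 5, s_net 1, r_lin 1
#' @export
track_stats <- function(tracks, max_gap = 8L, diffusion = FALSE) {
  one <- function(d) {
    abort_if(nrow(d) < 2, "trajectory needs at least 2 localizations")
    abort_if(any(duplicated(d$t_s)), "duplicate timestamps in trajectory")
    d <- dplyr::arrange(d, .data$t_s)
    p <- cbind(d$x_um, d$y_um)
    d_net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    d_max <- max_pairwise_dist(p)
    total_t <- d$t_s[nrow(d)] - d$t_s[1]
    s_net <- d_net / total_t
    step <- sqrt(rowSums(diff(p)^2))
    dt <- diff(d$t_s)
    dfr <- diff(d$frame)
    keep <- dfr <= max_gap
    s_mean <- if (any(keep)) mean(step[keep] / dt[keep]) else NA_real_
    r_lin <- if (isTRUE(s_mean > 0)) min(s_net / s_mean, 1) else 0
    tibble::tibble(n_locs = nrow(d), duration_s = total_t,
                   d_net_um = d_net, d_max_um = d_max,
                   s_net_um_s = s_net, s_mean_um_s = s_mean, r_lin = r_lin)
  }
  out <- dplyr::reframe(dplyr::group_by(tracks, .data$track_id), one(dplyr::pick(dplyr::everything())))
  if (diffusion) {
    out <- dplyr::left_join(out, estimate_diffusion(tracks), by = "track_id")
  }
  out
}

# maximum pairwise distance via the convex hull
max_pairwise_dist <- function(p) {
  if (nrow(p) == 2) return(sqrt(sum((p[2, ] - p[1, ])^2)))
  h <- unique(p[chull(p), , drop = FALSE])
  if (nrow(h) < 2) return(0)
  max(stats::dist(h))
}

#' Window-based instantaneous velocity
#'
#' At each localization, a sliding window of `window` localizations
#' centred there is fit to a linear model in time, separately for x and y;
#' the fitted slopes approximate the instantaneous velocity. Near track
#' ends the window truncates (minimum 4 points) and the number of
#' supporting points is recorded. Tracks shorter than 4 localizations
#' yield an empty profile.
#'
#' @param tracks Tracks tibble.
#' @param window Window size in localizations (odd; default 7).
#' @return Tibble: `track_id`, `frame`, `t_s`, `vx_um_s`, `vy_um_s`,
#'   `speed_um_s`, `support`.
#' @export
instantaneous_velocity <- function(tracks, window = 7L) {
  abort_if(window %% 2 == 0, "`window` must be odd")
  half <- window %/% 2
  one <- function(d) {
    n <- nrow(d)
    if (n < 4) {
      return(tibble::tibble(frame = integer(), t_s = numeric(),
                            vx_um_s = numeric(), vy_um_s = numeric(),
                            speed_um_s = numeric(), support = integer()))
    }
    d <- dplyr::arrange(d, .data$t_s)
    vx <- vy <- numeric(n)
    supp <- integer(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      # widen a truncated window on the available side up to 4 points
      while (hi - lo + 1L < 4L) {
        if (lo > 1L) lo <- lo - 1L else hi <- hi + 1L
      }
      idx <- lo:hi
      vx[i] <- ls_slope(d$t_s[idx], d$x_um[idx])
      vy[i] <- ls_slope(d$t_s[idx], d$y_um[idx])
      supp[i] <- length(idx)
    }
    tibble::tibble(frame = d$frame, t_s = d$t_s, vx_um_s = vx, vy_um_s = vy,
                   speed_um_s = sqrt(vx^2 + vy^2), support = supp)
  }
  dplyr::reframe(dplyr::group_by(tracks, .data$track_id),
                 one(dplyr::pick(dplyr::everything())))
}

#' Maximum-likelihood diffusion constant with localization error
#'
#' Per-axis increments `d_i = x_{i+1} - x_i` are modelled as independent
#' zero-mean Gaussians with variance
#' `2 D dt_i + sigma_i^2 + sigma_{i+1}^2`, where `sigma_i` is the
#' localization precision of point `i`; the likelihood is summed over both
#' axes and maximized over `D >= 0`. The confidence interval comes from
#' the profile likelihood. The default treats increments as independent
#' (the `-sigma^2` covariance between consecutive increments is ignored);
#' `method = "tridiagonal"` uses the full tridiagonal increment
#' covariance instead.
#'
#' @param tracks Tracks tibble; if a `precision_um` or
#'   `precision_x_um`/`precision_y_um` column is present it supplies the
#'   per-localization precisions.
#' @param precision_um Constant precision used when the data carry none.
#' @param method `"independent"` (default) or `"tridiagonal"`.
#' @param conf_level Confidence level of the profile-likelihood interval.
#' @return One row per track: `track_id`, `D_um2_s`, `D_conf_low`,
#'   `D_conf_high`, `n_increments`, `loglik`, `degenerate`.
#' @export
estimate_diffusion <- function(tracks, precision_um = 0,
                               method = c("independent", "tridiagonal"),
                               conf_level = 0.95) {
  method <- match.arg(method)
  dplyr::reframe(dplyr::group_by(tracks, .data$track_id),
                 fit_diffusion_one(dplyr::pick(dplyr::everything()),
                                   precision_um, method, conf_level))
}

#' Fit the diffusion model to a single trajectory
#'
#' Single-track engine behind [estimate_diffusion()]; returns a fit object
#' with [tidy()][generics::tidy] and [glance()][generics::glance]-style
#' accessors ([tidy.diffusion_fit()], [glance.diffusion_fit()]).
#'
#' @inheritParams estimate_diffusion
#' @param track A single-track tibble.
#' @return An object of class `diffusion_fit`.
#' @export
fit_diffusion <- function(track, precision_um = 0,
                          method = c("independent", "tridiagonal"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  res <- fit_diffusion_one(track, precision_um, method, conf_level)
  structure(c(as.list(res), list(method = method, conf_level = conf_level)),
            class = "diffusion_fit")
}

fit_diffusion_one <- function(d, precision_um, method, conf_level) {
  d <- dplyr::arrange(d, .data$t_s)
  n <- nrow(d)
  abort_if(n < 11, "diffusion estimation needs at least 10 increments")
  sig <- if ("precision_um" %in% names(d)) d$precision_um
  else if (all(c("precision_x_um", "precision_y_um") %in% names(d)))
    sqrt((d$precision_x_um^2 + d$precision_y_um^2) / 2)
  else rep(precision_um, n)
  dt <- diff(d$t_s)
  dx <- diff(d$x_um)
  dy <- diff(d$y_um)
  s2 <- sig[-n]^2 + sig[-1]^2
  nll <- if (method == "independent") {
    function(D) {
      v <- 2 * D * dt + s2
      0.5 * sum(log(2 * pi * v) + dx^2 / v) + 0.5 * sum(log(2 * pi * v) + dy^2 / v)
    }
  } else {
    function(D) {
      v <- 2 * D * dt + s2
      offd <- -sig[-c(1, n)]^2
      nll_tridiag(dx, v, offd) + nll_tridiag(dy, v, offd)
    }
  }
  msd <- mean((dx^2 + dy^2) / dt)
  d_hi <- max(msd, 1e-6) * 10
  if (all(abs(c(dx, dy)) < 1e-12) && all(s2 < 1e-18)) {
    return(tibble::tibble(D_um2_s = 0, D_conf_low = 0, D_conf_high = 0,
                          n_increments = n - 1L, loglik = NA_real_,
                          degenerate = TRUE))
  }
  opt <- optimize(nll, c(0, d_hi), tol = 1e-10)
  # refine near the boundary
  if (opt$minimum < d_hi * 1e-3) {
    opt2 <- optimize(nll, c(0, d_hi * 2e-3), tol = 1e-12)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  D_hat <- opt$minimum
  n0 <- nll(0)
  if (n0 <= opt$objective + 1e-12) {
    D_hat <- 0
    opt$objective <- n0
  }
  cut <- opt$objective + qchisq(conf_level, 1) / 2
  f <- function(D) nll(D) - cut
  lo <- if (D_hat == 0 || f(0) <= 0) 0 else
    uniroot(f, c(0, D_hat), tol = 1e-10)$root
  hi_bound <- d_hi
  while (f(hi_bound) < 0 && hi_bound < 1e6) hi_bound <- hi_bound * 4
  hi <- if (f(hi_bound) < 0) Inf else
    uniroot(f, c(max(D_hat, 1e-12), hi_bound), tol = 1e-10)$root
  tibble::tibble(D_um2_s = D_hat, D_conf_low = lo, D_conf_high = hi,
                 n_increments = n - 1L, loglik = -opt$objective,
                 degenerate = FALSE)
}

# Gaussian negative log-likelihood with tridiagonal covariance
# (diagonal v, off-diagonal offd), via the symmetric Thomas/LDL recursion
nll_tridiag <- function(x, v, offd) {
  m <- length(x)
  dvec <- numeric(m)
  z <- numeric(m)
  dvec[1] <- v[1]
  z[1] <- x[1]
  if (m > 1) {
    for (i in 2:m) {
      l <- offd[i - 1] / dvec[i - 1]
      dvec[i] <- v[i] - l * offd[i - 1]
      z[i] <- x[i] - l * z[i - 1]
    }
  }
  0.5 * sum(log(2 * pi * dvec) + z^2 / dvec)
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s [%.4g, %.4g] (%s)\n",
              x$D_um2_s, x$D_conf_low, x$D_conf_high, x$method))
  invisible(x)
}

#' Tidy a diffusion fit
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A one-row tibble with estimate and confidence bounds.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D_um2_s,
                 conf.low = x$D_conf_low, conf.high = x$D_conf_high)
}

#' Glance at a diffusion fit
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n_increments,
                 method = x$method, degenerate = x$degenerate)
}

#' Turn a fitted object into a tidy tibble
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model-level summary of a fitted object
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
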