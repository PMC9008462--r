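#' Detection configuration
#'
#' Parameters of the spot detection stage: the difference-of-Gaussians
#' (DoG) bandpass sigmas, the candidate threshold (in filter-response
#' units; `NULL` selects a robust automatic threshold of
#' `threshold_sigma` response MADs above the response median), the fitting
#' window, the PSF sigma of the integrated-Gaussian model, and the
#' intensity / fit-quality acceptance filters. The fit-quality statistic
#' is the Poisson deviance of the fitted window,
#' `2 (loglik_saturated - loglik_fit)`; when `max_fit_quality` is `NULL`
#' the ceiling is chosen per record at filter time,
#' `F (df + 6 sqrt(2 df))` with `df = n_px - 4` and `F` the EM
#' excess-noise factor of the data (see [filter_localizations()]).
#'
#' @param dog_sigma_small,dog_sigma_large DoG sigmas in pixels
#'   (small < large).
#' @param candidate_threshold Response threshold, or `NULL` for automatic.
#' @param threshold_sigma Multiplier for the automatic threshold.
#' @param fit_window Square fit window side in pixels (odd, >= 5).
#' @param psf_sigma_px PSF sigma of the fit model, pixels.
#' @param min_photons Minimum fitted photon count to accept.
#' @param max_fit_quality Maximum deviance to accept (`NULL` = default).
#' @param merge_radius_px Fitted spots closer than this are duplicates;
#'   the brighter one is kept.
#' @param max_iterations,tol_px Optimizer controls.
#' @return A `detection_config` object.
#' @export
detection_config <- function(dog_sigma_small = 1, dog_sigma_large = 2,
                             candidate_threshold = NULL, threshold_sigma = 5,
                             fit_window = 9L, psf_sigma_px = 1.3,
                             min_photons = 100, max_fit_quality = NULL,
                             merge_radius_px = 2, max_iterations = 50L,
                             tol_px = 1e-4) {
  abort_if(dog_sigma_small >= dog_sigma_large,
           "`dog_sigma_small` must be smaller than `dog_sigma_large`")
  abort_if(fit_window %% 2 == 0 || fit_window < 5, "`fit_window` must be odd and >= 5")
  structure(list(dog_sigma_small = dog_sigma_small, dog_sigma_large = dog_sigma_large,
                 candidate_threshold = candidate_threshold,
                 threshold_sigma = threshold_sigma,
                 fit_window = as.integer(fit_window), psf_sigma_px = psf_sigma_px,
                 min_photons = min_photons, max_fit_quality = max_fit_quality,
                 merge_radius_px = merge_radius_px,
                 max_iterations = as.integer(max_iterations), tol_px = tol_px),
            class = "detection_config")
}

#' Difference-of-Gaussians spot-enhancing filter
#'
#' Bandpass response `G(sigma_small) * I - G(sigma_large) * I`, with
#' mirror boundary handling. The response of a constant image is zero
#' everywhere and the filter is linear in its input.
#'
#' @param image Numeric matrix (photon units).
#' @param sigma_small,sigma_large Gaussian sigmas in pixels.
#' @return Response matrix of the same shape.
#' @export
dog_filter <- function(image, sigma_small = 1, sigma_large = 2) {
  abort_if(sigma_small >= sigma_large, "`sigma_small` must be < `sigma_large`")
  image <- as.matrix(image)
  .gauss_blur_cpp(image, sigma_small) - .gauss_blur_cpp(image, sigma_large)
}

#' Find candidate spots as local maxima of a filter response
#'
#' Strict local maxima over the 8-neighbourhood with response above the
#' threshold; ties on a plateau are broken toward the smallest (row, col).
#'
#' @param response Response matrix from [dog_filter()].
#' @param threshold Threshold in response units.
#' @return Tibble with `row`, `col` (1-based pixel indices) and `response`.
#' @export
find_candidates <- function(response, threshold) {
  out <- .local_maxima_cpp(as.matrix(response), threshold)
  tibble::as_tibble(out)
}

auto_threshold <- function(response, k) {
  # robust median + k * MAD; large responses are subsampled on a fixed
  # stride, which leaves the threshold unchanged to well under a MAD
  v <- as.numeric(response)
  if (length(v) > 20000) v <- v[seq(1, length(v), by = length(v) %/% 20000)]
  median(v) + k * mad(v)
}

#' Maximum-likelihood sub-pixel fit of candidate spots
#'
#' Fits an integrated symmetric Gaussian PSF plus constant background to
#' the photon counts in a window around each candidate, maximizing the
#' Poisson likelihood by Fisher scoring. Localization precision is the
#' Cramer-Rao lower bound from the Fisher information at the optimum;
#' `fit_quality` is the Poisson deviance of the fitted window.
#'
#' Continuous pixel coordinates follow the half-open convention: pixel
#' (1,1) spans `[0,1) x [0,1)`, so a spot at the centre of pixel (1,1) has
#' `x_px = y_px = 0.5`.
#'
#' @param image Photon-unit matrix.
#' @param candidates Tibble with `row`, `col` (as from [find_candidates()]).
#' @param config A [detection_config()].
#' @return Tibble of localizations in pixel units: `x_px`, `y_px`,
#'   `photons`, `background`, `precision_x_px`, `precision_y_px`,
#'   `fit_quality`, `n_px`, `converged`.
#' @export
fit_spot_mle <- function(image, candidates, config = detection_config()) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(x_px = numeric(), y_px = numeric(), photons = numeric(),
                          background = numeric(), precision_x_px = numeric(),
                          precision_y_px = numeric(), fit_quality = numeric(),
                          n_px = integer(), converged = logical()))
  }
  fit <- .fit_spots_cpp(as.matrix(image), as.integer(candidates$row),
                        as.integer(candidates$col), config$fit_window,
                        config$psf_sigma_px, config$max_iterations, config$tol_px)
  tibble::tibble(x_px = fit$x_px, y_px = fit$y_px, photons = fit$photons,
                 background = fit$background,
                 precision_x_px = fit$crlb_x_px, precision_y_px = fit$crlb_y_px,
                 fit_quality = fit$fit_quality, n_px = fit$n_px,
                 converged = fit$converged)
}

#' Filter localizations on intensity and fit quality
#'
#' Accepts records with `photons >= min_photons`,
#' `fit_quality <= max_fit_quality` and a converged fit; each rejected
#' record carries its reason. When `max_fit_quality` is unset, the
#' per-record default is `F (df + 6 sqrt(2 df))` with
#' `df = n_px - 4` and `F` the EM excess-noise factor — with EM
#' amplification the gain-calibrated counts are over-dispersed relative
#' to Poisson by the factor `F`, which inflates the deviance accordingly.
#'
#' @param locs Localization tibble from [fit_spot_mle()].
#' @param config A [detection_config()].
#' @param em_excess Excess-noise factor of the data (1 for pure Poisson).
#' @return The tibble with `accepted` and `reject_reason` columns.
#' @export
filter_localizations <- function(locs, config = detection_config(), em_excess = 1) {
  df <- locs$n_px - 4
  max_q <- config$max_fit_quality %||% (em_excess * (df + 6 * sqrt(2 * df)))
  reason <- rep(NA_character_, nrow(locs))
  reason[!locs$converged] <- "not_converged"
  reason[locs$converged & locs$fit_quality > max_q] <- "poor_fit"
  reason[locs$converged & locs$fit_quality <= max_q &
           locs$photons < config$min_photons] <- "below_min_photons"
  dplyr::mutate(locs, accepted = is.na(reason), reject_reason = reason)
}

# drop duplicate fits within merge_radius_px, keeping the brighter record
merge_duplicates <- function(locs, radius_px) {
  if (nrow(locs) < 2) return(locs)
  ord <- order(-locs$photons)
  keep <- logical(nrow(locs))
  kx <- ky <- numeric(0)
  for (i in ord) {
    if (length(kx) == 0 ||
        min((kx - locs$x_px[i])^2 + (ky - locs$y_px[i])^2) >= radius_px^2) {
      keep[i] <- TRUE
      kx <- c(kx, locs$x_px[i]); ky <- c(ky, locs$y_px[i])
    }
  }
  locs[keep, ][order(locs$x_px[keep]), ]
}

#' Detect and localize spots in every frame of a movie
#'
#' Runs the DoG filter, candidate finding, maximum-likelihood fitting and
#' acceptance filtering frame by frame. The movie must be in photon units
#' (see [gain_calibrate()]).
#'
#' @param movie A `qd_movie` with `units = "photons"`.
#' @param config A [detection_config()].
#' @return Localization tibble with `frame`, `t_s`, pixel and micrometre
#'   coordinates, `photons`, `background`, per-axis precisions (um),
#'   `fit_quality`, `accepted` and `reject_reason`.
#' @export
detect_spots <- function(movie, config = detection_config()) {
  abort_if(!inherits(movie, "qd_movie"), "`movie` must be a qd_movie")
  abort_if(!identical(movie$units, "photons"),
           "movie must be gain-calibrated to photon units first")
  px <- movie$camera$pixel_size_um
  dt <- movie$camera$frame_interval_s
  em <- movie$camera$em_excess
  d <- dim(movie$frames)
  if (is.null(config$candidate_threshold)) {
    # one movie-level threshold from the response statistics of a spread
    # of frames (the background is temporally stationary)
    sel <- unique(round(seq(1, d[3], length.out = min(16, d[3]))))
    config$candidate_threshold <- median(vapply(sel, function(f) {
      img <- matrix(movie$frames[, , f], d[1], d[2])
      resp <- .gauss_blur_cpp(img, config$dog_sigma_small) -
        .gauss_blur_cpp(img, config$dog_sigma_large)
      auto_threshold(resp, config$threshold_sigma)
    }, 0))
  }
  raw <- .detect_movie_cpp(as.numeric(movie$frames), d[1], d[2], d[3],
                           config$dog_sigma_small, config$dog_sigma_large,
                           config$candidate_threshold, config$fit_window,
                           config$psf_sigma_px, config$max_iterations,
                           config$tol_px)
  raw$converged <- raw$converged == 1L
  # per-frame duplicate merge (brighter record wins), then acceptance filter
  keep <- logical(nrow(raw))
  for (idx in split(seq_len(nrow(raw)), raw$frame)) {
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    ord <- idx[order(-raw$photons[idx])]
    kx <- ky <- numeric(0)
    for (i in ord) {
      if (length(kx) == 0 ||
          min((kx - raw$x_px[i])^2 + (ky - raw$y_px[i])^2) >= config$merge_radius_px^2) {
        keep[i] <- TRUE
        kx <- c(kx, raw$x_px[i]); ky <- c(ky, raw$y_px[i])
      }
    }
  }
  out <- tibble::as_tibble(raw[keep, , drop = FALSE])
  out <- filter_localizations(out, config, em)
  if (nrow(out) == 0) {
    return(tibble::tibble(frame = integer(), t_s = numeric(), x_px = numeric(),
                          y_px = numeric(), x_um = numeric(), y_um = numeric(),
                          photons = numeric(), background = numeric(),
                          precision_x_um = numeric(), precision_y_um = numeric(),
                          fit_quality = numeric(), accepted = logical(),
                          reject_reason = character()))
  }
  dplyr::transmute(out, frame = .data$frame, t_s = (.data$frame - 1) * dt,
                   x_px = .data$x_px, y_px = .data$y_px,
                   x_um = .data$x_px * px, y_um = .data$y_px * px,
                   photons = .data$photons, background = .data$background,
                   precision_x_um = .data$precision_x_px * px,
                   precision_y_um = .data$precision_y_px * px,
                   fit_quality = .data$fit_quality, accepted = .data$accepted,
                   reject_reason = .data$reject_reason)
}

#' Count discrete spots in a fixed-cell z-stack
#'
#' Maximum-intensity projection over z, DoG bandpass, local-maxima
#' candidate detection and maximum-likelihood localization, with
#' intensity/fit filtering and duplicate merging. Warns if the projection
#' saturates the 16-bit range.
#'
#' @param stack A `qd_movie` whose frames are z slices (ADU or photons).
#' @param config A [detection_config()].
#' @param calib Optional [calibration_result()]; if the stack is in ADU and
#'   no calibration is given, the camera metadata of the stack is used.
#' @return Tibble of accepted spot positions (`x_um`, `y_um`, `photons`);
#'   the spot count is `nrow()` of the result.
#' @export
count_fixed_stack <- function(stack, config = detection_config(), calib = NULL) {
  abort_if(!inherits(stack, "qd_movie"), "`stack` must be a qd_movie")
  proj <- apply(stack$frames, c(1, 2), max)
  if (identical(stack$units, "ADU")) {
    if (max(proj) >= 65535) warning("saturated projection; counts may be unreliable")
    calib <- calib %||% calibration_result(stack$camera$gain, stack$camera$offset,
                                           stack$camera$read_noise,
                                           stack$camera$em_excess)
    proj <- pmax((proj - calib$offset) * calib$gain, 0)
  }
  resp <- dog_filter(proj, config$dog_sigma_small, config$dog_sigma_large)
  thr <- config$candidate_threshold %||% auto_threshold(resp, config$threshold_sigma)
  cand <- find_candidates(resp, thr)
  locs <- fit_spot_mle(proj, cand, config)
  locs <- merge_duplicates(locs, config$merge_radius_px)
  # local intensity threshold: counting keeps every converged fit bright
  # enough to be a discrete emitter (no deviance filter on a projection,
  # whose noise is no longer Poisson)
  locs <- dplyr::filter(locs, .data$converged, .data$photons >= config$min_photons)
  px <- stack$camera$pixel_size_um
  dplyr::transmute(locs, x_um = .data$x_px * px, y_um = .data$y_px * px,
                   photons = .data$photons)
}
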