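#' Calibration result
#'
#' Holds the global EMCCD conversion parameters (gain in photons/ADU,
#' offset in ADU, read noise in ADU RMS) and, optionally, a per-pixel
#' flat-field reference normalized to mean 1.
#'
#' @param gain Photons per ADU (may be `NA` when only a dark stack was
#'   available).
#' @param offset Camera offset, ADU.
#' @param read_noise Read noise, ADU RMS.
#' @param em_excess Excess-noise factor assumed when converting the
#'   mean-variance slope to gain.
#' @param reference Optional strictly positive matrix, normalized to mean 1.
#' @return A `calibration_result` object.
#' @export
calibration_result <- function(gain, offset, read_noise, em_excess = 2,
                               reference = NULL) {
  abort_if(!is.na(gain) && gain <= 0, "`gain` must be > 0 (or NA if unavailable)")
  if (!is.null(reference)) {
    abort_if(any(reference <= 0), "flat-field reference must be strictly positive")
    reference <- reference / mean(reference)
  }
  structure(list(gain = gain, offset = offset, read_noise = read_noise,
                 em_excess = em_excess, reference = reference),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> gain %.4f photons/ADU, offset %.2f ADU, read noise %.3f ADU\n",
              x$gain, x$offset, x$read_noise))
  invisible(x)
}

#' Estimate gain, offset and read noise from static calibration stacks
#'
#' Mean-variance (photon-transfer) calibration: the stack with the lowest
#' mean is taken as the dark stack, giving the offset (its mean) and read
#' noise (its per-pixel temporal SD, averaged); the gain follows from the
#' slope of per-pixel temporal variance against mean across illumination
#' levels. With EM excess noise the raw slope equals
#' `em_excess / gain`, so the excess-noise factor is folded into the
#' returned gain (set `assume_em_excess = 1` for a conventional CCD).
#'
#' @param stacks A list of 3D arrays (rows x cols x frames), each a
#'   temporally static illumination level; must include a dark stack.
#' @param assume_em_excess Excess-noise variance factor folded into the
#'   slope (default 2).
#' @return A [calibration_result()]. If only the dark stack is supplied the
#'   gain is `NA` and flagged unavailable.
#' @examples
#' \donttest{
#' cam <- camera_model()
#' set.seed(1)
#' mk <- function(level) render_movie(
#'   tibble::tibble(track_id = 1L, frame = 1L, t_s = 0, x_um = -10, y_um = -10,
#'                  visible = TRUE),
#'   cam, bg_photons = level, roi = c(32, 32), n_frames = 200)$frames
#' cal <- estimate_gain_offset(list(mk(0), mk(20), mk(60), mk(120)))
#' }
#' @export
estimate_gain_offset <- function(stacks, assume_em_excess = 2) {
  abort_if(!is.list(stacks) || length(stacks) < 1, "`stacks` must be a non-empty list")
  means <- vapply(stacks, mean, 0)
  abort_if(all(vapply(stacks, function(s) var(as.numeric(s)) == 0, TRUE)),
           "degenerate calibration stacks (zero variance)")
  dark <- stacks[[which.min(means)]]
  offset <- mean(dark)
  # per-pixel temporal SD of the dark stack
  dark_v <- apply(dark, c(1, 2), var)
  read_noise <- sqrt(mean(dark_v))
  lit <- stacks[means > min(means) + 1e-12]
  if (length(lit) < 1) {
    return(calibration_result(NA_real_, offset, read_noise, assume_em_excess))
  }
  pts <- purrr::map_dfr(c(list(dark), lit), function(s) {
    m <- apply(s, c(1, 2), mean)
    v <- apply(s, c(1, 2), var)
    tibble::tibble(mean = as.numeric(m), var = as.numeric(v))
  })
  slope <- coef(lm(var ~ mean, data = pts))[["mean"]]
  abort_if(!is.finite(slope) || slope <= 0, "mean-variance slope not positive; cannot fit gain")
  calibration_result(gain = assume_em_excess / slope, offset = offset,
                     read_noise = read_noise, em_excess = assume_em_excess)
}

#' Convert a movie from ADU to photon units
#'
#' Applies `photons = (ADU - offset) * gain`, clipping negative values at
#' zero (the downstream Poisson-likelihood fit requires non-negative
#' data). The operation is affine and order-preserving; applying it to a
#' movie already in photon units is refused.
#'
#' @param movie A `qd_movie` in ADU units.
#' @param calib A [calibration_result()] with a finite gain.
#' @param clip Clip negative photon values at zero (default `TRUE`).
#' @return The movie with `units = "photons"`; frames become numeric.
#' @export
gain_calibrate <- function(movie, calib, clip = TRUE) {
  abort_if(!inherits(movie, "qd_movie"), "`movie` must be a qd_movie")
  abort_if(!identical(movie$units, "ADU"),
           "movie is already gain-calibrated (units are not ADU)")
  abort_if(!inherits(calib, "calibration_result") || is.na(calib$gain),
           "calibration with a finite gain is required")
  ph <- (movie$frames - calib$offset) * calib$gain
  if (clip) ph[ph < 0] <- 0
  out <- movie
  out$frames <- ph
  out$units <- "photons"
  out
}

#' Flat-field (shading) correction
#'
#' Divides an image by its reference image (same exposure and optics,
#' no sample), with the reference normalized to mean 1 first so that the
#' intensity scale of the corrected image is preserved.
#'
#' @param image Numeric matrix.
#' @param reference Numeric matrix of the same shape; must be strictly
#'   positive after subtracting `offset`.
#' @param offset Camera offset to subtract from the reference before
#'   normalization.
#' @return The corrected image.
#' @export
flat_field_correct <- function(image, reference, offset = 0) {
  abort_if(!all(dim(image) == dim(reference)), "image and reference shapes differ")
  ref <- reference - offset
  n_bad <- sum(ref <= 0)
  abort_if(n_bad > 0, sprintf("reference has %d non-positive pixel(s) after offset subtraction", n_bad))
  image / (ref / mean(ref))
}
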