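#' Render a synthetic movie from ground-truth tracks
#'
#' Emitters are rendered as integrated 2D Gaussians (error-function pixel
#' integration) on a constant photon background, then passed through the
#' EMCCD noise chain: Poisson shot noise, EM-register excess noise (a gamma
#' stage multiplying the shot-noise variance by `camera$em_excess`),
#' conversion to ADU, offset, and Gaussian read noise. The mean ADU of an
#' emitter-free region equals the camera offset.
#'
#' @param tracks Ground-truth tracks tibble; only rows with
#'   `visible == TRUE` emit.
#' @param camera A [camera_model()].
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param photons_per_frame Photons emitted per visible emitter per frame.
#' @param bg_photons Background photons per pixel per frame.
#' @param roi Optional `c(rows, cols)` overriding `camera$roi`.
#' @param n_frames Number of frames (defaults to the maximum track frame).
#' @return A `qd_movie` object: integer ADU frames (rows x cols x frames),
#'   the camera, `units = "ADU"`, and the truth table in `$truth`.
#' @export
render_movie <- function(tracks, camera = camera_model(), psf_sigma_px = 1.3,
                         photons_per_frame = 400, bg_photons = 5,
                         roi = NULL, n_frames = NULL) {
  abort_if(photons_per_frame <= 0, "`photons_per_frame` must be > 0")
  abort_if(bg_photons < 0, "`bg_photons` must be >= 0")
  roi <- as.integer(roi %||% camera$roi)
  n_frames <- as.integer(n_frames %||% max(tracks$frame))
  em <- dplyr::filter(tracks, .data$visible, .data$frame <= n_frames)
  x_px <- em$x_um / camera$pixel_size_um
  y_px <- em$y_um / camera$pixel_size_um
  frames <- .render_movie_cpp(roi[1], roi[2], n_frames,
                              as.integer(em$frame), x_px, y_px,
                              rep(photons_per_frame, nrow(em)),
                              psf_sigma_px, bg_photons,
                              camera$gain, camera$offset, camera$read_noise,
                              camera$em_excess)
  new_qd_movie(frames, camera, units = "ADU", psf_sigma_px = psf_sigma_px,
               truth = tracks)
}

new_qd_movie <- function(frames, camera, units, psf_sigma_px = NA_real_,
                         truth = NULL) {
  structure(list(frames = frames, camera = camera, units = units,
                 psf_sigma_px = psf_sigma_px, truth = truth),
            class = "qd_movie")
}

#' @export
print.qd_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<qd_movie> %d x %d px, %d frame(s), units: %s\n",
              d[1], d[2], d[3], x$units))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `qd_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame of a movie as a matrix
#' @param movie A `qd_movie`.
#' @param i Frame index.
#' @return A numeric matrix.
#' @export
movie_frame <- function(movie, i) {
  d <- dim(movie$frames)
  abort_if(i < 1 || i > d[3], "frame index out of range")
  matrix(movie$frames[, , i], d[1], d[2])
}

#' Render a synthetic fixed-cell z-stack field
#'
#' Places `n_spots` point emitters uniformly in a field with a minimum
#' in-plane separation, with axial positions spread over the stack depth.
#' Each spot contributes an integrated-Gaussian image to the slices near
#' its axial position (Gaussian axial envelope of SD `sigma_z_um`), so a
#' spot appears in a contiguous subset of slices. Slices pass through the
#' same EMCCD noise chain as [render_movie()].
#'
#' @param n_spots Number of spots (may be 0).
#' @param camera A [fixed_camera_model()] (195 nm pixels, 250 nm z-step).
#' @param field_px `c(rows, cols)` field size in pixels.
#' @param n_slices Number of z slices (default 20, i.e. 5 um).
#' @param psf_sigma_px In-plane PSF sigma, pixels.
#' @param photons_in_focus Photons per slice at best focus.
#' @param bg_photons Background photons per pixel per slice.
#' @param sigma_z_um Axial envelope SD in micrometres.
#' @param min_sep_um Minimum in-plane separation between spots; an error is
#'   raised if the requested density cannot satisfy it.
#' @return A list: `stack` (a `qd_movie` whose frames are z slices),
#'   `truth` (tibble of true positions) and `n_spots`.
#' @export
render_fixed_field <- function(n_spots, camera = fixed_camera_model(),
                               field_px = c(512L, 512L), n_slices = 20L,
                               psf_sigma_px = 1.3, photons_in_focus = 400,
                               bg_photons = 5, sigma_z_um = 0.6,
                               min_sep_um = 1) {
  abort_if(n_spots < 0, "`n_spots` must be >= 0")
  abort_if(photons_in_focus <= 0, "`photons_in_focus` must be > 0")
  px <- camera$pixel_size_um
  margin_um <- 10 * psf_sigma_px * px
  lim_x <- c(margin_um, (field_px[2]) * px - margin_um)
  lim_y <- c(margin_um, (field_px[1]) * px - margin_um)
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_spots) {
    cand_x <- runif(1, lim_x[1], lim_x[2])
    cand_y <- runif(1, lim_y[1], lim_y[2])
    if (length(xs) == 0 || min((xs - cand_x)^2 + (ys - cand_y)^2) >= min_sep_um^2) {
      xs <- c(xs, cand_x); ys <- c(ys, cand_y)
    }
    tries <- tries + 1L
    abort_if(tries > 2000L * max(n_spots, 1L),
             "spot density too high for the requested minimum separation")
  }
  z_range <- (n_slices - 1L) * camera$z_step_um
  zs <- runif(max(n_spots, 0), 0, z_range)
  truth <- tibble::tibble(spot_id = seq_len(n_spots), x_um = xs, y_um = ys, z_um = zs)
  z_slice <- (seq_len(n_slices) - 1L) * camera$z_step_um
  em <- tidyr::expand_grid(spot_id = truth$spot_id, slice = seq_len(n_slices))
  if (nrow(em) > 0) {
    em <- dplyr::left_join(em, truth, by = "spot_id")
    em$photons <- photons_in_focus *
      exp(-0.5 * ((z_slice[em$slice] - em$z_um) / sigma_z_um)^2)
    em <- dplyr::filter(em, .data$photons >= 1)
  } else {
    em <- tibble::tibble(spot_id = integer(), slice = integer(),
                         x_um = numeric(), y_um = numeric(), photons = numeric())
  }
  frames <- .render_movie_cpp(field_px[1], field_px[2], n_slices,
                              as.integer(em$slice),
                              em$x_um / px, em$y_um / px, em$photons,
                              psf_sigma_px, bg_photons,
                              camera$gain, camera$offset, camera$read_noise,
                              camera$em_excess)
  list(stack = new_qd_movie(frames, camera, units = "ADU",
                            psf_sigma_px = psf_sigma_px, truth = truth),
       truth = truth, n_spots = n_spots)
}
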