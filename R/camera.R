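#' EMCCD camera model
#'
#' Describes the acquisition geometry and noise statistics of the EMCCD
#' detector: pixel size, frame interval, photon/ADU gain, offset, Gaussian
#' read noise, and the excess-noise factor of the electron-multiplying
#' register (applied as a variance multiplier on the shot noise).
#'
#' Defaults follow the live-imaging configuration used throughout the
#' package: 127 nm pixels, 17 frames/s, 512 x 512 region of interest,
#' gain 0.13 photons/ADU, offset 100 ADU, read noise 0.65 ADU RMS and an
#' EM excess-noise factor of 2.
#'
#' @param pixel_size_um Pixel size in micrometres.
#' @param frame_interval_s Time between frames in seconds.
#' @param gain Conversion gain in photons per ADU.
#' @param offset Camera offset in ADU.
#' @param read_noise Read noise in ADU RMS.
#' @param em_excess Excess-noise variance factor of the EM register
#'   (1 disables the EM stage; 2 is standard EMCCD physics).
#' @param roi Integer vector `c(rows, cols)` of the region of interest.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' cam$frame_interval_s
#' @export
camera_model <- function(pixel_size_um = 0.127, frame_interval_s = 1 / 17,
                         gain = 0.13, offset = 100, read_noise = 0.65,
                         em_excess = 2, roi = c(512L, 512L)) {
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_interval_s, "frame_interval_s")
  check_positive(gain, "gain")
  abort_if(!is_scalar_num(offset) || offset < 0, "`offset` must be >= 0")
  abort_if(!is_scalar_num(read_noise) || read_noise < 0, "`read_noise` must be >= 0")
  abort_if(!is_scalar_num(em_excess) || em_excess < 1, "`em_excess` must be >= 1")
  abort_if(length(roi) != 2L || any(roi < 1), "`roi` must be c(rows, cols)")
  structure(list(pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
                 gain = gain, offset = offset, read_noise = read_noise,
                 em_excess = em_excess, roi = as.integer(roi)),
            class = "camera_model")
}

#' Camera model for fixed-cell z-stack imaging
#'
#' Same detector model as [camera_model()] but with the wider-field optics
#' used for fixed specimens: 195 nm pixels and a 250 nm z-step.
#'
#' @param ... Overrides passed to [camera_model()].
#' @param z_step_um Axial step between slices in micrometres.
#' @return A `camera_model` with a `z_step_um` field.
#' @export
fixed_camera_model <- function(..., z_step_um = 0.25) {
  cam <- camera_model(pixel_size_um = 0.195, ...)
  cam$z_step_um <- z_step_um
  cam
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n")
  cat(sprintf("  pixel %.0f nm, frame interval %.1f ms, roi %d x %d\n",
              x$pixel_size_um * 1e3, x$frame_interval_s * 1e3, x$roi[1], x$roi[2]))
  cat(sprintf("  gain %.3f photons/ADU, offset %.1f ADU, read noise %.2f ADU, EM excess %.1f\n",
              x$gain, x$offset, x$read_noise, x$em_excess))
  invisible(x)
}

#' Two-state quantum-dot blinking model
#'
#' Per-frame Markov chain between an emitting ("on") and a dark ("off")
#' state. `p_off` is the probability per frame of entering the dark state,
#' `p_on` the probability per frame of recovering from it; dark dwells are
#' geometric with mean `1/p_on` frames.
#'
#' @param p_off,p_on Per-frame transition probabilities.
#' @return An object of class `blink_model`.
#' @export
blink_model <- function(p_off = 0.1, p_on = 0.5) {
  check_prob(p_off, "p_off")
  check_prob(p_on, "p_on")
  structure(list(p_off = p_off, p_on = p_on), class = "blink_model")
}

#' Microfluidic chamber geometry
#'
#' One-dimensional arc-length model of the compartmented culture: the
#' axonal compartment (where cargo is added, distance 0), the microchannel
#' (the distal axon region, 450 um long by default), the axonal stretch in
#' the cell-body compartment (the proximal region), and the soma beyond it.
#' Distances are measured along the axon from the point of cargo addition.
#'
#' @param axonal_len_um Extent of the axonal compartment before the channel.
#' @param channel_len_um Microchannel length (450 um by default).
#' @param proximal_len_um Axonal extent inside the cell-body compartment.
#' @param soma_len_um Extent attributed to the soma region.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(axonal_len_um = 100, channel_len_um = 450,
                             proximal_len_um = 500, soma_len_um = 100) {
  for (nm in c("axonal_len_um", "channel_len_um", "proximal_len_um", "soma_len_um"))
    check_positive(get(nm), nm)
  b <- cumsum(c(axonal_len_um, channel_len_um, proximal_len_um, soma_len_um))
  structure(list(axonal_len_um = axonal_len_um, channel_len_um = channel_len_um,
                 proximal_len_um = proximal_len_um, soma_len_um = soma_len_um,
                 breaks_um = c(0, b)),
            class = "chamber_geometry")
}

#' Axon path
#'
#' A polyline in micrometre coordinates along which simulated cargo moves.
#' Arc length increases in the direction of retrograde transport (toward
#' the soma). The default is a straight segment, which keeps trajectory
#' statistics analytically checkable.
#'
#' @param length_um Path length for the default straight segment.
#' @param origin_um Numeric `c(x, y)` start point.
#' @param direction Unit-normalized `c(dx, dy)` direction.
#' @param vertices Optional n x 2 matrix of vertices overriding the
#'   straight-segment construction.
#' @return Object of class `axon_path` with vertices and cumulative arc length.
#' @export
axon_path <- function(length_um = 200, origin_um = c(0, 0), direction = c(1, 0),
                      vertices = NULL) {
  if (is.null(vertices)) {
    check_positive(length_um, "length_um")
    d <- direction / sqrt(sum(direction^2))
    vertices <- rbind(origin_um, origin_um + d * length_um)
  }
  vertices <- as.matrix(vertices)
  abort_if(ncol(vertices) != 2 || nrow(vertices) < 2, "`vertices` must be an n x 2 matrix")
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  abort_if(any(seg_len == 0), "degenerate (zero-length) path segment")
  structure(list(vertices = vertices, seg_len = seg_len,
                 cum_len = c(0, cumsum(seg_len)), length_um = sum(seg_len)),
            class = "axon_path")
}

# positions (x, y) at arc lengths s (clamped to the path ends)
path_point <- function(path, s) {
  s <- pmin(pmax(s, 0), path$length_um)
  idx <- findInterval(s, path$cum_len, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(path$seg_len))
  frac <- (s - path$cum_len[idx]) / path$seg_len[idx]
  p0 <- path$vertices[idx, , drop = FALSE]
  p1 <- path$vertices[idx + 1L, , drop = FALSE]
  p0 + (p1 - p0) * frac
}

# arc-length of the orthogonal projection of points onto the path polyline;
# returns list(s, dist) with the perpendicular distance
path_project <- function(path, x, y) {
  n <- length(x)
  best_d2 <- rep(Inf, n)
  best_s <- rep(NA_real_, n)
  for (k in seq_along(path$seg_len)) {
    p0 <- path$vertices[k, ]
    v <- path$vertices[k + 1L, ] - p0
    L2 <- sum(v^2)
    t <- pmin(pmax(((x - p0[1]) * v[1] + (y - p0[2]) * v[2]) / L2, 0), 1)
    dx <- x - (p0[1] + t * v[1])
    dy <- y - (p0[2] + t * v[2])
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- path$cum_len[k] + t[upd] * path$seg_len[k]
  }
  list(s = best_s, dist = sqrt(best_d2))
}
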