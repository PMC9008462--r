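#' Write a movie as a 16-bit multi-frame TIFF with metadata sidecar
#'
#' Frames are stored as unsigned 16-bit TIFF pages; the camera metadata
#' (pixel size, frame interval, gain, offset, read noise, units) goes into
#' a plain key-value text sidecar `<path>.meta.txt`.
#'
#' @param movie A `qd_movie`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$frames)
  abort_if(max(movie$frames) > 65535 || min(movie$frames) < 0,
           "frames not representable as unsigned 16-bit")
  pages <- lapply(seq_len(d[3]), function(i) movie_frame(movie, i) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(pixel_size_um = movie$camera$pixel_size_um,
            frame_interval_s = movie$camera$frame_interval_s,
            gain = movie$camera$gain, offset = movie$camera$offset,
            read_noise = movie$camera$read_noise,
            em_excess = movie$camera$em_excess)
  writeLines(c(paste(names(meta), unname(meta), sep = "="),
               paste0("units=", movie$units)),
             paste0(path, ".meta.txt"))
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; the `<path>.meta.txt` sidecar is read if present.
#' @return A `qd_movie`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- as.integer(round(pages[[i]] * 65535))
  meta_path <- paste0(path, ".meta.txt")
  camera <- camera_model(roi = d[1:2])
  units <- "ADU"
  if (file.exists(meta_path)) {
    kv <- strsplit(readLines(meta_path), "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    units <- vals[["units"]] %||% "ADU"
    camera <- camera_model(pixel_size_um = as.numeric(vals[["pixel_size_um"]]),
                           frame_interval_s = as.numeric(vals[["frame_interval_s"]]),
                           gain = as.numeric(vals[["gain"]]),
                           offset = as.numeric(vals[["offset"]]),
                           read_noise = as.numeric(vals[["read_noise"]]),
                           em_excess = as.numeric(vals[["em_excess"]]),
                           roi = d[1:2])
  }
  new_qd_movie(frames, camera, units = units)
}

#' Serialize a calibration result to key-value text (plus reference TIFF)
#'
#' @param calib A `calibration_result`.
#' @param path Output text path; a strictly positive flat-field reference,
#'   if present, is written alongside as `<path>.reference.tif`.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  abort_if(!inherits(calib, "calibration_result"), "`calib` must be a calibration_result")
  writeLines(c(paste0("gain=", calib$gain), paste0("offset=", calib$offset),
               paste0("read_noise=", calib$read_noise),
               paste0("em_excess=", calib$em_excess)), path)
  if (!is.null(calib$reference)) {
    ref <- calib$reference / max(calib$reference)
    tiff::writeTIFF(ref, paste0(path, ".reference.tif"), bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a calibration result written by [write_calibration()]
#' @param path Text path.
#' @return A `calibration_result`.
#' @export
read_calibration <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  ref_path <- paste0(path, ".reference.tif")
  ref <- NULL
  if (file.exists(ref_path)) {
    ref <- tiff::readTIFF(ref_path)
    ref <- ref / mean(ref)
  }
  calibration_result(gain = as.numeric(vals[["gain"]]),
                     offset = as.numeric(vals[["offset"]]),
                     read_noise = as.numeric(vals[["read_noise"]]),
                     em_excess = as.numeric(vals[["em_excess"]]),
                     reference = ref)
}
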