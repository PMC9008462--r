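# internal helpers

# gamma draw matched by moments to (mean, sd); sd = 0 degenerates to the mean
rgamma_ms <- function(n, mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

# positive normal draw (resample until > floor); used for per-phase run speeds
rnorm_pos <- function(n, mean, sd, floor = 1e-3) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= floor)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= floor)
    tries <- tries + 1L
  }
  x[x <= floor] <- floor
  x
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, name) {
  abort_if(!is_scalar_num(x) || x <= 0, sprintf("`%s` must be a positive number", name))
  invisible(x)
}

check_prob <- function(x, name) {
  abort_if(!is_scalar_num(x) || x < 0 || x > 1, sprintf("`%s` must be in [0, 1]", name))
  invisible(x)
}

# apply fn per track (preserving first-appearance order and id type),
# prepending track_id to the result
by_track <- function(data, fn) {
  ids <- unique(data$track_id)
  purrr::map_dfr(ids, function(id) {
    res <- fn(data[data$track_id == id, , drop = FALSE])
    if (nrow(res) == 0) return(res)
    dplyr::mutate(res, track_id = id, .before = 1)
  })
}

# least-squares slope of y on t (uneven spacing allowed)
ls_slope <- function(t, y) {
  tb <- mean(t)
  st <- sum((t - tb)^2)
  if (st == 0) return(NA_real_)
  sum((t - tb) * (y - mean(y))) / st
}
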