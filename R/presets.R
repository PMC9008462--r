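#' Motion parameters for synthetic cargo trajectories
#'
#' Kinetic parameters for one simulated particle. For active transport
#' ("AT") the trajectory alternates motor-driven runs and pauses; run
#' speeds are constant within a phase and drawn per phase, phase durations
#' are gamma distributed matched by moments to (mean, sd). "B&F" is
#' confined one-dimensional diffusion inside a short axonal domain, "S" is
#' stationary jiggle, and "AT_pair" is a tethered pair of active-transport
#' particles.
#'
#' @param motion_class One of `"AT"`, `"B&F"`, `"S"`, `"AT_pair"`.
#' @param active_speed_mean,active_speed_sd Run speed distribution (um/s).
#' @param active_dur_mean,active_dur_sd Active-phase duration (s).
#' @param pause_dur_mean,pause_dur_sd Paused-phase duration (s); a zero
#'   mean disables pausing.
#' @param pause_jitter_sd Positional jitter while paused (um, per axis).
#' @param confinement_length_um Domain length for B&F motion (3-7 um).
#' @param bf_diffusion_um2_s Diffusion constant of B&F motion.
#' @param pair_coupling_rest_um,pair_coupling_sd_um Rest length and
#'   fluctuation SD of the tether for coordinated pairs; the implied
#'   inter-particle distance must stay below 2 um.
#' @return An object of class `motion_params`.
#' @seealso [motion_preset()] for the named presets used in this package.
#' @export
motion_params <- function(motion_class = c("AT", "B&F", "S", "AT_pair"),
                          active_speed_mean = 1.5, active_speed_sd = 0.45,
                          active_dur_mean = 7, active_dur_sd = 6.5,
                          pause_dur_mean = 5, pause_dur_sd = 9,
                          pause_jitter_sd = 0.05,
                          confinement_length_um = 5, bf_diffusion_um2_s = 0.05,
                          pair_coupling_rest_um = 0.5, pair_coupling_sd_um = 0.2) {
  motion_class <- match.arg(motion_class)
  if (motion_class %in% c("AT", "AT_pair")) {
    check_positive(active_speed_mean, "active_speed_mean")
    check_positive(active_dur_mean, "active_dur_mean")
    abort_if(pause_dur_mean < 0, "`pause_dur_mean` must be >= 0")
  }
  abort_if(active_speed_sd < 0 || active_dur_sd < 0 || pause_dur_sd < 0,
           "duration and speed SDs must be >= 0")
  abort_if(pause_jitter_sd < 0, "`pause_jitter_sd` must be >= 0")
  abort_if(confinement_length_um <= 0, "`confinement_length_um` must be > 0")
  abort_if(bf_diffusion_um2_s <= 0, "`bf_diffusion_um2_s` must be > 0")
  if (motion_class == "AT_pair") {
    reach <- pair_coupling_rest_um + 4 * pair_coupling_sd_um
    abort_if(reach >= 2 || pair_coupling_rest_um <= 0,
             "pair coupling implies inter-distance >= 2 um (rest + 4 sd must be < 2)")
  }
  structure(list(motion_class = motion_class,
                 active_speed_mean = active_speed_mean, active_speed_sd = active_speed_sd,
                 active_dur_mean = active_dur_mean, active_dur_sd = active_dur_sd,
                 pause_dur_mean = pause_dur_mean, pause_dur_sd = pause_dur_sd,
                 pause_jitter_sd = pause_jitter_sd,
                 confinement_length_um = confinement_length_um,
                 bf_diffusion_um2_s = bf_diffusion_um2_s,
                 pair_coupling_rest_um = pair_coupling_rest_um,
                 pair_coupling_sd_um = pair_coupling_sd_um),
            class = "motion_params")
}

#' Named motion presets
#'
#' Kinetic presets for the study conditions this package emulates.
#' `"distal"`, `"proximal"` and `"soma"` carry the region-stratified
#' active-transport kinetics (active run speed, active and paused phase
#' durations, mean +/- SD): distal axon 1.531 +/- 0.486 um/s,
#' 7.218 +/- 6.346 s active, 5.288 +/- 9.420 s paused; proximal axon
#' 1.544 +/- 0.446 um/s, 6.721 +/- 6.634 s, 1.931 +/- 1.842 s; soma
#' 1.1 +/- 0.55 um/s, 1.955 +/- 1.945 s active, 4.953 +/- 3.777 s paused.
#' `"bf"` is confined back-and-forth diffusion in a 5 um domain, `"s"` a
#' stationary particle, `"pair"` a coordinated pair with proximal
#' kinetics, and `"ehna"` a dynein-inhibited condition in which active
#' transport is disabled and the particle only exhibits paused jiggle.
#'
#' @param preset Preset name.
#' @return A `motion_params` object.
#' @examples
#' motion_preset("distal")$active_speed_mean
#' @export
motion_preset <- function(preset = c("distal", "proximal", "soma", "bf", "s",
                                     "pair", "ehna")) {
  preset <- match.arg(preset)
  switch(preset,
    distal = motion_params("AT",
      active_speed_mean = 1.531, active_speed_sd = 0.486,
      active_dur_mean = 7.218, active_dur_sd = 6.346,
      pause_dur_mean = 5.288, pause_dur_sd = 9.420),
    proximal = motion_params("AT",
      active_speed_mean = 1.544, active_speed_sd = 0.446,
      active_dur_mean = 6.721, active_dur_sd = 6.634,
      pause_dur_mean = 1.931, pause_dur_sd = 1.842),
    soma = motion_params("AT",
      active_speed_mean = 1.1, active_speed_sd = 0.55,
      active_dur_mean = 1.955, active_dur_sd = 1.945,
      pause_dur_mean = 4.953, pause_dur_sd = 3.777),
    bf = motion_params("B&F"),
    s = motion_params("S"),
    pair = motion_params("AT_pair",
      active_speed_mean = 1.544, active_speed_sd = 0.446,
      active_dur_mean = 6.721, active_dur_sd = 6.634,
      pause_dur_mean = 1.931, pause_dur_sd = 1.842),
    ehna = motion_params("AT",
      active_speed_mean = 1.5, active_speed_sd = 0.45,
      active_dur_mean = 1e-6, active_dur_sd = 0,
      pause_dur_mean = 600, pause_dur_sd = 0)
  )
}
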