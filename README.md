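# axodyn

Single-particle tracking analysis of quantum-dot (QD) labelled neurotrophin
cargo moving along sensory axons. Neurons grown in compartmented microfluidic
chambers take up QD-labelled BDNF at their distal axon tips and carry it in
signaling endosomes toward the cell body; `axodyn` turns the resulting EMCCD
movies — or fully synthetic, ground-truthed equivalents — into calibrated,
region-stratified transport kinetics.

The pipeline:

1. **Calibration** — EMCCD gain/offset/read-noise from static calibration
   stacks (mean–variance method with the EM excess-noise factor folded in),
   ADU→photon conversion, flat-field correction.
2. **Detection** — difference-of-Gaussians spot enhancement, local-maxima
   candidates, maximum-likelihood fits of an integrated Gaussian PSF under
   Poisson noise (sub-pixel positions, photon counts, CRLB precisions,
   deviance-based fit quality), intensity/quality filtering; discrete-QD
   counting in fixed-cell z-stacks.
3. **Linking** — blinking-aware cost-matrix assignment (birth/death costs
   from the blink model, exact Jonker–Volgenant solver) plus gap closing
   across dark dwells.
4. **Trajectory metrics** — net and maximum displacement, net speed
   `s_net = ||p_N − p_1|| / (t_N − t_1)`, mean curvilinear speed `s̄`,
   linearity of forward progression `r_lin = s_net / s̄`, window-7
   instantaneous velocity, and a maximum-likelihood diffusion constant with
   per-localization precision (`Var[Δx_i] = 2 D Δt_i + σ_i² + σ_{i+1}²`).
5. **Segmentation** — motion taxonomy (stationary / back-and-forth / active
   transport) and hysteresis segmentation of active transport into
   alternating active and paused phases with per-phase kinetics.
6. **Regional analysis** — distal (microchannel) vs proximal (cell-body
   compartment) vs soma summaries, 200 µm spatial histograms, coordinated
   pair detection (< 2 µm criterion), and group-comparison reporting.

A first-class synthetic-data module (`motion_preset()`,
`simulate_trajectory()`, `apply_blinking()`, `render_movie()`,
`render_fixed_field()`) emulates the study conditions — motor-driven runs
interrupted by pauses, confined 3–7 µm back-and-forth diffusion, stationary
jiggle, coordinated pairs, QD blinking, and the full EMCCD noise chain — so
every stage is testable without access to the original recordings.

## Worked example

Simulate one actively transported cargo for two minutes, image it, and
recover its kinetics:

```r
library(axodyn)
set.seed(11)

sim    <- simulate_movie("proximal", total_time_s = 120)   # rendered ADU movie + truth
cam    <- sim$movie$camera
photons <- gain_calibrate(sim$movie,
                          calibration_result(cam$gain, cam$offset,
                                             cam$read_noise, cam$em_excess))
locs   <- detect_spots(photons)
tracks <- link_movie(locs)
phases <- segment_phases(tracks)
phase_kinetics(phases)
```

```
#> # A tibble: 4 × 8
#>   label  scope        n mean_duration_s sem_duration_s mean_net_disp_um mean_net_speed_um_s
#> 1 active interior     8           13.1           5.30            20.5                 1.54
#> 2 paused interior     9            1.49          0.409            0.103               0.130
#> 3 active all         10           10.7           4.49            16.7                 1.53
#> 4 paused all          9            1.49          0.409            0.103               0.130
```

The generative proximal preset runs at 1.544 µm/s between pauses of mean
1.931 s; the recovered kinetics come back through the complete imaging chain
— rendering, shot/EM/read noise, detection, linking, segmentation. Averaged
over 30 such movies the pipeline recovers a mean interior pause duration of
2.10 s and a mean interior active-phase net speed of 1.43 µm/s; the methods
vignette explains the residual biases (sub-0.3 s pauses are below the
temporal resolution floor and merge into runs). Interior phases are those
bounded by opposite-label phases on both sides, i.e. with a known beginning
and end.

Trajectory-level statistics for a batch of simulated distal-axon cargoes:

```r
set.seed(1)
tracks <- purrr::map_dfr(1:53, function(i)
  add_localization_noise(
    simulate_trajectory(motion_preset("distal"), axon_path(450),
                        camera_model(), 120, track_id = i), 0.02))
mean(track_stats(tracks)$s_net_um_s)
#> [1] 0.9125
```

— the whole-trajectory net speed that alternating 1.531 µm/s runs and
5.3 s pauses produce (renewal closed form
`s_a · T_a / (T_a + T_p) ≈ 0.88` µm/s).

## Further reading

The methods vignette (`vignettes/axodyn-methods.Rmd`) documents the camera
and PSF models, the cost-matrix formulation, every default threshold and its
rationale, what the synthetic generator does and does not emulate, and the
known estimator biases, with pointers to the tests that quantify each claim.
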