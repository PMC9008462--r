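---
title: "Methods: single-particle tracking of quantum-dot labelled axonal cargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle tracking of quantum-dot labelled axonal cargo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axodyn)
```

## The problem

Neurotrophins such as BDNF signal from the tips of sensory axons back to the
cell body by riding in endosomes along microtubules. Labelling single BDNF
molecules with quantum dots (QDs) and growing dorsal root ganglion neurons in
compartmented microfluidic chambers makes this retrograde traffic observable
one cargo at a time, over hundreds of micrometres of axon. The measurement
chain, however, is long: EMCCD movies in camera units have to be calibrated to
photons, diffraction-limited spots detected and localized to tens of
nanometres, positions connected into trajectories across the stochastic dark
periods ("blinking") that single QDs exhibit, and the resulting tracks reduced
to kinetic quantities — run speeds, pause durations, diffusion constants —
stratified by where along the axon they were observed.

`axodyn` implements this chain end to end, together with a ground-truthed
synthetic-movie generator, so that every stage can be validated against data
whose answer is known.

## Camera model and calibration

Pixels record ADU counts `offset + electrons / gain` where `gain` is in
photons/ADU. Shot noise is Poisson; the electron-multiplying register
multiplies the shot-noise variance by an excess-noise factor `F` (default 2,
the standard EMCCD limit, implemented as a gamma stage so that the output
stays positive with mean preserved); Gaussian read noise is added in ADU. The
forward model in `render_movie()` and the calibration in
`estimate_gain_offset()` are exact inverses of one another: the mean–variance
(photon-transfer) slope equals `F / gain`, and the returned gain folds `F` in
(set `assume_em_excess = 1` for a conventional CCD). Whether a given
experimental gain figure already accounts for excess noise is often ambiguous,
which is why the factor is an explicit argument rather than a constant.

Defaults mirror the live-imaging configuration this package targets: 127 nm
pixels, 17 frames/s (2,000 frames in 120 s), 512 x 512 regions of interest,
gain 0.13 photons/ADU, read noise 0.65 ADU. The photon budget of the live
movies is not stated anywhere we could anchor to, so the simulator's defaults
— 400 photons per frame per QD on a background of 5 photons/pixel — are this
package's choice; they give ~15–25 nm localization precision, the regime in
which the downstream defaults were designed to operate. Fixed-cell z-stacks
use 195 nm pixels and a 250 nm z-step, and are flat-field corrected by
dividing by a reference image normalized to mean one (plain division would
rescale intensities with exposure; normalization preserves photon semantics).
Negative post-offset values are clipped to zero because the localization
likelihood is a Poisson model.

## Detection and localization

Candidate spots are the strict 8-neighbourhood local maxima of a
difference-of-Gaussians bandpass (sigmas 1 and 2 px by default — a matched
filter near the diffraction limit; mirror boundaries). The candidate threshold
is robust and automatic (median + 5 MAD of the response; computed once per
movie, since the background is temporally stationary) and can be pinned
numerically. Each candidate is fit in a 9 x 9 px window by maximizing the
Poisson likelihood of an integrated symmetric Gaussian (error-function pixel
integration) with free position, photon count and constant background, by
Fisher scoring with positivity clamps (50 iterations maximum, convergence at
1e-4 px). Localization precision is the Cramér–Rao bound from the Fisher
information at the optimum; on pure Poisson data the fitter's RMSE matches it
within a few percent at 200–2,000 photons (see the test suite).

Acceptance filtering keeps fits with at least `min_photons` (default 100) and
a Poisson deviance `2(loglik_sat - loglik_fit)` below a ceiling. Because EM
amplification over-disperses calibrated counts by the factor `F`, the default
ceiling is `F (df + 6 sqrt(2 df))` with `df = n_px - 4`; single-pixel
artefacts exceed it by orders of magnitude. Fits that leave their window are
rejected as artefacts, and fits closer than 2 px are merged keeping the
brighter record (a guard against double counting; duplicates at that scale
cannot be distinct QDs at these densities).

Discrete QDs in fixed cells are counted on the maximum-intensity projection
with the same bandpass/maxima/fit machinery but without the deviance filter
(projection noise is no longer Poisson); at the densities and photon budgets
the synthetic fields emulate, counting error is well below the 5 % the
application demands.

## Blinking-aware linking

Frame-to-frame association solves a linear assignment problem on the standard
augmented cost matrix: squared displacement for candidate links (forbidden
beyond 0.5 µm/frame), and diagonal birth/death blocks priced from the blink
model, `death = birth = -log(p_off + p_miss)` with `p_miss = 0.05` a detection
failure allowance. The exact formulation behind the cost-matrix idea is not
fully specified anywhere we could follow, so this augmentation is this
package's documented choice; the solver is an exact Jonker–Volgenant shortest
augmenting path implementation validated against brute-force enumeration. A
second pass closes gaps across dark periods: a track end may join a later
track start across up to `max_gap = 8` frames (≈ 0.5 s) within a radius that
grows as `sqrt(gap)` (diffusive part) plus a linear transport term
(2 µm/s). Dark dwells are geometric with mean `1/p_on` (defaults
`p_off = 0.1`, `p_on = 0.5` per frame — an on/off pattern typical of single
QDs at ~60 ms integration; the dwell tail beyond `max_gap`, about 0.4 % of
dwells, splits a track by design rather than risk bridging distinct
endosomes). Tracks shorter than 10 localizations are dropped: the window-7
velocity and the trajectory statistics need that much support, and this
automated filter replaces the manual trajectory curation such experiments
traditionally rely on.

In the tests, linking quality is scored as weighted purity (fraction of a
recovered track belonging to its majority particle) and association-level
completeness (fraction of consecutive detections of a particle kept in one
track). Completeness is defined on associations rather than largest fragments
because fragment scores are dominated by the legitimate long-dwell splits just
described, not by linking errors.

## Trajectory statistics

For a track `{p_i, t_i}`: net displacement `d_net = ||p_N - p_1||`, maximum
displacement `d_max = max ||p_i - p_j||` (computed on the convex hull), net
speed `s_net = d_net / (t_N - t_1)`, mean curvilinear speed `s_mean` (mean of
per-step speeds), and the linearity of forward progression
`r_lin = s_net / s_mean`, near 1 for directed and near 0 for random motion.
Steps spanning more than `max_gap` frames are excluded from `s_mean` so blink
gaps do not dilute the speed estimate (a documented deviation knob; all other
statistics use actual time differences). The instantaneous velocity at each
localization is the slope of a least-squares line through a window of seven
localizations centred there; near track ends the window truncates to no fewer
than four points and the support is recorded, so segmentation has coverage
everywhere.

The diffusion constant is a per-track maximum-likelihood estimate that
incorporates localization error: per-axis increments are zero-mean Gaussian
with variance `2 D dt_i + s_i^2 + s_{i+1}^2`. The default treats increments as
independent, ignoring the `-s^2` covariance between consecutive increments;
the bias of that approximation is below 5 % across `D` from 0.01 to 1 µm²/s at
the precisions this pipeline produces (quantified in the tests), and a full
tridiagonal-covariance option is available. Motion blur is not modelled
(exposure ≈ frame interval is noted as a caveat). Confidence intervals come
from the profile likelihood. The estimator is computed per trajectory and can
equally be applied to segments; both uses are labelled by the caller.

## Motion taxonomy and phase segmentation

Whole tracks are classified, in fixed order, as stationary (S: `d_max` <
0.5 µm), active transport (AT: `d_net` ≥ 5 µm), confined back-and-forth
(B&F: `d_max` 2–10 µm, `r_lin` < 0.2, and at least three velocity reversals
along the principal axis), or unclassified. No numeric thresholds for this
taxonomy exist in the source material; these are this package's documented,
configurable choices, validated against simulations of each class.

AT tracks are segmented into alternating active and paused phases by
two-threshold hysteresis on the window-7 speed: enter active above
`v_on = 0.5` µm/s, leave below `v_off = 0.3` µm/s. Phase boundaries are placed
midway between adjacent localizations so phases tile the track exactly; a
phase's net speed is its net displacement over its duration, the whole-track
`s_net` applied to the sub-trajectory. Phases shorter than
`min_phase_duration` are merged into their neighbours. Its default is 0.25 s —
the shortest phase supported by at least four localizations, the same floor
as the velocity window truncation. We initially carried a 0.5 s default, but
simulation showed it truncates the short tail of near-exponential pause-length
distributions hard enough to bias the recovered mean pause duration by ~+19 %,
violating the pipeline's own requirement of ≤ 10 % end-to-end bias; at 0.25 s
the bias is roughly halved. Remaining known biases, quantified by simulation
(30 rendered two-minute movies through the complete chain): pauses shorter
than roughly 0.3 s are unresolvable at 17 frames/s with window-7 smoothing
(they merge into the surrounding runs), truncating the near-exponential
pause-duration distribution, so the recovered mean interior pause duration
runs about 8–9 % high; and the net speed of very short active phases is
underestimated because smoothing widens their apparent duration, so the mean
interior active-phase net speed runs about 7 % low. Both sit inside a 10 %
tolerance in expectation, the pause bias with little margin. Removing either
would need sub-window temporal resolution — changepoint-style segmentation —
which is outside this package's deliberately simple scheme.

A phase is *interior* when bounded by opposite-label phases on both sides —
for an alternating sequence, everything except the first and last phase.
Aggregates are reported separately for interior phases and for all phases:
an active phase between two pauses has a known beginning and end, whereas
boundary phases are truncated by the observation window. By the same
definition a paused phase — the duration between two active phases — is
meaningful only as an interior phase, so pause-duration summaries use
interior pauses.

## Regional context

The chamber geometry is a one-dimensional arc-length model along the axon
from the point of cargo addition: axonal compartment, microchannel (450 µm —
the *distal* axon), the axonal stretch of the cell-body compartment
(*proximal*), and soma. Region intervals are half-open on the upstream side,
so boundary points are deterministic. Whether "distance travelled" should be
Euclidean or along the axon is ambiguous in general; this package computes
along-path arc distance (points are projected onto the axon polyline), which
is the quantity transport kinetics act on. Spatial spread is summarized in
left-closed 200 µm bins with mean ± SEM across replicate cultures or runs. A
track's region is the majority region of its localizations, and tracks
crossing the distal/proximal boundary can be split at the crossing for
region-pure statistics. Coordinated transport is detected as co-temporal
track pairs whose mean inter-distance stays below 2 µm for at least 5 s (the
observation motivating the criterion reports pairs never separating by more
than 2 µm; the detector needs an operational rule, so mean distance over a
minimum overlap is this package's choice). The group-comparison layer wraps
Welch tests and one-way ANOVA with Bonferroni-adjusted pairwise post-hocs —
reporting plumbing only, kept thin deliberately.

## The synthetic-data generator

`simulate_trajectory()` draws alternating active/paused phase sequences with
gamma-distributed durations matched by moments to the study conditions
(distal axon: runs at 1.531 ± 0.486 µm/s lasting 7.218 ± 6.346 s between
pauses of 5.288 ± 9.420 s; proximal axon: 1.544 ± 0.446 µm/s,
6.721 ± 6.634 s, 1.931 ± 1.842 s; soma: 1.1 ± 0.55 µm/s, 1.955 ± 1.945 s,
4.953 ± 3.777 s). Gamma durations have positive support and accommodate the
heavy-tailed distal pauses whose SD exceeds their mean. Run speed is constant
within a phase and drawn per phase — matching the sustained linear runs such
cargo exhibits — and paused cargo jitters with 0.05 µm SD, a value at the
localization-noise scale chosen to keep paused cargo "on the track".
Back-and-forth motion is reflected one-dimensional diffusion in a 3–7 µm
domain; coordinated pairs share phase boundaries and trail each other by a
clipped AR(1) tether that keeps the inter-distance below 2 µm; the `ehna`
preset (dynein inhibited) disables active phases entirely. The default axon
path is a straight line, which keeps every kinematic statistic analytically
checkable; a curvilinear polyline can be supplied.

What the generator does *not* emulate: power-law (non-geometric) blink
dwells, axon crossing/fasciculation, depth-dependent aberrations or focus
drift, vesicle fusion and splitting, and motion blur within an exposure.
Passing tests therefore demonstrate correctness of the analysis chain under
the stated model, not robustness to every artefact of real recordings.

## Reproducibility and problem sizes

Every stochastic stage draws from R's global RNG, so a single `set.seed()`
(or the `seed` field of `pipeline_config()`) reproduces movies, masks and all
derived tables bit for bit; `run_pipeline()` writes a manifest sufficient to
re-execute a run. Movies for end-to-end validation are rendered on a narrow
pixel strip along a straight axon — tall enough for the fitting window, long
enough for the expected travel — which keeps a 120 s, 17 frames/s movie
tractable while leaving the camera model untouched. The validation suites
use 10–30 such movies, 53-trajectory preset batches for the trajectory-level
statistics and 20 synthetic fixed-cell fields; these sizes give Monte-Carlo
standard errors comfortably inside the 10 % tolerances being checked.

## Known limitations

Single global gain/offset (no per-pixel sCMOS-style maps); no multi-emitter
fitting, so QDs closer than ~2 px merge; no merge/split events in linking; no
hidden-Markov or Bayesian changepoint segmentation (the hysteresis scheme is
deliberately simple and auditable — a changepoint extension is a natural
future addition); pauses below the temporal resolution floor are absorbed
into runs, as quantified above.
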