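---
title: "Models and methods: meningeal afferent calcium imaging around CSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: meningeal afferent calcium imaging around CSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `meningealCSD`, the choices made
where the analysis was genuinely open, and what the synthetic-session tests
do and do not establish about real data.

## The scientific setting

Cortical spreading depolarization (CSD) is a slow, self-propagating wave of
neuronal and glial depolarization, the presumed substrate of migraine aura.
Two-photon calcium imaging of GCaMP6s-expressing trigeminal afferents over
the meninges of an awake, head-fixed mouse captures three phenomena around a
single CSD episode:

1. an acute calcium wave sweeping across the field of view (FOV) at a few
   mm/min;
2. minutes-long changes in ongoing activity (a small population with delayed
   prolonged activation, another with immediate suppression);
3. mechanical sensitization — an increased calcium response per unit of
   locomotion-driven meningeal deformation (scaling, shearing, Z-shift),
   including the unmasking of previously deformation-insensitive afferents.

The package implements the full trace-level pipeline for these analyses,
assuming registration and ROI extraction have already produced per-ROI
fluorescence traces, neuropil (background-mask) traces, per-frame affine
registration parameters, and a spatially binned background-fluorescence
movie. These inputs live in a validated S4 container
(`RecordingSession`) with an HDF5 on-disk representation.

## Signal model

Per ROI, the corrected fluorescence is `F = F_ROI - F_np + <F_np>`, where
`<.>` is the mean over the whole recording; the baseline `F0(t)` is the 10th
percentile of `F` over the trailing 32 s (partial history near the start, so
the early baseline is defined rather than NA); `dFF = (F - F0)/F0`; and the
standardized trace is `z = (dFF - median(dFF)) / SD(dFF over quiet
wakefulness)`. Quiet wakefulness is operationalized as stillness: outside
locomotion bouts and their 30-s margins. The median is taken over the full
trace (the natural reading of an unqualified median; flagging this choice
here). A fluorescence event is a maximal run with `z > 1` (strict) lasting
at least 1 s whose peak dFF reaches 0.05. Percentiles interpolate linearly
between order statistics (R type 7) for bit-reproducibility.

For sessions with a CSD trigger, the quiet mask for standardization is
restricted to the baseline (pre-CSD) epoch. This keeps the acute wave and
any post-CSD activity changes out of the noise estimate and — critically for
the sensitization analysis — gives the pre and post epochs one common scale.

## Locomotion and deformation

Wheel velocity is the first difference of the encoder series times the
sampling rate (15.5 Hz), block-averaged onto imaging frames (1.03
volumes/s). A two-state hidden Markov model with Gaussian emissions is fit
to speed (|velocity|) by EM with 20 random restarts (forward-backward and
Viterbi recursions in C++); the higher-mean state is "locomoting", making
the labels invariant to state permutation. Speed rather than signed velocity
is used because wheel direction is irrelevant to the behavioral state.
Bouts are state runs of at least 2 s; stillness excludes bouts plus 30-s
margins on both sides.

Meningeal deformation comes from the per-frame affine registration
correction. The method for converting an affine to scalar scale/shear series
is not standard, so the package commits to a singular-value decomposition:
with singular values `s1 >= s2` of the 2x2 linear part, the isotropic
stretch is `sqrt(s1*s2) - 1` (signed: + expansion, - compression) and the
anisotropy (shear) is `(s1 - s2)/2` (non-negative by construction). This
split is rotation-invariant and symmetric in expansion/compression. Scale is
converted to micrometers by multiplying by half the FOV diagonal — the
displacement of a corner under pure isotropic stretch; shear is additionally
reported in the same unit. Z-shift is plane shift times plane spacing,
positive toward the skull. These conversion rules are the package's own
(documented) choices; only their rotation-invariance and exact recovery of
planted deformations are testable properties.

## Fiber clustering

ROIs belonging to one axon co-activate. During quiet wakefulness the
binary event-indicator series of each ROI are correlated (Pearson),
thresholded at 0.7 into an adjacency, and the cosine dissimilarity between
adjacency rows feeds average-linkage hierarchical clustering. The
dissimilarity between binary rows lives in [0, 1]: 0 for identical event
profiles, ~1 for orthogonal ones. Flat clusters are cut at cophenetic
distance 0.5 — half-way between those poles. We document two alternatives
and why they were rejected: a distance cutoff of 2 can never split (2 is the
cosine-distance maximum, and binary rows cannot even reach 1), and the
MATLAB-style dendrogram-inconsistency criterion (available via
`criterion = "inconsistent"`) is bounded by 2/sqrt(3) for its default
depth-2 neighborhood and stays below 2 for small subtrees at any depth, so
it cannot separate few-ROI fibers at a cutoff of 2. The distance rule at
0.5 recovers planted fibers exactly in the noiseless limit and with
adjusted Rand index above 0.9 at the generator's default noise. Clusters
are accepted as-is (no manual screening step); each afferent's trace is the
mean of its members' standardized traces.

## CSD wave characterization

The FOV trace is the mean over background-grid bins. Within 5 min of the
trigger, the smoothed derivative's maximum and following minimum bracket the
initial rise; the pre-wave baseline `F_pre` is the 10th percentile of the
preceding 30 s; the wave onset/offset are the outward crossings of
`0.1 * max(dFF)` around the peak — a relative threshold, so the window is
invariant to fluorescence units.

Each 40x40-pixel background bin is fit with the logistic
`A/(1 + exp(-(t - t_onset)/tau)) + K` over −6..+14 s around the FOV onset.
Initialization is a grid over `t_onset` (1-s steps) and `tau` in {0.5, 1, 2}
s with `A`, `K` solved in closed form, followed by Levenberg-Marquardt
refinement; fits with `R^2 < 0.5`, `tau > 2` s or `tau < 0` are excluded.
Propagation speed is the inverse slope of onset time regressed on the
projection of bin centers onto the propagation axis; the axis itself is the
normal of a total-least-squares line through the wavefront contour (the
median-onset level set of the onset map), oriented toward increasing onset.
Directions are image-coordinate bearings with +y posterior, so 90° means
anterior-to-posterior. Along single long (> 200 µm) fibers the same onset
fit per ROI yields the activation *pace* (s/mm, the inverse of speed),
which stays finite for the near-simultaneous activation seen during
locomotion bouts.

## Ongoing activity

Per afferent, ongoing activity is the fraction of stillness time spent
inside events, in 1-min bins; bins with under 50% stillness coverage are
missing. Against the baseline bins' mean and SD, a post-CSD bin is elevated
above `mean + 2 SD` or reduced below `max(0, mean - 2 SD)`; an afferent is
activated (suppressed) when an elevated (reduced) run longer than 10 min
starts within 30 min of the wave offset. The `±2 SD` rule and the
offset-referenced onset window are this package's operationalization (the
quantitative criterion is not fully specified by the qualitative
description "sustained change"); both `kSd` and the window are arguments.
Missing bins never break a run — they carry no evidence either way — but a
run must hold at least `runMin/2` qualifying bins, so locomotion gaps can
neither truncate a sustained change nor stitch isolated fluctuations
together.

A structural point worth making explicit: under a ±2 SD rule, suppression
is only detectable in afferents whose baseline rate exceeds twice the
bin-to-bin SD of that rate. With sparse Poisson-like events this is
impossible at a 6.9% occupancy baseline — `mean - 2 SD` is negative — so
observed suppression implies tonically active afferents with regular firing.
The synthetic generator encodes exactly that (below).

## Sensitization encoding models

Five predictor families — locomotion state, velocity, scale, shear,
Z-shift — are each expanded into temporally shifted copies at every
integer-frame delay within ±6 s, z-scored, and fit to each afferent's `z`
trace with a Gaussian elastic net (`alpha = 0.01`, i.e. predominantly
ridge). The first 75% of the epoch trains the model; `lambda` is chosen at
the minimum of a 10-fold blocked (contiguous-fold) cross-validation within
the training segment; deviance explained is evaluated on the held-out final
25% against the training-mean null model. The contiguous split and blocked
folds respect temporal autocorrelation — a random split would leak. An
afferent is "well fit" at held-out deviance explained ≥ 0.05.

Post-CSD designs reuse the baseline column means and SDs, so a coefficient
is comparable per physical unit of predictor across epochs — the essence of
the "equal deformation, larger response" comparison. Family contributions
are deviance drops after refitting without a family group (locomotion =
state + velocity; deformation = scale + shear + Z-shift; plus each
deformation member), floored at zero.

Sensitization is a decision table over the pre/post well-fit flags and
per-family peak |beta| across delays: both fit and any family's peak rising
at least 10% (and at least 0.1 absolute) → sensitized; both fit with no
rise and a ≥10% fall → desensitized; fit only post → sensitized by
unmasking; fit only pre → desensitization by loss; neither → never fit. The
10% margin operationalizes "higher coefficients" (no numeric margin is
standard); the absolute floor exists because a maximum over 13 delays is
upward-noise-biased, and empirically separates planted gains (peak changes
≥ 0.3 at the default coupling) from estimation noise (≤ 0.05).

## The synthetic-session generator

`simConfig()`/`generateSession()` produce sessions with full ground truth.
Defaults encode the study conditions: 60 min baseline + 120 min post-CSD at
1.03 volumes/s; 15.5 Hz wheel sampling; 626x423 µm FOV with 40-pixel bins; a
planar wave at 3.8 mm/min traveling anterior→posterior; baseline events
occupying 6.9% of stillness; ~10% of afferents with ~25-min-delayed
prolonged activation and ~20% with immediate suppression, both lasting ~25
min; post-CSD bout rate scaled by 0.6 with unchanged bout characteristics;
and a ×2 post-CSD gain on deformation coefficients in a subset of afferents
sized so that about half of the afferents well fit in both epochs are
sensitized, next to unmasked (silent→coupled) and lost (coupled→silent)
subsets. Deformation series are causally filtered velocity plus noise;
affines are rebuilt from the planted scale/shear with random rotations, so
the decomposition must undo them exactly.

Choices the data could not pin down, fixed once here:

- **GCaMP6s kernel**: difference of exponentials, 0.2 s rise, 1.5 s decay,
  peak-normalized — mid-range for the sensor literature; configurable.
- **Wave shape**: logistic rise (τ = 1 s default) with a 15-s plateau and
  ~10-s exponential return. The logistic matches the wave-fitting model, so
  noiseless recovery is exact by construction; the short return keeps the
  acute wave from bleeding into the post-CSD ongoing-activity bins.
- **Event amplitudes**: ~0.2 dFF with 0.3 lognormal spread. Not calibrated
  to data (amplitude distributions are not reported); documented default.
- **Coupling injection**: the planted coefficient vector acts directly on
  the standardized predictors (the GCaMP kernel is applied to the discrete
  event train only), so planted coefficients are in exactly the units the
  estimator reports. Convolving the drive too would make "recovery" depend
  on deconvolving the kernel — a different estimand than the encoding model
  fits.
- **Occupancy calibration**: detection operates on standardized traces, and
  the quiet-epoch SD is inflated by the events themselves (shot-noise
  variance, Campbell's theorem) and by any coupling drive. The generator
  solves for the Poisson rate whose *detected* occupancy matches the target
  given that self-inflation, including frame-level noise at the run
  boundaries and Boolean overlap of events. A consequence worth knowing:
  detected occupancy saturates near ~0.22 regardless of amplitude, because
  brighter events inflate the SD as fast as they clear the threshold.
- **Suppressed-class fibers** therefore carry a 20% baseline occupancy of
  large (0.8 dFF), near-uniform, quasi-regular (gamma shape 8 inter-event
  intervals) transients — the only regime in which a ±2 SD suppression
  criterion has power. The 6.9% occupancy condition describes the ordinary
  (baseline-class) fibers.

What passing recovery tests shows: the pipeline inverts its own generative
assumptions — planar wavefront, logistic onsets, linear lagged couplings,
step-like activity changes — at realistic noise. What it does not show:
robustness to non-planar or multi-wave episodes, bleaching and slow drift,
registration failure, overlapping ROIs, non-GCaMP6s indicator dynamics, or
couplings that are nonlinear or nonstationary within an epoch. Those belong
to the non-goals of the trace-level pipeline.

## Numerical and testing notes

- Problem sizes in the shipped tests are scaled for a desk run: cohorts of
  12–20 fibers, 14–105-minute sessions, 3 replicates per wave condition,
  100 noise afferents for the false-positive control. All seeds are fixed.
- The event-detection path is verified against a brute-force
  run-enumeration oracle on 1,000 random hour-long traces; baselines
  against direct trailing-window quantiles; BH-FDR and the paired t against
  hand formulas; the bootstrap CI against an enumerable 3-pair resample
  space.
- Degenerate inputs: constant velocity yields all-still with a warning;
  constant predictors are dropped from designs and recorded; singular
  affines are flagged and interpolated; an all-zero dissimilarity yields a
  single cluster; simultaneous onsets raise "no propagation" rather than an
  infinite speed.
- `runPipeline()` is deterministic given its seed, skips the wave, ongoing
  and post-CSD model stages for sessions without a trigger, and prefixes
  stage names to error messages.
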