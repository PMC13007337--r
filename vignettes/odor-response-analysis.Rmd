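---
title: "Methods: odor-evoked calcium response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-evoked calcium response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odortrace)
```

# Scope and model

`odortrace` analyzes somatic calcium signals recorded from
nuclear-localized GCaMP in the olfactory bulb while a panel of odors is
delivered under a fixed trial structure. The measurement model is simple
and deliberately close to how such data are analyzed in practice: each
manually drawn circular ROI integrates the fluorescence of one soma; odor
responses are stimulus-locked transients riding on a stable baseline; and
all population-level claims are built from per-cell summary statistics
(response magnitude, significance, preferred stimulus, lifetime
sparseness), never from raw pixels.

The default protocol is 25 frames/s, 3 s baseline, 5 s odor, 16 s
post-stimulus (600-frame trials, onset at frame 75, stimulus window
`[75, 200)`), seven stimuli, three trials per stimulus. All frame indices
in the package are 0-based with half-open windows, and the onset frame is
`round(baseline_s * frame_rate_hz)` — whole-frame alignment is assumed
throughout.

# The trace pipeline

1. **Extraction.** `extract_traces()` averages all pixels whose centers
   fall within `radius` of the (drift-offset) ROI center. Trial-to-trial
   rigid XY drift is compensated by caller-supplied per-trial offsets;
   there is no motion-correction algorithm, matching a workflow where ROIs
   are adjusted by hand.
2. **Trial averaging.** `average_trials()` is the elementwise mean of
   retained trials. Discards are caller-supplied flags (gross movement
   artifacts are judged by the experimenter, not detected automatically).
3. **ΔF/F.** `compute_dff()` divides each trace by F₀, the mean of the 10
   frames immediately before onset. We store `F/F₀ − 1` so the baseline
   sits at 0. Whether the pure ratio `F/F₀` or the shifted version is used
   makes no difference downstream: every derived quantity is either a
   difference of trace values or a standard deviation, both invariant to
   the constant shift. The choice is therefore a convention, not a claim.
4. **Filtering.** `lowpass()` applies a 4th-order Butterworth design at
   5 Hz, forward and backward. Only the cutoff is part of the analysis
   definition; the realization is ours. Zero-phase application was chosen
   because a causal filter would delay transient peaks into or out of the
   fixed 30-frame magnitude window. The implementation pads by odd
   reflection far enough for the filter transient to decay below 1e-12
   (the commonly used filtfilt in the `signal` package leaves large edge
   transients, which would corrupt the baseline statistics). DC gain is
   exactly 1; a 1 Hz transient passes within 0.2%, a 10 Hz noise
   component is attenuated by >10^5.

We average trials first and filter once, rather than filtering each trial:
both orders give identical results for a linear zero-phase filter, so the
cheaper one is used.

# Response statistics

- **Magnitude** `r_ij` = mean ΔF/F over the first 30 stimulation frames
  minus the mean over the 10 frames immediately preceding the stimulus.
  The 10-frame reference equals the F₀ window by construction (internal
  consistency); both window lengths are arguments.
- **Significance**: peak ΔF/F during the full 125-frame stimulus window,
  expressed in SDs of the pre-stimulus period. We use the entire 75-frame
  baseline for the mean and SD rather than only the 10-frame F₀ window: a
  10-frame SD estimate is far too unstable to anchor a 6-SD rule. The
  threshold (6) is an argument. A baseline with zero SD (noiseless
  synthetic input) is rejected as degenerate — significance is a statement
  about noise, and noiseless data must be assessed through magnitudes.
- **Preference**: the stimulus with the largest *signed* magnitude, among
  cells with at least one significant response. Cells whose only
  responses are suppressions therefore end up unclassified: a "largest
  response" rule with purely negative responses would elevate the least
  suppressed stimulus, which is not a preference in any useful sense.
  Exact ties go to the earlier stimulus in protocol order and emit a
  warning.
- **Lifetime sparseness** `LS = (Σ r/m)² / (Σ r²/m)` on rectified
  magnitudes (negatives set to 0). The formula is only confined to
  `(0, 1]` for non-negative inputs — mixed signs can push it above 1 —
  and no published rule covers suppressed responses, so rectification is
  our documented choice; the signed values remain available in the
  response table. An all-zero rectified vector has no defined selectivity
  and is flagged `NA` rather than forced to a number.
- **Heat-map ordering** is fully deterministic: preferred stimulus in
  protocol order, then descending magnitude to the preferred stimulus,
  then cell id.

# Spatial activity maps

`frame_subtraction()` subtracts the mean of the 10 frames preceding the
odor from the mean of 10 frames during stimulation. The stimulation
window's position within the 5-s odor period is not pinned down by the
analysis definition; the default starts 25 frames (1 s) after onset,
near the rise-time peak of a slow indicator, and is exposed as
`stim_window_offset`. Maps can be scaled per stimulus or across a
subject's whole panel (`scale_maps()`); scaling divides by a maximum
absolute value, preserving sign and zeros exactly.

# Group statistics

- `normalize_counts()` forms per-sample count/volume ratios (cells/µm³)
  and averages ratios within groups — never the ratio of summed counts to
  summed volumes, which would weight samples by size.
- `holm_sidak_family()` runs two-sided Student (pooled-variance) t-tests.
  Pooled variance was chosen because the integer degrees of freedom this
  yields (n₁ + n₂ − 2) match how such families are conventionally
  reported. The Holm–Šidák step-down is implemented directly:
  sorted raw p-values are adjusted to `1 − (1 − p_(i))^(k−i+1)` under a
  running maximum, capped at 1. Degenerate comparisons drop out of the
  family size instead of killing the family.
- `rm_anova_sidak()` fits the classical mixed design (between-group ×
  within-stimulus, subject as the random block) by sums of squares when
  every subject has every level; with missing cells that decomposition is
  undefined and the model is refit by REML (`lmerTest`, Satterthwaite
  df). Post-hoc per-level group comparisons use unpaired t-tests with the
  single-step Šidák correction `1 − (1 − p)^k`, k = number of
  within-factor levels. An effect whose sum of squares is numerically
  zero relative to the data scale (an identically constant response)
  reports F = 0, p = 1 instead of 0/0.

# The synthetic-data generator

`sample_ground_truth()` + `render_ideal_traces()` + `render_movie()`
emulate the features of the recordings that the pipeline actually relies
on:

- **Somata** are isotropic Gaussian intensity profiles (σ = radius/2,
  truncated at 2 radii) at integer pixel positions with a minimum
  pairwise center distance (default twice the 3-px radius, so nuclei do
  not interpenetrate), baseline brightness F₀ ~ U(800, 1200) counts on a
  flat background (default 0 — no dark-frame offset is modeled, and the
  ΔF/F ratio cancels any uniform profile scale, which is what makes exact
  noiseless recovery possible).
- **Tuning**: each cell has one dominant stimulus (amplitude
  U(0.3, 0.8) peak ΔF/F) and a tuning class — `selective` cells respond
  to other stimuli at 0–20% of the preferred amplitude, `broad` cells at
  30–70% — plus, with probability 0.15, one suppressed (negative)
  off-stimulus response in U(−0.2, −0.05). These ranges are stated
  assumptions, not estimates: no amplitude or SNR statistics for the real
  recordings are available to fit.
- **Kinetics**: the transient is the stimulus boxcar convolved with a
  difference-of-exponentials kernel (rise 0.2 s, decay 2.0 s — order of
  magnitude for a slow genetically encoded indicator), evaluated in
  closed form at frame times and scaled so the trace maximum equals the
  stored amplitude. Traces are exactly zero before onset.
- **Nuisances**: additive Gaussian noise (a tractable shot-noise
  surrogate; SD 50 counts by default), optional exponential
  photobleaching, and rigid integer-pixel per-trial drift. Negative
  *model* intensities (possible only with suppression below −1 or a
  negative background) are clipped with a warning above 1% of pixels;
  the post-noise detector floor clips silently, because at a zero
  background offset half of all *empty* pixels fall below zero by noise
  symmetry alone and no signal is lost there.
- **Determinism**: the seed fixes placement, tuning, kinetics, drift and
  every noise realization; noise substreams are derived from the seed and
  the (stimulus, trial) pair, so identical calls give bit-identical
  movies.

What the generator does *not* emulate: optics (no PSF, no depth
blurring), Z-drift, neuropil or hemodynamic contamination, non-rigid
motion, photon-counting (Poisson) statistics by default, or correlated
noise. Passing the recovery suites therefore demonstrates that the
pipeline is a faithful implementation of its own definitions and is
well-conditioned at realistic SNR — not that it is robust to artifacts
the generator never produces.

# Problem sizes and tolerances

The test and acceptance suites run at sizes chosen to exercise the full
acquisition geometry while staying desk-sized: noiseless round-trip
recovery on 50 cells × 7 stimuli (peak ΔF/F within 2%, window magnitudes
within 1e-6 of ideal-trace means, using a 12-px center spacing so
truncated soma profiles cannot overlap ROI disks); a 1000-cell,
three-trial null simulation for the 6-SD false-positive bound (≤1%);
200 cells × 7 stimuli × 3 trials at peak SNR ≥ 10 (noise SD 24 with the
default amplitude and brightness ranges) for ≥95% preferred-stimulus
recovery; and 10,000-replicate global-null simulations (k = 7, n = 8 per
group) for familywise error ≤ 0.055. Analytic LS identities are checked
to 1e-12; filter contracts to their stated bands. Movie memory is kept
near one 600 × 256 × 256 stack (~300 MB) by rendering and extracting one
trial at a time (`simulate_stimulus_traces()`).

# Known limitations

- No automated ROI detection, motion correction, or artifact rejection;
  these are experimenter responsibilities in the intended workflow.
- The 6-SD rule inherits the usual fragility of SD-based thresholds under
  non-stationary baselines; the generator's stationary noise cannot probe
  that failure mode.
- The REML route reports Satterthwaite denominator degrees of freedom,
  which need not match the classical balanced df even on balanced data.
- `lifetime_sparseness()` quantifies selectivity only among *excitatory*
  responses by construction of the rectification rule.
- TIFF I/O is limited to single-channel integer stacks; proprietary
  acquisition formats and OME metadata are out of scope.
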