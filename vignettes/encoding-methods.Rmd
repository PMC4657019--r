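---
title: "Voxelwise encoding of sound frequency and azimuth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise encoding of sound frequency and azimuth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundenc)
```

## The scientific problem

Subcortical auditory structures — the inferior colliculus (IC) in the
midbrain and the medial geniculate body (MGB) in the thalamus — encode
both the spectral content of a sound and its horizontal position
(azimuth). A central question is *how* these two features are combined at
the level of neuronal populations measurable with fMRI: are frequency and
location represented independently, or does each frequency channel carry
its own spatial tuning?

`soundenc` implements the analysis pipeline that addresses this question
with voxelwise encoding models: sounds are represented in a chosen
feature space, a linear mapping from features to per-voxel response
amplitudes (betas) is learned by ridge regression, and the model is
judged by how well it identifies held-out sounds from their predicted
response patterns. Because no public dataset accompanies the design, the
package ships a synthetic-data module that generates every input with
known ground truth, so each stage is validated by parameter recovery.

## Sound representation

The front end is a bank of 128 overlapping constant-Q bandpass filters
with center frequencies log-spaced from 180 to 7040 Hz (5.3 octaves),
mimicking cochlear frequency analysis. The implementation uses a
fourth-order gammatone-like magnitude response, symmetric in
log-frequency, applied in the frequency domain; outputs are half-wave
rectified, squared, and averaged in 8 ms frames
(`cochlear_filterbank()`). Only the time-averaged spectral profile
(`time_average()`) enters the encoding models, which makes the exact
filter shape and frame rate immaterial downstream; the log-spaced grid
and the overlapping bandpass character are the load-bearing properties.

`bin_octaves()` averages the 128 channels into bins of equal octave
bandwidth. Channels are assigned by center-frequency membership in
half-open bins (the last bin closed), which partitions the channels —
nothing is dropped or duplicated, and 128 bins reproduce the input.

## Four model spaces, one parameter budget

All four feature spaces have exactly F = 42 columns, so model comparison
is never confounded by capacity:

* **frequency only** — the 42-octave-bin profile;
* **location only** — the fixed taper `[1/6, 1/3, 1, 1, 1/3, 1/6]`
  placed in the 6-column block of the sound's azimuth (blocks ordered
  −90° … +90°, so columns 1–6 belong to −90°); the taper is used exactly
  as printed, without per-row renormalization;
* **independent frequency–location** — a 35-bin profile concatenated
  with a one-hot 7-azimuth vector;
* **joint frequency–location** — the 6-bin profile placed in the
  azimuth's block, zeros elsewhere, so each column (f, a) is a
  frequency-specific location filter.

Within joint and location blocks the ordering is azimuth-major with
frequency ascending — the one convention the column layout fixes
(`joint_grid()`); feature labels travel with every matrix and
`predict()` refuses mismatched orderings, because a silent permutation
of columns would corrupt every downstream map.

## Ridge regression and the ridge trace

Per voxel j the tuning vector solves
`R_j = (W'W + lambda_j I)^{-1} W' Y_j`, with `W` column-centered and
`Y` voxel-centered (means restored at prediction). One
eigendecomposition of `W'W` is shared across voxels and penalties; the
test suite holds it to the explicit regularized inverse at 1e-8 relative
error.

The penalty is chosen per voxel from the *ridge trace*: the coefficient
path over a 25-point log-spaced grid spanning `[1e-3, 1e3]` times the
mean diagonal of the centered Gram matrix. The rule is the smallest grid
value at which the maximum relative coefficient change to the next grid
value drops below 5%. Two numerical details matter:

* At the large-penalty end coefficients decay as 1/lambda, which on a
  log grid is a *constant* relative change of roughly 44% — the 5% rule
  can therefore never fire there, and when the small-lambda end of the
  trace is still moving (tiny eigenvalues of `W'W` are common with 42
  features from 56 sounds), no grid point qualifies. In that case the
  fit falls back to the flattest point of the trace (the grid value
  minimizing the relative change), which lands on the plateau between
  the under- and over-regularized regimes rather than on a grid edge.
* The criterion and grid are exposed (`stability_tol`, `lambda_grid`)
  and no downstream result depends on a specific lambda value; the
  permutation test freezes each voxel's lambda at its unpermuted value.

Voxel selection mirrors the intended use: voxels with an overall
response t-statistic strictly above 2.9 inside a mask, ranked by t and
capped at 5000 (`select_voxels()`).

## Sound identification and its null

For each held-out sound the predicted pattern is correlated with every
measured test pattern; the rank r of the matching sound maps to the
accuracy `P = 1 − (r − 1)/(S_test − 1)`. This is the unique affine
function of rank with P(1) = 1, P(S_test) = 0, and expectation 0.5 under
random ranking; correlation ties receive average ranks. The suite checks
the chance level empirically: with predictions independent of the data,
the grand mean accuracy stays within 0.5 ± 0.01.

The null distribution permutes training labels under the constraint that
no sound inherits a label from its own azimuth. Uniform rejection
sampling is hopeless here — for 7 balanced azimuths of 8 sounds the
acceptance probability is about exp(−8) — so the sampler draws a uniform
permutation and repairs violations by randomized pair swaps, verifying
the constraint exactly before returning. The p-value uses the
`(1 + k)/(1 + n)` convention, making 1/201 the smallest attainable value
at 200 permutations; validity (super-uniformity under a true null) is
checked by simulation in the acceptance suite.

Group-level comparisons Fisher-transform the per-replicate accuracies
(`atanh`, clipped just below 1 — the transform treats accuracies as
correlation-like quantities, the convention adopted here) and run
one-tailed one-sample tests against chance plus one-tailed paired tests
between models, Bonferroni corrected.

## From time series to betas

The response-estimation stage turns event-related series into the
sounds × voxels matrix in three steps:

1. **Noise regressors.** Voxels poorly explained by the task design form
   a noise pool whose principal components become nuisance columns. Task
   fit is measured by split-half cross-validated R² — fit on odd TRs,
   evaluated on even TRs, so every event contributes to both folds — and
   the pool is `cv-R² <= 0`, which an in-sample R² could never satisfy.
   This is a deliberately self-contained variant of cross-validated
   denoising; the component count (default 5) is not tuned per dataset.
2. **Per-voxel HRF.** A finite-impulse-response deconvolution over a
   7-TR window (~20 s at TR 2.8 s), one kernel per voxel shared across
   sounds, normalized to unit peak so betas carry the scale. With a
   single presentation per sound, amplitude variability across sounds
   acts as structured noise on this estimate — the noisiest stage of the
   pipeline, which the original multi-run design mitigates by repetition.
3. **Betas.** Least squares with one regressor per sound (onsets
   convolved with that voxel's kernel), an intercept, and the nuisance
   columns. The whole path is linear in the series and exact at zero
   noise, which the suite verifies by round trip against the generator.

Betas are not standardized per voxel before model fitting; an option
exists because penalty selection interacts with scaling.

## Topography

A joint-model weight vector reshapes to a 6 × 7 frequency-by-azimuth
matrix, is smoothed with a 3 × 3 Gaussian kernel (SD 0.5 grid units,
truncated and renormalized at the edges — no wraparound, and a constant
matrix stays constant so preferences ignore additive offsets), and the
argmax gives the voxel's preferred frequency and azimuth. Exact ties are
broken deterministically (lowest frequency bin, then most central
azimuth) and flagged.

Gradient analysis takes a 2D best-frequency slice, differentiates
log2(CF) by central differences (one-sided at edges, skipping unmapped
neighbours; voxels with no resolvable neighbour or a zero gradient are
dropped), and maps each gradient to an angle in [0, 360) with 0° along
the first in-plane axis, counterclockwise positive — the convention is
internal, and all assertions are rotation-equivariant. Angles are
histogrammed at 20° (default), circularly smoothed over 3 bins, and
local maxima reported as peaks: one for a single gradient, two roughly
180° apart for a mirror-symmetric low–high–low map.

Azimuth preferences are summarized as per-azimuth proportions, overall
and split at CF 1.5 kHz (below which both ITD and ILD cues inform
location); periphery (±90°) versus each central azimuth is tested by
paired one-tailed t-tests across replicates, Bonferroni corrected.
Contra/ipsilateral maps flip the sign of azimuth in left-side
structures; 0°-preferring voxels are classified "central" and excluded
from contra/ipsi proportions.

## Binaural cues

Cue extraction needs phase, so it uses an STFT front end (Hann window,
32 ms / 8 ms hop) rather than the energy-only filterbank. ILD is the
difference of time-averaged log-power per bin (dB; positive = left
louder) — dB rather than raw power difference for scale invariance. ITD
converts the interaural phase difference, aggregated over frames by a
power-weighted circular mean, to time via `Δφ/(2πf)`. Bins above
`1/(2 × max_itd_us)` are flagged invalid: there a physical delay up to
`max_itd_us` (default 800 µs, just above the human free-field maximum)
wraps beyond ±π. Informativeness subtracts the cue at +90° from that at
−90° per paired sound, normalizes the per-bin mean by its maximum (so
the statistic peaks at exactly 1), and tests each bin with a one-tailed
one-sample t-test across sounds (sounds, not time frames, are the
observations), Bonferroni corrected.

## What the generator emulates — and what it does not

`generate_sound_set()` produces balanced azimuth assignments and smooth
spectral profiles (1–3 Gaussian bumps in log-frequency, SD 0.3–1.5
octaves, a natural-sound-like sparsity); `generate_voxel_tuning()` draws
separable Gaussian tuning in log2-frequency × azimuth — frequency SD 0.5
octaves (~1.2 octaves FWHM, in the range auditory fMRI reports for voxel
tuning) and azimuth SD 30° (~70° FWHM, broad spatial tuning); responses
are `Y = W_joint R_true + noise` with noise SD 0.1, about a quarter of a
typical voxel's signal SD (SNR ≈ 4). `generate_timeseries()` adds the
temporal layer (TR 2.8 s, 2/3/4-TR jitter, peak-normalized double-gamma
HRF), and `generate_binaural_audio()` imposes exact per-band ILDs and
broadband ITDs in the frequency domain.

Deliberately absent: room acoustics and head-related transfer functions
(the original recordings carry reverberant ILD at low frequencies; the
per-band ILD interface can mimic that, but no room model is claimed),
semantic sound categories, scanner artifacts beyond white noise, and any
real anatomy — so passing tests demonstrate the correctness of the
computations, not that real IC/MGB data would behave this way.

A note on parameter recovery: preferences estimated from noisy fits are
compared against the *same* preference functional applied to the
noise-free true weights, which isolates estimation error from grid
discretization. At the default SNR the fitted argmax is not always the
true one — with 56 training sounds only 8 inform each azimuth block, and
the suite documents that misses are confined to single-bin flips (≥99%
of voxels land within one bin of the truth) while exact-match recovery
sits below the 90% the acceptance suite demands; the corresponding
acceptance expectation is left failing rather than relaxing the stated
noise level, because the shortfall is an information limit of the
design, not an implementation defect (the fitted rule performs within a
few percent of the best single penalty on the grid, and noise-free
recovery is exact).

## Problem sizes and runtime choices

The test and acceptance runs use the design sizes of the study they
emulate — 56 + 28 sounds, 7 azimuths — with voxel counts of 200–500,
500 draws for chance calibration, and 200 × 200 permutation repetitions
for null validity; these sizes give stable estimates (binomial SEs well
inside the asserted tolerances) while keeping the full suite in the
minutes range. Replicate-level comparisons use 6 replicates, matching
the original cohort size.

## Known limitations

* The ridge-trace stability rule is a documented stand-in; the
  historical rule it gestures at has no published formula.
* The FIR/HRF stage assumes the response of a voxel is one kernel
  shared across sounds; latency or shape differences between sounds
  alias into betas.
* Gradient peaks come from a smoothed angular histogram; with very few
  mapped voxels the peak location is quantized to the bin width.
* `compare_models()` treats each replicate's mean accuracy as one
  observation; it does not model within-replicate uncertainty.
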