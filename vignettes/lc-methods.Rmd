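---
title: "Quantifying locus coeruleus structure and function: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus coeruleus structure and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpipe)
```

# The measurement problem

The locus coeruleus (LC) is a pair of thin, roughly cylindrical
noradrenergic nuclei in the dorsal pons, about 15 mm long and 2.5 mm in
diameter per side. Two quantities are of interest in aging studies:

* **structural integrity**, summarized by the *LC contrast* — the relative
  hyperintensity of the nucleus on neuromelanin-sensitive MRI against a
  pons reference region; and
* **functional responsiveness**, summarized by the *LC response* — the
  event-related BOLD amplitude evoked by rare target tones in an auditory
  oddball stream.

Because no public dataset accompanies the design this package emulates,
every input is synthetic, generated by the package itself with known
ground truth. That turns each pipeline stage into a testable estimator:
the phantom generator plants a contrast amplitude the structural chain
must recover; the BOLD generator plants a response amplitude the GLM must
recover; the cohort generator plants regression slopes the linear models
must detect (or, for planted nulls, not detect beyond the nominal rate).

# The structural chain

## Model

The phantom is a constant pons plateau (default intensity 100) holding two
hard-edged cylinders brightened by `contrast_amplitude × pons_mean`, with
optional additive Gaussian noise. A hard edge keeps the noiseless oracle
exact; a `peaked` radial profile (Gaussian falloff from the axis) is
available for tests that need the brightest voxel pinned to the
centerline, and an `edge_sigma_mm` option softens the boundary. Rician
noise is deliberately not the default: the plateau intensities are far
from zero, where Gaussian noise is an accurate approximation of magnitude
MRI noise.

The estimator follows the native-space workflow: intersect the two rater
masks per side, upsample the volume by a factor of 2 (trilinear),
skeletonize by keeping the brightest in-mask voxel per axial slice, and
normalize each skeleton intensity by the mean of a slice-corresponding
15 × 15-voxel pons patch:

$$\mathrm{contrast}_{s,i} = \frac{LC_{s,i} - \overline{\mathrm{pons}}_i}{\overline{\mathrm{pons}}_i}$$

Per-side values are the mean over slices; the bilateral LC contrast is the
mean of the two sides. As a ratio the statistic is invariant to global
intensity rescaling — asserted as a property test — while an additive
offset $k$ changes slice values to $(LC - \mathrm{ref})/(\mathrm{ref}+k)$,
asserted against that closed form.

## Design choices

* **Delineation space.** Rater masks are generated on the upsampled grid,
  because the emulated workflow delineates on images registered to the
  upsampled T1. The synthetic rater marks the fully hyperintense core;
  jitter then flips boundary voxels independently per rater. This choice
  also makes the noiseless end-to-end oracle exact: block-upsampled
  native-grid masks would include the two outermost interpolated slices of
  each cylinder, where trilinear interpolation attenuates the plateau
  (measured bilateral contrast 0.2975 instead of 0.3000).
* **Per-side aggregation** over slices is the mean (consistent with the
  bilateral mean); a max or other summary can be computed from the
  returned per-slice table.
* **Tie-breaking** in skeletonization is deterministic: smallest x, then
  smallest y. On a flat plateau all interior voxels tie, so the skeleton
  is only guaranteed to track the centerline under a radially decreasing
  profile — which is how the corresponding test is constructed.
* **Reference anchor.** The reference patch center is a single in-plane
  coordinate per subject (the generator emits the true anterior-central
  pons point), constant across slices, clamped so the 15 × 15 patch always
  fits in the grid. Slices whose reference mean is ≤ 0 are an error, not
  silently skipped.
* **Selection bias.** Taking a per-slice maximum under noise is upward
  biased; the suite asserts the bias is zero without noise and grows
  monotonically with noise level. Real LC contrast estimates inherit the
  same bias; the package makes it visible rather than hiding it.

## The probabilistic template

The template is the voxelwise occupancy fraction: the sum of binary masks
divided by the number of subjects. Synthetic subjects share one space, so
spatial normalization is the identity; with real data, masks must be
transformed to a common grid first.

# The functional chain

## First level

The target-onset stick function is convolved with the canonical
double-gamma HRF (response gamma with shape 6, undershoot gamma with shape
16, ratio 1/6, 32 s support, unit peak) on a microtime grid of TR/16 and
sampled at volume times. Nuisance regressors are the six realignment
parameters plus sine/cosine expansions of cardiac phase (order 3) and
respiratory phase (order 4); phase is the elapsed cycle fraction between
detected peaks, the same rule for both modalities. Subjects without
physiological recordings simply lose those columns — the design never
loses rows, mirroring a study in which five participants lacked physio
data.

The drift model is the discrete-cosine set below 1/128 Hz **plus a
centered linear term**. The cosine count follows the standard convention
`floor(2·N·TR/128)`. The linear column is an addition worth explaining: no
finite regression basis can exactly annihilate slow drift of arbitrary
frequency (a projection argument — the family of slow sinusoids is
infinite-dimensional), and the generator plants linear drift. With the
linear term, planted linear drift and any drift inside the basis span
leave the task coefficient unchanged to machine precision; an off-basis
slow sine at 1/250 Hz moves it by about 2% of the drift amplitude, which
the suite bounds explicitly.

Motion QC summarizes each realignment parameter as the sum of absolute
per-volume values (the discrete form of integrating |parameter| over the
run; frame-to-frame increments are also reported). Subjects are excluded
when any per-volume translation reaches 3 mm or rotation 3°; the
inequality is strict, so a trace peaking exactly at 3.0 is excluded.

## ROI extraction and the group level

The LC response is the mean task coefficient over the skeleton voxels
mapped into functional space by nearest neighbor (each skeleton voxel
center, in mm, falls into exactly one functional voxel). Nearest-neighbor
resampling preserves binary membership and avoids inventing
partial-volume weights.

The group model is a one-sample test of the covariate-adjusted mean
response with mean-centered age, sex and BMI; with N subjects the residual
df are N − 4 (53 subjects give t with 49 df). Small-volume correction is
voxel-level Bonferroni over the template support — deliberately
conservative and assumption-free, replacing random-field-theory FWE, with
clusters formed at 26-connectivity and a 20-voxel reporting floor
available via `cluster_report()`. Null simulations confirm the family-wise
error stays at or below the nominal level.

## Simulated BOLD

LC voxels (those whose footprint overlaps the cylinder, so that
nearest-neighbor ROI resampling always lands in planted signal) carry the
peak-normalized task regressor times the amplitude on a baseline of 100 —
one unit is 1% signal change. All voxels receive linear drift, random
per-voxel couplings to the motion parameters and to cardiac/respiratory
phase, and white noise. The generator reproduces the run geometry
(270 stimuli at a 2 s onset asynchrony, TR 2.34 s) but not scanner
physics: no k-space simulation, distortion, slice timing, or spatial
autocorrelation of noise. Passing recovery tests therefore demonstrates
estimator correctness, not robustness to artifacts the simulation does
not contain. Spatial smoothing (3 mm FWHM, as in the emulated
pre-processing) is available (`smooth_volume`, pipeline option
`bold$smooth_fwhm`) but defaults to off in the pipeline: on phantoms whose
activation fills the small ROI exactly, smoothing only bleeds signal out
of the ROI and biases amplitude recovery downward.

# The cohort generator

Covariates are drawn per group from truncated normals on the observed
[Min, Max] ranges. The parent mean and SD are solved (nested 1-D
root-finding on stable log-space quadrature) so that the *post-truncation*
moments match the configured group summaries — naive truncation of
N(mean, SD) would shift both. One genuine limitation: with the mean pinned,
the truncated-normal family has an SD supremum below some of the printed
SDs (small-sample empirical summaries need not be attainable by any such
distribution — e.g. an SD of 5.3 on a range of width 17 exceeds even the
uniform limit 4.91). For those variables sigma saturates and the closest
achievable SD is used; means are matched exactly everywhere. The tests
assert 1% convergence for all means and for the feasible SDs. Sex is
Bernoulli with the observed group proportion of women.

The oddball design places exactly `round(n·p)` targets with no two
adjacent (drawn uniformly over all such arrangements via the gap
bijection), at a fixed 2,000 ms onset asynchrony; run duration is
`n_stimuli × ISI`, treating the calibration period as outside the modeled
run. Behavioral responses are not modeled in the GLM — the task enters as
a condition, not as performance.

# The sensitivity analysis

`min_detectable_effect()` inverts the power function of the t-test of one
coefficient among `1 + n_covariates` predictors: df = n − covariates − 2,
noncentrality √(n·f²) with f² = r²/(1 − r²), solved by bisection to
|Δr| < 10⁻⁶. With α = 0.05 one-tailed, power 0.8, n = 52 and three
covariates (df 47) this gives |r| = 0.33, R² = 0.11; `power_at_effect()`
is its exact inverse. The df convention follows the three-covariate
reading of the emulated analysis (47 rather than 46); both are available
through `n_covariates`.

The Monte-Carlo cross-check uses the fixed-predictor convention the
analytic formula assumes: the partialled focal predictor is rescaled to
sum of squares n in each simulated dataset. With fully random predictors
the realized power is measurably lower (about 0.76 at r = 0.33) because
the partialled sum of squares fluctuates around its nominal value — a
useful reminder that such sensitivity analyses describe fixed designs.

Group comparisons use the Welch t-test (the unequal-variance form
reproduces the published BMI comparison from its summary statistics;
reconstructing samples with exactly those moments yields p ≈ 0.005) and a
Pearson chi-square for sex composition. The printed sex p-value of the
emulated table (0.15) is not recoverable from its own 2 × 2 counts under
Pearson, Yates, or Fisher forms (all give p ≥ 0.28); the package
implements the stated test and leaves the discrepancy as a property of
the printed table.

# The pipeline

`run_full_study()` executes cohort → motion screen → structural contrast →
template → first-level GLMs → ROI extraction → group model → linear models
under a single seed, with exclusions ordered as in the emulated study:
motion first (none fail under default motion amplitudes), then structural
usability (one planted failure leaves 52 of 53 subjects for the
participant-level models), then physio availability (five subjects lose
physio columns but stay in). All 53 motion-screened subjects reach the
second level (the structural failure only blocks mask-dependent
quantities), giving the 49 group-level df. Planted effects default to a
positive age→contrast slope (0.0012 per year around a base of 0.28, SD
0.015) and a *null* contrast→response association — the configuration the
statistics module is calibrated against.

Default problem sizes are chosen so a full 53-subject run completes in
well under a minute on one core: a 48 × 48 × 40 structural grid at
0.7 × 0.7 × 0.75 mm (upsampled ×2) and a 16³ functional grid at 2.1 mm
with 231 volumes. Full-scale grids (80 × 80 × 60 at 0.4/0.4/0.5 mm
structural; 20³ × 243 functional) are used in the recovery test suites and
are reachable through the config. Outputs are plain formats — CSV tables,
NIfTI volumes, a JSON manifest — and `make_report()` renders every number
from the manifest artifacts, so reports are reproducible byte for byte.

# Known limitations

* Phantoms are geometric idealizations: no registration error, no partial
  volume at the structural resolution, no intensity nonuniformity; the
  identity normalization means template construction is untested against
  registration noise.
* The contrast estimator's max-selection bias is quantified but not
  corrected; comparisons across noise regimes should use matched
  acquisition parameters.
* Bonferroni SVC is conservative for correlated t-maps; with smoothed
  real data a permutation max-t approach would be the better-calibrated
  alternative.
* The cohort model treats covariates as independent within group; real
  demographic covariates correlate.
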