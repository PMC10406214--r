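# lcpipe

Structural and functional quantification of the locus coeruleus (LC) — the
small (~15 mm × 2.5 mm per side) noradrenergic brainstem nucleus — as an R
package for simulation-backed analysis pipelines.

The LC appears hyperintense on neuromelanin-sensitive structural MRI, and
its *contrast* relative to the surrounding pons is an accepted marker of
the nucleus's structural integrity. Its *functional response* can be probed
with an auditory oddball task, where rare deviant target tones evoke an
event-related BOLD response. `lcpipe` implements both measurements and the
statistics that relate them, together with a synthetic-data module that
generates every input with known ground truth, so that each stage of the
pipeline is testable by parameter recovery.

## What the package computes

**LC contrast.** The consensus LC mask (intersection of two rater
delineations) is skeletonized by keeping the single brightest voxel per
axial slice. On slice *i*, with skeleton intensity LC<sub>side,i</sub> and
the mean of a slice-corresponding 15 × 15-voxel reference patch in the
anterior-central pons, the per-slice contrast is

    contrast_side,i = (LC_side,i − mean(pons_i)) / mean(pons_i)

The per-side contrast is the mean over slices, and the bilateral LC
contrast is the mean of the left and right values. The chain operates on
the native-space volume upsampled by a factor of 2 (trilinear).

**LC response.** The target-tone onsets are convolved with the canonical
double-gamma HRF and used as the condition of interest in a voxelwise GLM
with a 128 s discrete-cosine high-pass set (plus a linear drift term), six
realignment parameters and Fourier expansions of cardiac (order 3) and
respiratory (order 4) phase as nuisance regressors. The LC response is the
mean task coefficient over the skeleton resampled (nearest-neighbor) into
functional space; group maps use a covariate-adjusted one-sample model with
Bonferroni small-volume correction inside a probabilistic LC template.

**Statistics.** Three participant-level linear models (covariates: sex,
BMI, education): contrast ~ age, response ~ age, and response ~ contrast +
age + contrast × age; Welch t and chi-square group comparisons; and a
sensitivity analysis that inverts the noncentral-t power function of a
single-coefficient test (df = n − covariates − 2, noncentrality
√(n·f²), f² = r²/(1 − r²)) to give the minimum detectable effect size.

## Worked example

```r
library(lcpipe)

# a noisy structural phantom with a planted bilateral contrast of 0.30
ph <- generate_lc_volume(lc_geometry(contrast_amplitude = 0.30),
                         noise_sd = 2, seed = 1)
masks_l <- simulate_rater_masks(ph$truth, "left",  jitter = 0.15, seed = 2, factor = 2)
masks_r <- simulate_rater_masks(ph$truth, "right", jitter = 0.15, seed = 3, factor = 2)
res <- compute_lc_contrast(ph$volume, masks_l, masks_r,
                           ph$truth$pons_anchor, factor = 2)
res$contrast
#> LC contrast: left 0.3174, right 0.3196, bilateral 0.3185 (120 slices)

m <- min_detectable_effect(alpha = 0.05, power = 0.8, n = 52,
                           n_covariates = 3, tails = 1)
round(c(r = m$r, R2 = m$R2), 2)
#>    r   R2
#> 0.33 0.11
```

The recovered bilateral contrast (0.3185) sits slightly above the planted
0.30: selecting the per-slice maximum under noise is upward biased, a
property the test suite asserts explicitly (the bias vanishes as the noise
goes to zero). The sensitivity analysis says a study with n = 52 and three
covariates can detect |r| ≥ 0.33 (R² ≥ 0.11) at one-tailed α = 0.05 with
80% power.

A full simulated study — cohort, phantoms, rater masks, oddball BOLD runs,
group model, and the three linear models — runs from one config:

```r
man <- run_full_study(default_config(seed = 1), out_dir = "study_out")
writeLines(make_report("study_out"))
```

A thin CLI over the same functions is installed at `inst/cli/lcstudy.R`
(subcommands `run`, `power`, `design`, `contrast`).

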