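---
title: "Methods: connectivity-density mapping, factorial ANCOVA and bootstrap mediation"
author: "gfcdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-density mapping, factorial ANCOVA and bootstrap mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfcdkit)
```

# What the package computes

`gfcdkit` implements a gene-brain-cognition analysis chain for resting-state
fMRI cohorts stratified by a two-level clinical factor (cognitively normal,
CN, versus mild cognitive impairment, MCI) and a three-level APOE genotype
factor (protective ε2 carriers, ε3ε3 reference homozygotes, risk ε4
carriers). Its stages are:

1. **Preprocessing** of aligned 4D BOLD series: equilibration-volume discard,
   joint linear detrending and 0.01–0.1 Hz band-pass, nuisance regression
   (motion parameters, tissue signals), and framewise displacement (FD).
2. **Global functional connectivity density (gFCD)**: per voxel, the number
   of other qualified voxels whose time course correlates above *r* = 0.6
   with it — a degree-style hubness measure — followed by grand-mean scaling
   and 6 mm Gaussian smoothing.
3. **Voxel-wise 2×3 factorial ANCOVA** (diagnosis × genotype, Type-III
   tests) with age, sex, education and mean FD as covariates, cluster-extent
   correction by Monte-Carlo simulation of smooth Gaussian null fields, and
   extraction of per-subject cluster means.
4. **Scalar statistics** reproducing a cohort table: Kruskal–Wallis and
   chi-square for demographics, the same Type-III ANCOVA for cognitive and
   volumetric outcomes, covariate-adjusted post-hoc genotype contrasts.
5. **Simple mediation** (three OLS regressions, indirect effect `a*b`) with
   bias-corrected bootstrap confidence intervals, run within the MCI group.

A seeded synthetic-cohort generator supplies phenotype tables, motion traces
and 4D series with planted connectivity hubs, so the entire chain is testable
without clinical data.

# The synthetic cohort: what it emulates, and what it does not

The generator's defaults mirror the acquisition the pipeline targets: 140
volumes at TR = 3 s on a 3 mm isotropic grid, with the first 10 volumes
discarded downstream (leaving 130). The default unbalanced cell layout
(`reference_cell_sizes()`: CN 19/39/18, MCI 13/46/42 across ε2+/ε3ε3/ε4+;
177 subjects, 101 MCI) and the per-cell outcome means and dispersions
(`reference_phenotype_effects()`) are on the scale of a typical elderly
MCI/CN cohort — MMSE around 28, ADAS13 between 9 and 16, hippocampal volumes
near 7.5 ml. Demographics are plausibility dressing only: age ~ N(73, 6),
education ~ N(16, 2.5), sex Bernoulli(0.5).

**Hub construction.** Each connectivity hub carries one latent unit-variance
signal; a member voxel's series is `s · latent + N(0, 1)`. Two members then
correlate at exactly `s²/(s² + 1)`, which makes the connection-counting
threshold analytically checkable: strength 1.23 puts the expected pair
correlation at 0.6, so hubs with `s` clearly above that (the tests use 1.5–2)
are counted and `s = 0` yields a null map. Motion traces are Gaussian random
walks; rotation increments are `amplitude/50` rad so their arc displacement
on the standard 50 mm sphere matches the translation scale, giving mean FD
near 0.15–0.25 mm at the default amplitude.

**What synthetic data cannot show.** Background voxels are temporally and
spatially independent; there is no hemodynamic autocorrelation, physiological
noise, scanner drift beyond a linear trend, registration error, or
anatomical covariance. Passing tests therefore demonstrate the *statistical
machinery* — exact counting, correct F distributions, familywise-error
control under the assumed smooth-Gaussian null — not robustness to real
acquisition artifacts. In particular the cluster-correction null is the
classic smooth-Gaussian one; real fMRI noise has heavier-tailed spatial
autocorrelation, a known fidelity limit of this style of correction.

For power and error-rate studies at scale, `generate_gfcd_cohort()` bypasses
the image chain and draws subject maps directly as unit-variance smoothed
Gaussian fields plus per-cell mean shifts: exactly the across-subject model
the voxel-wise ANCOVA assumes, at a tiny fraction of the cost.

# Preprocessing choices

**Band-pass as one projection.** The filter is realized as the orthogonal
projection removing the span of the intercept, the centred linear ramp, and
every discrete Fourier mode outside [0.01, 0.1] Hz. Realizing
detrend-plus-filter as a single projection makes the operation *exactly*
idempotent, which sequential detrend-then-filter is not. The cost is that the
in-band component of the drift direction is also removed: a ramp has in-band
Fourier content, so any operator that annihilates ramps must attenuate
in-band signals overlapping that direction (about 11% of a 0.05 Hz tone's
norm at 120 frames). We consider exact idempotence and exact ramp removal
the right trade; a zero-phase Butterworth variant is available via
`method = "butterworth"`. Output always has zero temporal mean.

**Order of operations** is discard → detrend/band-pass → nuisance
regression. Nuisance regressors are *not* band-pass filtered before
regression; this is a documented choice (filtering regressors to match the
data band is defensible and would slightly change residual spectra). Tissue
signals are extracted from the filtered series. The qualified mask, by
contrast, is built from **raw intensities** (before demeaning), since the
signal criterion compares temporal-mean intensities.

**FD** uses the translation-plus-50-mm-arc convention with the first frame
set to zero; mean FD is computed over post-discard frames. Subject-level
motion QC (translation > 3 mm or rotation > 2° relative to the first frame)
excludes subjects, not frames.

# gFCD details

A voxel qualifies if it is in the gray-matter mask and its temporal-mean
intensity exceeds 50% of the gray-matter grand mean (`snr_fraction`
configurable and recorded in the mask's provenance). Connections are counted
at strictly `r > 0.6`; only positive correlations count by default
(`absolute_r = TRUE` for the |r| variant); self-correlation never counts, so
raw counts live in [0, V−1] and are symmetric (the total over voxels is
even). Counting is blocked as a standardized cross-product, which is
algebraically identical to the naive O(V²) pairwise loop — the test-suite
asserts exact integer equality against `compute_gfcd_naive()` on random
instances. Grand-mean scaling divides by the qualified-voxel mean (fixing it
at 1 ± 1e−10); smoothing is a separable Gaussian with FWHM 6 mm per axis,
σ = FWHM / (2√(2 ln 2)), kernels truncated at 4σ and row-renormalized at the
edges so constants are preserved exactly and an interior impulse reproduces
the sampled kernel. Scaling precedes smoothing.

# Voxel-wise and scalar ANCOVA

Both use one shared core: an OLS fit of
`~ diagnosis * genotype + covariates` with sum-to-zero factor coding, and
Type-III (partial) F tests formed by comparing the full model's residual sum
of squares to the model with the effect's columns removed. With sum-to-zero
coding this matches `car::Anova(type = 3)` (asserted to 1e−10 in the tests)
and is well-defined under the unbalanced cell sizes the cohort layout
produces. A scalar outcome is processed as a one-voxel image, so the two
module surfaces agree exactly. Voxels that are constant across subjects have
no defined F; they are dropped from the analysis mask and reported.

**Smoothness estimation** uses the neighbour-correlation estimator on
standardized residual maps: with lag-one correlation `r₁` at voxel spacing
`d`, FWHM = `d·√(2 ln 2 / (−ln r₁))` per axis, pooled over residual maps.
`r₁` is clamped to [1e−4, 1−1e−8], so white noise collapses to a small
fraction of a voxel rather than failing.

**Cluster-extent correction** simulates `n_iter` standard-normal fields on
the mask's grid, smooths them to the stated (usually estimated) FWHM,
standardizes within the mask, thresholds at the two-tailed |z| quantile of
the cluster-forming `voxel_p` (two-tailed emulates the common simulator
default; a one-tailed switch exists), and records each iteration's maximum
cluster size under 26-connectivity (6/18 selectable, recorded in the
report). `k_min` is the smallest extent whose exceedance fraction is ≤ α.
`k_min` is always recomputed for the mask and smoothness at hand — a
published extent threshold is a property of someone else's mask — and the
report carries sizes in both voxels and mm³. Cluster-forming `voxel_p`
defaults to 0.005.

**Tie-breaks and degenerate cases**: an empty cluster report is a valid
result; peaks are located at the maximum of the supplied statistic map
(first index wins exact ties, as in `which.max`); cluster-level α below
`1/n_iter` is rejected as unresolvable.

# Mediation

`fit_mediation()` estimates `a` (X→M), `b` and `c′` (M and X → Y), and the
total effect `c` from three OLS fits sharing covariates; `c = c′ + a·b`
holds to machine precision and is asserted at 1e−10. Inference on `a·b`
resamples whole subject rows (preserving the joint X–M–Y–covariate
structure), refits both regressions per resample, and forms the
bias-corrected (z₀-only, no acceleration) percentile interval; `z₀` is the
normal quantile of the fraction of bootstrap draws below the point estimate,
clamped away from 0 and 1, and the interval uses type-6 quantiles of the
bootstrap distribution. Genotype enters as an ordinal code (ε2+ = 1,
ε3ε3 = 2, ε4+ = 3, risk-ordered; configurable) — a single-predictor X is
what the Model-4 style decomposition requires, and the risk ordering gives
the indirect effects interpretable signs. Rank-deficient resamples are
recorded and dropped rather than silently kept; a mediator collinear with X
(e.g. `M = X`) is an error, never silent output. The battery runs within
one diagnosis group (MCI by default, where gene–cognition associations are
expected); no multiplicity adjustment is applied across pairs — all
intervals are reported and adjustment is left to the user.

# Problem sizes used by the calibration studies

The package's own studies (also exercised by the test-suite and the
acceptance script) use scaled-down designs chosen to estimate each property
with useful precision at desk scale:

- **Coverage** of the BC interval: 500 datasets, n = 100, a = b = 0.5,
  2,000 bootstrap draws; nominal 95% coverage should land in [93%, 97%]
  (binomial noise ± 1%; published simulations of BC intervals for product
  effects sit near 94–95%).
- **Familywise error**: 200 null cohorts, 6 subjects/cell on a 20³ grid of
  3 mm voxels smoothed to 6 mm, voxel p = 0.005, cluster α = 0.05, 1,000
  null-field iterations; the empirical rate must not exceed α plus the 95%
  binomial margin (≈ 0.03).
- **Effect recovery**: an interaction pattern `d·[[1,0,−1],[−1,0,1]]` with
  d = 1.5 within-cell SD planted in a radius-3 sphere; 25 replicates; the
  surviving interaction clusters must overlap the sphere with Dice > 0.5 in
  at least 80%. Published analyses of this design rarely report voxel-level
  effect sizes, so d is a package choice: d = 1.5 puts per-voxel interaction
  power near 1 at 6 subjects/cell, making the study a test of *spatial
  localization*, not of marginal power.
- **gFCD oracle equivalence**: 20 random instances of up to ~300 qualified
  voxels and 50–200 frames, exact integer agreement.

# Known limitations

- The Monte-Carlo null is smooth-Gaussian, not an empirical autocorrelation
  model; heavier-tailed real noise can inflate cluster false positives.
- The ideal band-pass attenuates in-band signal along the drift direction
  (see above); users wanting strict pass-band fidelity at the price of
  idempotence can use the Butterworth variant.
- O(V²) connection counting is exact but quadratic; grids beyond ~50k voxels
  are guarded against in `cohort_spec()` and need deliberate configuration.
- Post-hoc contrasts default to Fisher LSD on adjusted means (Tukey
  selectable); with three groups LSD's familywise inflation is modest but
  real.
- Whether demographic p-values in cohort tables of this design come from
  ANCOVA or Kruskal–Wallis varies across publications; both are exposed
  (`scalar_ancova()`, `demographics_tests()`).

# A minimal run

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 1)
cfg$cohort$n_per_cell <- 3
cfg$cohort$grid_shape <- c(12, 12, 8)
cfg$glm$n_iter <- 500
cfg$glm$alpha <- 0.05
res <- run_pipeline(cfg)
res$manifest$stages$glm
res$mediation$table
```

The `analysis/` directory of the source repository runs the same chain as
six numbered, narrated scripts (simulate → QC/preprocess → gFCD → voxel-wise
ANCOVA → cohort table → mediation) writing tables under `results/`.
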