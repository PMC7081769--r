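# gfcdkit

Gene–brain–cognition analysis of resting-state fMRI cohorts in R:
**g**lobal **f**unctional **c**onnectivity **d**ensity mapping, voxel-wise
factorial ANCOVA with Monte-Carlo cluster-extent correction, cohort-table
statistics, and bias-corrected bootstrap mediation — with a seeded
synthetic-cohort generator so the whole chain runs and is tested without any
clinical data.

The package targets imaging-genetics studies that stratify an elderly cohort
by a two-level clinical factor (cognitively normal, CN, vs. mild cognitive
impairment, MCI) and a three-level APOE genotype factor (ε2+, ε3ε3, ε4+) and
ask (i) where brain connectivity differs by diagnosis, genotype or their
interaction, and (ii) whether brain features *mediate* the genotype's
influence on cognition.

## The model in brief

**gFCD.** For a voxel \(x_0\) inside the qualified mask (gray matter with
temporal-mean intensity above 50% of the gray-matter mean),

\[ \mathrm{gFCD}(x_0) \;=\; \#\{\, j \ne x_0 : r(x_0, j) > 0.6 \,\} \]

where \(r\) is the Pearson correlation of preprocessed time courses. Maps
are divided by their qualified-voxel mean (grand-mean scaling, mean ≡ 1) and
smoothed with a 6 mm FWHM Gaussian.

**Group model.** At every voxel (and for every scalar outcome) an OLS fit of

\[ y \;=\; \mu + \alpha_{\mathrm{dx}} + \beta_{\mathrm{geno}} +
   (\alpha\beta)_{\mathrm{dx\times geno}} + \gamma^\top \mathrm{covariates}
   + \varepsilon \]

with sum-to-zero coding yields Type-III F tests (df 1, 2, 2) for the two
main effects and the interaction. Voxel-wise maps are thresholded at
p < 0.005 and corrected at the cluster level with an extent threshold
\(k_{\min}\) recomputed from simulated smooth Gaussian null fields on the
actual mask at the actual residual smoothness (3dClustSim-style).

**Mediation.** With genotype coded ordinally (ε2+ = 1, ε3ε3 = 2, ε4+ = 3),
three regressions per (mediator M, outcome Y) pair give paths
\(a\) (X→M), \(b\), \(c'\) (M, X→Y) and the indirect effect \(ab\)
(\(c = c' + ab\) exactly); inference on \(ab\) uses case-resampling
bootstrap with bias-corrected percentile intervals.

## Worked example

A complete synthetic run — simulate, QC, preprocess, gFCD, voxel-wise
ANCOVA, clusters, mediation — on a desk-scale cohort:

```r
library(gfcdkit)
cfg <- default_run_config(seed = 1)
cfg$cohort$n_per_cell <- 4          # 24 subjects, 2x3 cells
cfg$glm$n_iter <- 1000
cfg$glm$alpha <- 0.05
res <- run_pipeline(cfg)

res$qualified_mask
#> <qualified_mask> 14 x 14 x 10 grid, 712 qualified voxels
round(res$smoothness_mm, 2)
#> [1] 4.63 4.65 4.64
res$extent
#> <extent_threshold> k_min = 5 voxels (voxel p < 0.005, alpha = 0.05,
#>                    1000 iterations, NN3)
```

The generator plants a connectivity hub whose coupling follows a
diagnosis × genotype pattern; at this seed the genotype effect survives
correction (one cluster). Mediation on a larger sample recovers planted
paths with a bias-corrected interval:

```r
d <- simulate_mediation_data(200, a = 0.5, b = 0.5, c_prime = 0.1, seed = 4)
fit_mediation(d$x, d$m, d$y, n_boot = 5000, seed = 4)
#> <mediation_fit> n = 200, 5000 bootstrap resamples
#>   a = 0.5163  b = 0.5702  c' = 0.0485  c = 0.3429
#>   indirect a*b = 0.2944, 95% BC CI [0.2000, 0.4119] *
```

The asterisk flags an interval excluding zero; `c - c' - a*b` is zero to
machine precision.

## The analysis workflow

`analysis/01_simulate_cohort.R` … `06_mediation.R` run the same chain as six
narrated scripts, writing tables under `results/`. Stage 2 reproduces the
screening bookkeeping on a 185-subject manifest (3 poor-signal + 5 motion
exclusions leave 177 analyzed, 101 of them MCI); stage 4 finds the planted
interaction hub, e.g.:

```
label  n_voxels  size_mm3  peak_x  peak_y  peak_z  peak_stat  effect
1      76        2052      -7.5    -13.5   4.5     21.4       interaction
2      89        2403       1.5      7.5   10.5    19.5       interaction
```

and stage 6 runs the mediation battery in the MCI group, where the planted
positive-control mediator is the one flagged significant.

## Package layout

- `R/` — synthetic cohorts (`generate_cohort`, `generate_gfcd_cohort`),
  preprocessing (`discard_initial`, `detrend_and_bandpass`,
  `nuisance_regress`, `compute_fd`), connectivity density (`compute_gfcd`,
  `grand_mean_scale`, `smooth_map`), voxel statistics
  (`fit_voxelwise_ancova`, `monte_carlo_extent_threshold`, `form_clusters`,
  `extract_cluster_means`), scalar statistics (`scalar_ancova`,
  `demographics_tests`, `post_hoc_genotype`), mediation (`fit_mediation`,
  `run_mediation_battery`), orchestration (`run_pipeline`, `qc_motion`).
- `vignettes/gfcd-pipeline-methods.Rmd` — the methods notes: model
  assumptions, parameter choices, calibration study sizes, limitations.
- `tests/testthat/` — oracle-based unit tests and the end-to-end property
  checks.
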