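# rehoconn

Resting-state fMRI analysis of **intraregional** and **interregional**
BOLD synchrony, for imaging groups comparing a patient cohort against
matched controls (the motivating application is chronic subjective
tinnitus with normal hearing, but nothing in the package is specific to
it).

The package implements, end to end:

* **Regional homogeneity (ReHo)** — for each in-mask voxel, Kendall's
  coefficient of concordance over the voxel and its 26 nearest
  neighbours:

  W = (Σᵢ Rᵢ² − n R̄²) / { [K²(n³ − n) − K ΣT] / 12 },

  with per-series midranks over n time points, rank sums Rᵢ across the
  K series, and the standard tie correction ΣT = Σⱼ Σ_g (t³ − t).
  Maps are global-mean normalised and smoothed (4 mm FWHM).
* **Seed-based functional connectivity** — Pearson correlation of each
  voxel with an ROI mean time course, Fisher z = atanh(r); seeds are the
  positive surviving clusters of the ReHo group contrast.
* **Preprocessing** — dummy-volume discarding (10 of 240), per-voxel
  linear detrending, ideal FFT band-pass (0.01–0.08 Hz), separable
  Gaussian smoothing, 9-regressor nuisance removal (6 motion +
  global/WM/CSF), and strict 2.0 mm / 2.0° motion screening.
* **Group inference** — covariate-adjusted voxelwise GLM contrasts
  (age, sex, education, gray-matter volume as nuisance covariates),
  residual-based Gaussian-field smoothness estimation, and AlphaSim-style
  Monte-Carlo cluster-extent correction with 6/18/26-connectivity.
* **Brain–behaviour statistics** — simple and partial correlation of
  cluster summaries with clinical scores (THQ, SAS, SDS, duration),
  Bonferroni control, plus summary-statistic t-tests and uncorrected
  chi-square for demographic tables.
* **A synthetic cohort generator** — two groups with planted
  local-synchrony spheres, seed-to-remote coupling whose per-subject
  strength drives a simulated severity score, drift, motion and
  global/tissue nuisance signals; every downstream stage can be validated
  against known ground truth.

## Worked example

Simulate a reduced-grid cohort (29 patients + 30 controls, 240 volumes at
TR 2 s, one planted effect) and run the whole chain:

```r
library(rehoconn)

cfg <- pipeline_config(
  cohort_spec = cohort_spec(
    n_group_a = 29, n_group_b = 30, grid_dims = c(16, 16, 12),
    mask_radius_mm = 21, n_volumes = 240,
    planted_effects = list(planted_effect(
      center_mm = c(-7.5, 4.5, 1.5), radius_mm = 9,
      remote_center_mm = c(7.5, -7.5, 1.5), remote_radius_mm = 9)),
    rng_seed = 1),
  n_iterations = 1000, rng_seed = 1)
run <- run_pipeline(cfg)
run
#> <pipeline_run> 59 analyzed (1 excluded for motion), 2 ReHo clusters (min extent 14), 1 seeds
#> top brain-behaviour correlations:
#> # A tibble: 4 × 6
#>   cluster    score kind          r p_two_sided p_adjusted
#>   <chr>      <chr> <chr>     <dbl>       <dbl>      <dbl>
#> 1 seed_2_cl1 thq   pearson  0.738   0.00000480  0.0000192
#> 2 seed_2_cl1 thq   partial  0.765   0.00000847  0.0000339
#> 3 seed_2_cl1 sds   partial  0.165   0.432       1
#> 4 seed_2_cl1 sas   partial -0.0822  0.696       1
```

Reading this: one extra simulated patient breached the 2 mm motion limit
and was excluded, leaving the 29 + 30 analysed subjects. The ReHo group
contrast (voxelwise p = 0.01, Monte-Carlo extent threshold 14 voxels at
α = 0.05) recovered the planted sphere as a positive cluster (Dice 0.52
against the planted sphere), which became the connectivity seed; the
seeded two-sample contrast recovered the remote coupled region; and the
patients' mean Fisher z in that cluster correlates positively with the
simulated THQ score (r = 0.74 for this seed, Bonferroni-adjusted
p < 0.001) — the planted severity link, whose generative strength is
r ≈ 0.46.

Cluster tables mirror the usual published layout:

```r
run$reho_clusters[, c("cluster_id", "sign", "n_voxels", "peak_t",
                      "x_mm", "y_mm", "z_mm")]
#> # A tibble: 2 × 7
#>   cluster_id sign     n_voxels peak_t  x_mm  y_mm  z_mm
#>        <int> <chr>       <int>  <dbl> <dbl> <dbl> <dbl>
#> 1          1 negative      534  -9.62 -10.5  13.5  -7.5
#> 2          2 positive      182  10.8   -7.5   4.5   1.5
```

(The broad negative cluster is a known side effect of global-mean
normalisation: raising synchrony inside the sphere in one group lowers
that group's normalised values everywhere else.)

`write_fixtures()` exports a cohort as NIfTI volumes, motion text files, a
TSV subject table and a JSON truth manifest; `load_series()`,
`read_motion_params()` and the stage functions (`preprocess_series()`,
`reho_map()`, `seed_correlation_map()`, `glm_contrast_tmap()`,
`alphasim_min_extent()`, `extract_clusters()`,
`correlate_clusters_with_scores()`, ...) can be driven individually on
data from disk.

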