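---
title: "Intra- and interregional BOLD synchrony: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra- and interregional BOLD synchrony: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rehoconn` implements a complete resting-state fMRI analysis chain that
combines two complementary views of spontaneous BOLD synchronisation:

* **intraregional synchrony** — regional homogeneity (ReHo), the voxelwise
  Kendall coefficient of concordance between each voxel's time course and
  those of its 26 nearest neighbours, and
* **interregional synchrony** — seed-based functional connectivity, the
  Fisher-z-transformed Pearson correlation between a region's mean time
  course and every other voxel,

followed by covariate-adjusted voxelwise group inference with Monte-Carlo
cluster-extent correction, data-driven seed selection, and correlation of
cluster summaries with clinical severity scores. Because this class of
case-control studies does not deposit raw scans, the package ships a
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, giving every downstream stage a known ground truth.

## The measurement model

A subject's data are a 4D BOLD array on a voxel grid with a brain mask and
repetition time TR (2 s by default). Temporal conditioning follows the
standard resting-state recipe:

1. **Dummy discarding** — the first 10 volumes are dropped (240 acquired
   volumes leave 230 analysed).
2. **Linear detrending** — per voxel, the least-squares line over time is
   removed.
3. **Ideal band-pass 0.01–0.08 Hz** — a discrete-Fourier projection that
   retains exactly the DFT bins inside the band (DC removed). Being a
   projection it is idempotent, which the tests verify to 1e-10. We chose
   the ideal filter over an IIR design because it is parameter-free, exact,
   and matches the behaviour of the classic resting-state toolboxes.
4. **Gaussian smoothing** (4 mm FWHM) — separable kernels, per-axis
   sigma = FWHM/(2√(2 ln 2)) converted to voxels. Kernel rows are
   renormalised at volume edges so each output voxel is a unit-weight
   average; in-mask smoothing of statistic maps is additionally
   mask-normalised (zero-fill, smooth, divide by the smoothed mask) so
   brain-edge values are unbiased.
5. **Nuisance regression** (connectivity branch only, per the conventional
   protocol) — per voxel, least squares on an intercept plus 9 regressors:
   6 rigid-motion parameters and the global, white-matter and CSF mean
   signals. Residuals are exactly orthogonal to every regressor.

Subjects whose motion exceeds 2.0 mm translation or 2.0° rotation on any
axis are excluded before analysis; the comparison is strict ("more than"),
so a maximum of exactly 2.0 mm is retained. Displacement is interpreted
per axis, not as framewise displacement, matching the wording of the
screening rule this default mirrors.

### Processing order

The ReHo branch computes the concordance statistic on *unsmoothed*
detrended, filtered data and smooths the resulting map, because smoothing
the series first would inflate neighbourhood concordance by construction
(smoothing mixes exactly the voxels whose agreement ReHo measures). A
`smooth_before_reho` switch reproduces the double-smoothing variant some
historical pipelines used. The connectivity branch smooths the series and
then regresses nuisance signals, i.e. discard → detrend → band-pass →
smooth → nuisance regression.

## Regional homogeneity

For K time series of length n, ranked over time with midranks for ties,
with rank sums \(R_i\) across series at time i:

\[
W \;=\; \frac{\sum_i R_i^2 - n \bar R^2}
            {\tfrac{1}{12}\left[K^2 (n^3 - n) - K \sum T\right]},
\qquad \textstyle\sum T = \sum_j \sum_g (t_{jg}^3 - t_{jg}),
\]

where \(t_{jg}\) are tie-group sizes of series j. W lies in [0, 1], equals
1 iff all series share one rank ordering, and has expectation 1/K for
independent series. Ties are handled with midranks plus the standard
correction; a switch disables the correction to mirror legacy
implementations (band-passed continuous data essentially never tie, so the
two agree in practice). The voxelwise map assigns to each in-mask voxel the
W of the voxel plus its in-mask neighbours in a 27-voxel cube (7/19
variants available). Neighbours outside the mask are dropped so K adapts at
the brain edge rather than deflating W with zero-filled series; a voxel
with no in-mask neighbour is NaN. Maps are divided by their in-mask mean
(global-mean normalisation; the normalised map has mean exactly 1 and is
scale-invariant) and then smoothed at 4 mm.

The inner rank-sum accumulation is implemented in C++ — the one place the
package uses compiled code, as is usual for voxelwise neighbourhood loops.

## Seed-based connectivity

Seeds are the positive surviving clusters of the ReHo group contrast
(increased local synchrony), mirroring the data-driven seed selection this
design follows. For each seed, the unweighted ROI mean time course is
correlated with every in-mask voxel (Pearson), and r is mapped through
z = atanh(r). Correlations of exactly ±1 (a seed voxel against a
single-voxel seed) are clamped to |r| = 1 − 1e-7 rather than mapped to
±∞ so they cannot poison group statistics; seed voxels stay in the map.

## Group inference

The covariate-adjusted "two-sample t-test" is realised as an OLS contrast:
per voxel, the subject maps are regressed on an intercept, a group
indicator (patient = 1), and the covariates age, sex (0/1), education and
gray-matter volume; \(t = c^\top\hat\beta / \sqrt{\hat\sigma^2
c^\top(X^\top X)^{-1}c}\) with dof = n − p. With no covariates this equals
the classical pooled two-sample t exactly (verified to 1e-10), and an
intercept-only design gives the one-sample test used for the per-group
connectivity masks.

Cluster-extent correction is an AlphaSim-style Monte-Carlo simulation:
standard-normal fields on the mask's bounding box are smoothed to the
estimated residual smoothness, standardised within the mask, thresholded at
the voxelwise p (two-sided by default, since both increases and decreases
are of interest), and the largest supra-threshold 26-connected component is
recorded; the minimum extent is the smallest size whose family-wise
occurrence probability is ≤ α. Defaults are p_voxel = 0.01, α = 0.05,
1000 iterations, 26-connectivity (matching the ReHo neighbourhood; the
6/18 variants are available). The null uses Gaussian fields — the usual
large-dof approximation — while the data threshold uses the t quantile at
the design's dof. Smoothness is estimated from the standardised GLM
residuals by the Gaussian-field first-difference estimator: per axis,
\(\hat\rho = 1 - \mathrm{var}(\Delta)/2\mathrm{var}\) over in-mask
neighbour pairs and \(\mathrm{FWHM} = 2\sqrt{2\ln 2}\,
\sqrt{-d^2/(4\ln\hat\rho)}\), pooled over subjects.

For each seed, the two-sample contrast is restricted to the union of the
two groups' one-sample surviving clusters (the same correction settings are
used for the one-sample tests; the protocol we follow leaves this
unspecified). If neither group shows significant connectivity the seed is
skipped with a warning.

## Brain–behaviour statistics

Patients' mean z (or ReHo) within each surviving cluster is correlated
with each clinical score (THQ, SAS, SDS, duration). Both the simple
Pearson correlation (p from t = r√(n−2)/√(1−r²) on n−2 dof) and the
partial correlation controlling age, sex, education and GM volume
(residualise both variables on an intercept plus covariates; dof =
n−2−k) are reported, because published reports of this design are
ambiguous about which was used — internal-consistency checks show the
printed headline p-values correspond to the simple Pearson dof.
Bonferroni adjustment uses the family m = clusters × scores within each
kind. Demographic summary comparisons use the pooled-variance t from
summary statistics (Welch optional) and the *uncorrected* Pearson
chi-square for 2×2 tables — the uncorrected form reproduces the printed
sex-split p-value from the printed counts, the Yates-corrected one does
not.

## The synthetic cohort

`cohort_spec()` defaults describe the emulated study: 29 patients and 30
matched controls, 240 volumes at TR 2 s (10 dummies), 3 mm isotropic
voxels on a 24 × 24 × 16 grid with an ellipsoidal mask (in-plane semi-axis
33 mm, capped just inside the grid through-plane). One acquisition-time
discrepancy is worth noting: the emulated protocol reports 8 min 6 s at
TR 2 s (≈243 volumes) but analyses 230 after discarding 10; the generator
rounds to 240 acquired volumes so that the analysed count is exactly 230.

Inside a planted sphere each voxel's series is
\(\sqrt{1-c}\,\varepsilon_v + \sqrt{c}\,u\) with cluster-shared latent u
and per-group coupling c (defaults 0.5 patients / 0.25 controls, radius
9 mm), so the expected within-sphere pairwise correlation equals c before
filtering. A remote sphere shares a second latent w with the seed sphere,
weighted per subject by \(\beta = \mathrm{slope}_{\mathrm{group}} +
0.2\,z\) (slopes 0.8 / 0.32), where z ~ N(0,1) is the subject's coupling
deviate. The simulated THQ is \(103.5 + 34\,z + \mathcal N(0, 66^2)\):
intercept and spread match the emulated patient sample (103.5 ± 74.4),
and the implied THQ–coupling correlation
\(34/\sqrt{34^2+66^2} \approx 0.46\) sits at the headline effect size of
the emulated study. All latents are band-limited to 0.01–0.08 Hz so the
planted structure survives the analysis filter — white latents would be
attenuated by the band-pass and the ground truth would drift away from its
nominal couplings. Every in-mask voxel additionally receives a per-voxel
random linear drift and three shared band-limited nuisance signals
(global/WM/CSF-like, weights 1/0.6/0.6 at amplitude 0.3) that the nuisance
regression removes; since tissue segmentation is out of scope, the
generator's known nuisance series stand in for measured tissue signals.
Motion parameters are bounded random walks (step sd 0.05 mm/°, folded into
±1.5); by default one *extra* patient is generated whose translation walk
is scaled to a 2.5 mm maximum, so screening excludes exactly one subject
and the analysed counts stay 29 + 30. Covariates are drawn from per-group
normal summaries matching the emulated demographic tables (age 40.9 ± 10.5
vs 46.2 ± 11.9, education 10.9 ± 2.2 vs 11.1 ± 1.7, GM volume 581.2 ± 26.4
vs 576.1 ± 22.1 ml, sex Bernoulli 16/29 vs 15/30 male).

What the generator does *not* emulate: scanner artefacts, slice timing,
k-space effects, physiological cardiac/respiratory cycles, spatially
structured tissue maps, motion-correlated signal changes, or registration
error (data are generated aligned; realignment and normalisation are out
of scope). Passing tests therefore demonstrate correctness of the
statistical machinery under the assumed generative model, not robustness
to acquisition artefacts in real scans.

## Numerical choices and degenerate inputs

* Voxel indices are 1-based internally (the R convention); all reported
  coordinates go through the affine applied to index − 1, so they equal
  those of a 0-based implementation. Synthetic grids use an RAS+ affine
  with the origin at the grid centre, giving reproducible MNI-like mm
  coordinates without registration.
* Kendall blocks in which every series is constant return W = 0 (the rank
  variance is undefined); voxels with K < 2 return NaN.
* Fisher z clamps at |r| = 1 − 1e-7; correlations of constant voxel series
  propagate NaN.
* GLM voxels whose residual variance is at rounding-noise level
  (σ² ≤ ε·mean(y²)) are flagged degenerate: t = 0 when the contrast
  estimate is also zero, ±Inf (with a warning) otherwise.
* A variable that is an exact linear function of the partialled covariates
  has partial correlation 0 by definition; the residual-noise correlation
  is not reported.
* `alphasim_min_extent` is deterministic given its seed; the pipeline fans
  one top-level seed into per-stage child seeds so stages can be rerun in
  isolation.
* Monte-Carlo fields are simulated on the mask's bounding box and then
  restricted to the mask, preserving edge effects comparably to the
  reference implementation of this correction.

## Open design points resolved here

* The correction threshold is reported as "corrected P < 0.01" in the
  protocol this follows, without a voxelwise/cluster-wise split; the
  package defaults to p_voxel = 0.01 with α = 0.05 and both are
  configurable, since the original split is not recoverable.
* Whether the ReHo branch also regressed nuisance signals is unspecified
  in the protocol (regression is described only for connectivity); the
  default is no, and `preprocess_series(..., regressors = )` enables it.
* Group means of the seed–remote coupling β needed a two-group split for
  the connectivity contrast to have a target; the generator exposes
  patient and control slopes as separate fields.

## Problem sizes used by the tests

The validation suite runs on reduced grids chosen to keep the full suite
in the minutes range while preserving every structural feature of the
default configuration: 16 × 16 × 12 voxels at 3 mm (ellipsoidal mask
semi-axes 21/21/15 mm, spheres at (−7.5, 4.5, 1.5) and (7.5, −7.5,
1.5) mm), 29 + 30 subjects and 240 volumes for recovery experiments, 40
subjects and 200 replicate analyses for the null-calibration experiment,
and 1000–2000 Monte-Carlo iterations for extent thresholds. The
acceptance script reuses the recovery configuration at the same scale.

## Known limitations

* ReHo and connectivity are computed on regular grids only; surface-based
  variants are out of scope.
* The Monte-Carlo null assumes stationary Gaussian smoothness; strongly
  non-stationary residual fields would need a nonstationary correction.
* Partial-correlation connectivity, sliding-window dynamics and ICA are
  out of scope, as are DICOM ingestion, registration and atlas labelling.
* With very few subjects the covariate-adjusted design can exhaust its
  degrees of freedom; the pipeline falls back to simple correlations when
  patients < covariates + 3.
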