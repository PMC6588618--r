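---
title: "Deriving and validating mask-based functional-connectivity biomarkers"
author: "dualmark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating mask-based functional-connectivity biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmark)
```

## The method

`dualmark` implements a two-cohort strategy for resting-state functional
connectivity (FC) biomarkers of autism spectrum disorder. On a large
*derivation* cohort, per-subject FC maps for K canonical resting-state
networks are computed by dual regression against a K-component spatial
template, and voxels whose FC differs between the ASD and typically
developing (TD) groups are identified with threshold-free cluster
enhancement (TFCE) and max-statistic permutation inference. The result is
30 binary masks (for K = 10): ten *R-masks* — template voxels with Z > 4 —
and twenty *A-masks* — FWE-significant voxels nested inside the matching
R-mask, split by contrast direction (A1–A10: ASD > TD; A11–A20: ASD < TD).
A biomarker is simply the subject's mean FC Z-value inside one mask. On an
independent *validation* cohort, the 30 biomarkers are tested for group
differences, correlated against nine questionnaire scores (SRS total and
its five factors; SNAP-IV hyperactivity, inattention, oppositional
symptoms) under Benjamini–Hochberg FDR, and evaluated as classifiers by
ROC/AUC with a paired test for correlated AUCs.

Because the cohorts behind the original analysis are not redistributable,
the package ships a fully ground-truthed synthetic-cohort generator, and
every quantitative claim made by the test suite is a property of the
pipeline (oracle equivalence, calibration, recovery), not a reproduction
of printed cohort statistics.

## Signal cleaning

Per subject, the pipeline applies, in order: temporal band-pass
(0.01–0.08 Hz), nuisance regression, Gaussian spatial smoothing
(FWHM 6 mm). The regressors are the Friston-24 motion expansion (six
rigid-body parameters, their backward differences with a zero first row,
and both sets squared) plus the top five CompCor components (principal
component time-courses of variance-normalised white-matter and CSF voxel
series). Choices the method text of the field leaves open, and how they
are fixed here:

* **Filter design.** A zero-phase forward–backward Butterworth band-pass,
  order 2 per pass. Zero phase matters because dual regression compares
  time-courses across voxels. Edge handling uses odd-reflection padding
  with steady-state initial conditions, which keeps transients small even
  at the slow 0.01 Hz edge; an ideal FFT filter is available
  (`method = "fft"`) and is used by the generator for band-limited
  time-courses.
* **Confounds are band-passed with the same filter before regression**
  (configurable off), so that the regression cannot re-introduce spectral
  content the filter removed and residuals are exactly orthogonal to the
  filtered confounds.
* **Smoothing last.** The processing order is configurable
  (`steps =`); the default applies smoothing after the temporal steps.
  Boundary handling is a truncated, renormalised kernel (mass-preserving
  away from edges); periodic and zero-padding modes exist for testing.

### Temporal degrees of freedom

A band of 0.01–0.08 Hz retains roughly `0.14 × T` real degrees of freedom
of a T-point series. With 29 nuisance regressors that are themselves
band-passed, a run needs `T` well above 200 × TR⁻¹-adjusted minima before
residuals retain genuine noise; at T = 60 (TR = 2 s) the confounds span
essentially the whole band and the post-regression residual is numerical
leakage. The synthetic generator therefore defaults to **T = 150**
(a five-minute TR = 2 s acquisition, the length typical of the validation
cohorts this design targets). Group inference remains valid at shorter T —
permutation inference only needs exchangeability — but per-subject Z-maps
are then unstable, which is why the calibration experiment (below) runs at
T = 60 while the recovery experiments run at T = 150.

## Dual regression

Stage 1 regresses every time-point's voxel vector on the K spatially
demeaned template maps jointly, giving K network time-courses; these are
demeaned and (by default) variance-normalised, mirroring the common
design-normalisation choice. Stage 2 regresses each voxel's series on all
K time-courses jointly; the stored FC value is the t-like statistic
β/SE(β) on T − K − 1 degrees of freedom, i.e. the GLM coefficient
normalised by residual within-subject noise. No Gaussianisation is applied
by default (a flag converts t to standard-normal quantiles by matching
cumulative probabilities); downstream permutation inference is unaffected
by that monotone choice. Degenerate voxels whose series the model explains
essentially exactly (R² ≈ 1 at double precision) or that are constant get
value 0 and are listed in a QC attribute. The analysis mask defaults to
the intersection of nonzero-variance voxels across subjects.

## Group inference

The group statistic is the pooled-variance two-sample t (exchangeability-
consistent inside a permutation scheme), enhanced with TFCE:
`TFCE(v) = Σ_h e(h,v)^E · h^H · dh` over `h = dh, …, max` with
`E = 0.5`, `H = 2`, 100 steps and 26-connectivity — the canonical defaults
of the enhancement method. Extents are counted in voxels; on a fixed grid
the voxel-volume factor cancels under max-statistic correction. Family-wise
error correction uses the permutation distribution of the image-wide
maximum TFCE value, per contrast direction; the observed labeling is
counted in the null, so p ≥ 1/n_perm and p can never be 0. When the number
of distinct relabelings is at most `nPerm`, they are enumerated
exhaustively and the result flagged accordingly. Monte-Carlo relabelings
are drawn without duplicate tracking — the collision probability is
negligible at realistic group sizes. The reference analysis uses 5000
permutations; desk-scale runs here use 200–500.

The TFCE implementation processes thresholds top-down with an incremental
union-find, entering each voxel at the highest step `s` with
`stat ≥ s·dh` using the same floating-point comparisons as a direct
per-threshold scan, so it agrees with a brute-force
threshold–label–sum oracle to machine precision.

## Masks and biomarkers

R-masks use a *strict* threshold (template Z > 4); A-masks intersect
strictly-significant voxels (FWE p < 0.05) with the component's R-mask.
Boundary values (Z = 4, p = 0.05 exactly) are excluded on both sides.
Empty masks are legitimate outputs: their volume is recorded as 0 and the
corresponding biomarker is missing, which the downstream tables propagate
(rows without tests) rather than abort on. Biomarkers are unweighted voxel
means of the subject's component Z-map inside the mask. The
`BiomarkerMatrix` container is a `SummarizedExperiment` (masks × subjects)
carrying group labels and scores in `colData` and mask bookkeeping in
`rowData`.

## Validation battery

* **Group tests**: two-sided Student's t with pooled variance by default
  (Welch by configuration), flags at 0.05 and 0.01.
* **Correlations**: Pearson r per (biomarker, metric) cell,
  pairwise-complete; BH-FDR adjustment treats all 30 × 9 cells as one
  family by default (a per-metric family is available) — the method text
  this design follows does not state the family, and the global choice is
  the more conservative of the two.
* **ROC/AUC**: the positive class is ASD; markers whose hypothesised
  direction is "ASD lower" (A11–A20) are sign-flipped first, and the flip
  recorded, so AUC ≥ 0.5 corresponds to the hypothesised direction. The
  AUC is the exact all-pairs statistic (ties count half), which equals the
  trapezoidal area of the tie-collapsed threshold sweep; that identity is
  asserted to 1e-12 in the tests.
* **Paired AUC comparison**: DeLong's placement-value
  (structural-components) variance estimator with a two-sided normal
  p-value; a permutation fallback swaps the two markers' scores within
  subjects. Comparing a marker with itself yields a degeneracy flag and
  p = 1.

## The synthetic generator

Each subject's BOLD is `Σ_k map_k(v) · s · w_k(t)` plus AR(1) Gaussian
noise (coefficient 0.3, marginal SD 1), where `w_k` are band-limited
unit-variance time-courses and `s` is a signal scale of 0.15 BOLD units
per template-Z unit, so a template peak (Z ≈ 6–10) carries roughly one
noise-SD of signal — network signal comparable to, not dwarfing, the
noise. Group effects are multiplicative amplitude modulations confined to
an *effect region* (the Z > 5 core of a chosen component, hence nested in
its R-mask): the ASD group's mean region amplitude is offset by
`effectSize × noiseSd` (default 1.5), each subject adds an individual
amplitude factor (SD 0.5, centred within group so the realised group
difference equals the nominal effect exactly), and those per-subject
amplitudes are the *true biomarkers* recorded in the ground truth.

Questionnaire scores use empirical ASD/TD means and SDs of the SRS and
SNAP-IV in an adolescent cohort, clipped to plausible instrument ranges
(clipping counted in the manifest). A *phenotype loading* ties one score
to one component's true biomarker at an exact population correlation `r`
by composing `pooled mean + pooled SD · (r · z_b + √(1−r²) · ε)` with
`z_b` standardised by the theoretical mixture moments; scores with a
loading deliberately do not also receive group-mean offsets, because the
offset itself correlates with the biomarker and would make the target
correlation untunable. The default ground truth ties `srs_total` to the
effect component at r = −0.4, echoing the negative SRS–DMN associations
this design is built to detect.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, scanner drift and artifacts,
motion-corrupted images (motion parameters are generated as smooth random
walks but images are not re-sliced), multi-site heterogeneity. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimators and inference under the stated model, not robustness to every
nuisance structure of real data.

## Calibration and recovery experiments

The test suite runs, among others:

* **FWE calibration**: 200 null cohorts (10+10 subjects, 12³ grid,
  T = 60, 200 permutations); the fraction with any corrected p < 0.05 in
  the positive contrast must lie in the exact 99% binomial interval
  around 0.05. One contrast direction is one corrected family — counting
  both directions would target ≈ 0.0975 under the null, which is not the
  nominal rate of either family.
* **Mask recovery**: ten seeded derivation runs (15+15 subjects, 16³
  grid, T = 150, effect size 1.5 in component 4, 250 permutations); the
  recovered A4 mask must reach Dice ≥ 0.5 against the true effect region
  intersected with R4 in at least 8 of 10 runs.
* **Correlation recovery**: 100 seeded validation runs (21+19 subjects,
  12³ grid, T = 150) with the loading at r = −0.4; the sample correlation
  must fall in the Fisher-z 95% interval around −0.4 in at least 90 runs.
  Estimation noise in the measured biomarker attenuates the observed
  correlation (measured-vs-true correlation ≈ 0.8 at these sizes), which
  the generous Fisher interval absorbs.

Problem sizes in the suite (grids of 12³–16³, T = 60–150, 200–500
permutations, 10–100 replicates) are desk-scale choices that keep the
whole battery runnable on a single CPU in well under half an hour while
preserving every structural property of the full-scale analysis.

## Numerical choices and degenerate inputs

* Strict inequalities at both mask thresholds; boundary voxels excluded.
* Zero pooled variance in a t-map, zero residual variance in stage 2, and
  all-zero TFCE inputs produce flagged zeros, never errors.
* BH-FDR is the standard step-up adjustment (`p.adjust`), validated in the
  tests against hand-computed step-up values and its monotonicity /
  never-create-significance guarantees.
* All randomness flows from explicit integer seeds; per-component
  permutation seeds are derived as `seed + component`. Identical
  (parameters, seed) give bit-identical cohorts, masks and reports.

## Limitations

The permutation design covers the two-group contrast only (no
covariates/Freedman–Lane schemes, no variance smoothing); templates are
consumed, never estimated (no group ICA); registration, slice timing and
motion estimation are out of scope — images are assumed to share a grid
and motion parameters arrive as inputs. Stage-2 "Z" values are t-ratios
whose nominal degrees of freedom overstate the information content of
band-passed data; they are treated as relative FC measures, which is all
the mask-mean biomarkers and rank-based validation statistics require.

## A worked run

```{r demo, eval = FALSE}
library(dualmark)
res <- demoPipeline(seed = 1)
# derivation: 15+15 subjects; validation: 21+23 subjects (matrix 44 x 30)
res$dice          # overlap of the recovered A4 mask with the truth
res$auc           # validation-arm AUC of the A4 biomarker
res$corSrsTotal   # its correlation with the SRS total score
```
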