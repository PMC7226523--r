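---
title: "Radiomic prognosis modeling with radprog: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic prognosis modeling with radprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radprog)
```

## The problem

Pancreatic adenocarcinoma treated with stereotactic body radiotherapy (SBRT)
responds heterogeneously, and clinical staging variables predict overall
survival and local-regional recurrence poorly. Radiomics asks whether
quantitative texture statistics of the pre-treatment contrast-enhanced CT
tumor volume carry prognostic information that clinical covariates do not.
`radprog` implements that analysis end to end — feature extraction, resampled
feature selection, boosted survival and recurrence models under nested
cross-validation, and the clinical / radiomic / combined model comparison —
together with a synthetic phantom-cohort generator so that every stage is
testable without patient imaging, which is never publicly deposited for
cohorts of this kind.

## The feature panel

`extract_features()` computes an 841-feature panel per tumor:

* 13 **shape** features from the binary mask;
* 92 intensity/texture features — 18 **first-order**, 23 **GLCM**, 14
  **GLDM**, 16 **GLRLM**, 16 **GLSZM**, 5 **NGTDM** — on the original image;
* the same 92 on each of the 8 sub-bands of a single-level undecimated 3-D
  wavelet transform (`{L,H}` per axis), for 8 × 92 = 736.

All definitions follow the Imaging Biomarker Standardization Initiative
(IBSI) reference. Images and masks are first resampled to an isotropic
2 × 2 × 2 mm³ grid (trilinear for intensities, nearest-neighbour for the
mask, half-voxel center alignment) and discretized with a fixed bin width of
25 intensity units referenced to the masked minimum. Both values are the
package defaults and are exposed in `extraction_config()`.

Conventions worth stating because tools differ on them:

* **Fixed bin width, not fixed bin count.** Levels are
  `floor((I - min)/w) + 1`, so binning is invariant to intensity shifts and
  each wavelet band is re-binned against its own masked minimum.
* **Direction handling.** GLCM and GLRLM matrices are built at distance 1
  over the 13 unique 3-D directions and feature values are averaged across
  directions; GLSZM zones and GLDM dependences use 26-connectivity.
* **Wavelet kernel.** The Coiflet-1 analysis pair (a `haar` option is also
  provided), applied as an undecimated separable filter bank with periodic
  boundary handling; sub-band labels order the axes as the first, second and
  third array dimension.
* **Degenerate ROIs.** On a constant ROI, correlation-type features return
  the sentinel 1 and entropies 0; failed feature classes propagate as
  flagged `NA` values, never as dropped columns.
* **Shape meshing.** Surface area and volume come from a
  marching-tetrahedra triangulation of the 0.5-isosurface of the mask after
  a light Gaussian smoothing (sigma = 0.7 voxel). Meshing the raw binary
  field overestimates a sphere's area by roughly 25% (stair-step facets);
  with the smoothed field a digital ball of 18 mm radius on a 2 mm grid
  yields sphericity ≈ 0.98 and volume within 2% of the analytic solid. The
  accuracy of the volume estimate degrades for very small lesions (below
  about 5 voxels radius), which is acceptable for the tumor sizes this
  package targets.

## Feature selection

`resampled_selection()` repeats, on random two-thirds subsamples drawn
without replacement (1000 times in the reference configuration):

1. **Univariate screen** — a single-covariate Cox model per feature for the
   survival endpoint (Efron ties, Newton iteration, Wald p), or a one-way
   ANOVA F test for the recurrence endpoint; Benjamini–Hochberg FDR
   adjustment. Features with FDR-adjusted p below 0.25 survive. The loose
   cutoff is intentional: selected-signature features can carry adjusted p
   up to ≈ 0.17, so a stringent screen would discard them; the later steps
   do the real winnowing. If nothing passes, the 10 smallest raw p survive,
   and at most `screen_top_n` candidates (30 by default) are carried
   forward.
2. **Recursive correlation pruning** — while any surviving pair has
   |Pearson r| > 0.80, the most correlated pair loses its weaker member
   (by univariate score; ties resolved by name order for determinism).
3. **SFFS** — classical sequential floating forward selection, with a
   cross-validated boosted-model objective (3-fold CV of a small ensemble;
   the objective ranks subsets, it does not tune hyperparameters).

Selection frequencies are aggregated across subsamples. The final signature
takes features in frequency order, with its size chosen as the smallest k
whose repeated-CV refit objective lies within one standard error of the best
k — a reproducible rule for a step where only the resulting sizes (6 for
survival, 7 for recurrence in the reference analysis) are usually reported.

Two behaviors of this procedure deserve emphasis. First, on a *fixed*
dataset with no signal, a by-chance-associated feature is consistently
re-selected across subsamples of that same dataset; null selection
frequencies of 0.5–0.7 for the luckiest feature are normal and are exactly
why selection must be validated inside resampling. Second, z-scoring the
whole feature table before selection (`normalize_features()` on all
patients) reproduces the whole-dataset-normalization convention of the
original analysis; it is an acknowledged information leak, which is why
`nested_evaluate()` also offers leak-free, per-outer-training-set selection
and normalization — the recommended mode for new analyses.

## Models and evaluation

Both endpoints use gradient-boosted tree ensembles
(`fit_boosted_cox()` / `fit_boosted_classifier()`): depth-limited regression
trees fitted stagewise to the gradient of the negative Cox partial
log-likelihood (Breslow form) or of the binomial deviance, with Newton leaf
values shrunk by the learning rate. The fits are deterministic (no
subsampling). Survival performance is the Harrell concordance index over
comparable pairs (earlier time must be an event; tied times are not
comparable; tied risks count 0.5); recurrence performance is AUC
(Mann–Whitney, midranks for ties) and AUPRC with precision-step
interpolation — linear PR interpolation is optimistic at small n, and the
step convention makes a constant scorer's AUPRC equal the prevalence.

`nested_evaluate()` wraps an outer repeated stratified 3-fold
cross-validation (500 repetitions in the reference configuration, giving
1500 outer test metrics) around an inner repeated 3-fold loop (100
repetitions) that picks hyperparameters from a small grid (ensemble size
× learning rate at tree depth 2; the original analysis names no
hyperparameters, so the grid is deliberately small). Folds are stratified on
the event/label so no fold is event-free at n ≈ 74–150. The fold stream
depends only on the resampling seed and the outcome vector, so the three
models (clinical: gender, T stage, N stage, site, resection; radiomic: the
selected signature; combined: both) are compared on identical outer folds.
Per-patient risks averaged over all outer test sets, split at the median,
give the averaged Kaplan–Meier comparison (`risk_stratification()`,
`average_km()`), with the two-group log-rank test from the survival package.

## The phantom generator

`generate_cohort()` emulates what the analysis needs from contrast-CT tumor
imaging, not the imaging itself. Each patient has three latent standard
normal factors: `z1` scales the correlation length of a Gaussian random
field (white noise smoothed with a kernel of width `corr_length * exp(0.30
z1)` voxels), `z2` scales that field's amplitude (`12 * exp(0.35 z2)`
intensity units), and `z3` scales a coarse blob field (kernel width 2.5
voxels, amplitude `7 * exp(0.35 z3)`), all added to a base intensity of 60
with 3 units of voxel noise inside an ellipsoidal mask with randomized
semi-axes (3.2 voxels to 28% of the grid). These choices make GLCM/NGTDM
statistics move with `z1`, variance-type features with `z2`, and zone/coarse
features with `z3`. Survival times are exponential with hazard
`h0 exp(beta' z)` (`h0 = log(2)/450` per day, matching a median survival of
about 15 months); censoring is uniform on `[0, c]` with `c` calibrated on
the drawn event times to a target censored fraction (default 0.07, the
share of patients alive at last follow-up in a typical cohort of this
kind); recurrence is Bernoulli with a logistic model on `z` (intercept
-0.4). Clinical covariates are drawn from realistic marginal frequencies
(60.8% male, 44.6% N1, 79.7% head tumors, 31.1% resected, T2/T3/T4 =
6.8/59.5/33.8%) and are independent of the latent factors unless the
optional `clinical_signal` switch is set — so the clinical model is
uninformative by construction and the radiomic > clinical ordering is the
planted truth.

What the phantoms deliberately do not emulate: real CT anatomy, Hounsfield
calibration, scanner noise spectra, segmentation uncertainty, or correlated
clinical-imaging confounding. Passing tests therefore demonstrate that the
pipeline recovers signal it is known to contain and stays at chance when
there is none — not that any particular clinical effect size is
reproducible on patient data.

## Numerical choices and degenerate inputs

* Newton steps in the univariate Cox fit are capped at |beta| ≤ 22 with step
  halving; constant features are flagged and excluded rather than fitted.
* Concordance with no comparable pairs, and AUC/AUPRC with a single class,
  return flagged `NA`; nested resampling excludes and counts such folds
  (`excluded`), so collected + excluded = outer_reps × outer_folds always
  holds.
* SFFS memoizes subset scores; an objective failure scores a subset -Inf
  rather than aborting; ties in the forward/backward steps resolve to the
  first candidate in order, making the search deterministic.
* Correlation pruning operates on the absolute correlation matrix with
  non-finite entries treated as 0 (constant columns never force drops).
* The boosted-tree split search breaks gain ties by feature order and
  midpoint thresholds; leaves fall back to a zero step when the Hessian mass
  underflows.

## Scaled-down study sizes

The reference configuration (1000 selection resamples, 500 × 3 outer /
100 × 3 inner) is available through the config objects and is what
`selection_config()` and `resampling_spec()` default to. The package's own
test suite and the acceptance script run the same machinery at desk scale —
150-phantom cohorts on 24³ grids, 30–60 selection resamples, 50 × 3 outer /
10 × 3 inner, and 20 simulation repeats for signature recovery — sizes
chosen so a complete run stays in the minutes range on a single CPU while
every structural count (841 features, 1500 outer metrics at 500 × 3) is
still exercised at full scale where it is cheap. One subtlety of null-control
checks at this scale: on a single fixed cohort with no signal, the mean outer
test metric of a model with fixed covariates carries the dataset's chance
covariate-outcome association (standard deviation across null cohorts ≈
0.05–0.06 at n = 120), so chance-level behavior is asserted on averages over
independent null cohorts rather than on one draw.

## Known limitations

* Phantom texture is stationary within the mask; real tumors are not, and
  shape features carry no planted signal.
* The NRRD codec is intentionally minimal (raw/ascii little-endian,
  `spacings` metadata) — enough for round-tripping the package's own
  cohorts; DICOM is out of scope.
* Maximum-2D-diameter features use surface voxel centers within a shared
  slice/column/row index rather than mesh vertices; for smooth convex masks
  the difference is below the voxel size.
* The log-rank comparison of risk groups is computed on pooled averaged
  risks by default; a per-fold variant can be assembled from
  `nested_evaluate()` predictions if needed.
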