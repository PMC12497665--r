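---
title: "Region-level MRI radiomics for cribriform prostate cancer growth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-level MRI radiomics for cribriform prostate cancer growth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cribriform growth is a Gleason pattern 4 (GP4) sub-pattern of prostate
cancer whose sieve-like, densely cellular architecture is associated with
adverse outcomes. Because dense cellularity restricts water diffusion,
cribriform regions (GP4Crib+) tend to show lower apparent diffusion
coefficient (ADC) values on diffusion-weighted MRI than GP3 or
non-cribriform GP4 (GP4Crib-) tissue. `cribromics` implements a
region-level analysis that asks whether quantitative MRI features can
separate GP4Crib+ regions from GP3/GP4Crib- regions: histopathology-derived
region masks carried on the ADC grid are eroded, radiomics features are
extracted from T2-weighted, ADC and fractional blood volume (fBV) images,
and a class-weighted logistic regression over mRMR-selected features
produces a per-region probability of cribriform growth.

Clinical cohorts with whole-mount, sub-pattern-level histology are not
openly available, so the package ships a seeded synthetic phantom
generator that reproduces the *structure* of such a cohort. Every stage is
exercised end-to-end on phantoms; what that does and does not demonstrate
is discussed at the end.

## Pipeline stages and their models

### IVIM maps

DWI signal follows the intravoxel incoherent motion (IVIM) model

$$S(b) = S_0\left[f e^{-b D^*} + (1-f) e^{-b D}\right],$$

with tissue diffusion $D$ (mm²/s), pseudo-diffusion $D^*$ and perfusion
fraction $f$. The segmented fit uses only the high-b window
**200–800 s/mm² (boundaries inclusive)**, where the $D^*$ term has
essentially decayed: ordinary least squares of $\ln S(b)$ on $b$ gives
slope $-\hat D$ (the ADC) and intercept $A$; the perfusion fraction is
estimated from the intercept deficit, $\widehat{fBV} = 1 - e^{A}/S(0)$.
This estimator is the standard segmented-IVIM form; it reduces to 0 for
monoexponential signals and recovers $D$ exactly on noiseless
monoexponential input (tested to 1e-9 relative). With the
`{0, 50, 300, 800}` scheme only 300 and 800 enter the fit. Voxels with a
non-positive signal at `b = 0` or anywhere in the window are flagged and
set to zero rather than passed to the logarithm; negative fitted ADC or
fBV voxels are set to exactly 0 (and fBV capped at 1) as non-physical.

Residual pseudo-diffusion at `b = 200` biases $\hat D$ slightly upward
relative to the generative $D$; this is a property of the estimator, not a
bug, and the phantom tests assert against the closed-form two-point value
rather than the generative one.

### Region erosion

Two uncertainty sources motivate erosion of the co-registered region
masks: manual histology-to-MRI alignment and partial-volume effects at
region boundaries. The procedure, applied on the ADC grid:

1. **Edge slices are removed entirely**: a slice survives only if the
   region also occupies the slices directly above and below. Removal (not
   mere exemption from erosion) is the reading consistent with whole
   regions vanishing when thin — the phantom reproduces this: small
   cribriform regions are lost preferentially.
2. Every remaining slice is eroded in 2D with a disk: voxel $(i,j)$
   survives iff every in-plane voxel within Euclidean distance
   $r \cdot s_{xy}$ mm was set, where $r =
   \lceil s_{acq}/s_{grid} \rceil \ge 1$ removes one acquisition voxel
   isotropically. Both spacings stay explicit in `erosion_spec()` because
   the acquisition voxel may exceed the resampled grid voxel.

Slice adjacency is judged on the region's own occupancy (the region, not
the prostate, is the delineated object), and each region mask is eroded
independently — overlapping labels are separate objects. Post-erosion
regions with fewer than 2 voxels cannot support feature extraction and are
dropped with reason codes (`empty_after_erosion`, `single_voxel`). A
region can also fall below 2 voxels only after nearest-neighbour transfer
to the T2w grid (whose 3 mm slices are coarser than the 2.73 mm ADC
slices, so an occasional ADC slice has no nearest T2w slice); these are
dropped with reason `insufficient_voxels_on_grid`. Disabling erosion
(`erosion_enabled = FALSE`) reproduces the control analysis on non-eroded
regions.

### Feature extraction

Per region, 153 features named `<map>_<family>_<feature>`:

| map | families | count |
|-----|----------|-------|
| ADC | first-order (19) + shape (7) | 26 |
| fBV | first-order (19) + shape (7) | 26 |
| T2w | first-order (19) + shape (7) + GLCM (24) + GLRLM (16) + GLSZM (16) + NGTDM (5) + GLDM (14) | 101 |

Texture is extracted only from T2w, whose sub-millimetre in-plane
resolution supports it; the diffusion maps contribute intensity and shape
only. The five stated texture families standardly total 75 features; the
implementation exposes exactly those 75.

Settings (all defaults of `extraction_settings()`):

* **T2w normalization**: z-score over the whole image, scale 100.
  Normalization precedes region handling, so the region's discretized
  values depend on whole-image statistics — intentional, as T2w units are
  arbitrary and scanner-dependent. Diffusion maps are physical quantities
  and are not normalized.
* **Resampling**: T2w to 0.27 × 0.27 × 3 mm, ADC/fBV to
  1.03 × 1.03 × 2.73 mm (cohort median voxel sizes); images by cubic
  B-spline (exact for polynomials up to degree 3; mirror boundaries, so
  exactness holds away from edges), masks by nearest neighbour so they
  stay binary.
* **Discretization**: fixed bin width anchored on an absolute
  `floor(x / width)` grid — a scan with intensity range `[6.81, 330.4]`
  and width 3 occupies the bin interval `[2.27, 110.13]`, i.e. the range
  divided by the width. Width 3 for normalized T2w (chosen so most scans
  give roughly 10–100 bins); width 25 for ADC and fBV. ADC is carried in
  1e-3 mm²/s units, where a width of 25 collapses the physiological range
  into a single bin — so ADC/fBV first-order Entropy and Uniformity are
  degenerate (0 and 1) at these defaults. This mirrors the behaviour of
  default-width extraction on small-valued maps and affects only those
  two features; it is kept deliberately rather than silently rescaled.
* **Percentiles** use linear interpolation between closest ranks
  (the convention of the major numerical libraries), which makes the
  90th-percentile-ADC cutoff well defined.
* **Moments** use the population (1/N) convention; Kurtosis is not
  excess-corrected. The robust MAD falls back to the plain MAD when no
  value lies strictly inside [P10, P90] (possible for 2–3-voxel regions).

Shape's `SurfaceArea` counts exposed voxel faces. This estimator is exact
for axis-aligned cuboids but converges to about 1.5× the smooth area for
round bodies (the average of |cos| over orientations), so `Sphericity`
tends to 2/3, not 1, for a digitized ball. A marching-cubes mesh estimator
would remove that bias; face counting was chosen for its exactness on the
lattice and its trivial auditability, and the bias is constant enough
across similarly shaped regions not to disturb ranking-based selection.
The seven features are VoxelVolume, SurfaceArea, SurfaceVolumeRatio,
Sphericity, Maximum3DDiameter, MajorAxisLength and Elongation
(principal-component definitions, zero-clamped eigenvalues for degenerate
regions).

Texture matrices use 3D 26-connectivity at Chebyshev distance 1 with 13
unique angles; GLCM and GLRLM are symmetric per angle and features are
averaged over angles *after* computation. Gray values entering the
formulas are the discretization levels; normalizers that need "the number
of gray levels" (`Idn`, `Idmn`) use the region's full discretized level
count. Degenerate inputs return documented limits (constant region: GLCM
Contrast 0, Correlation 1, JointEnergy 1; NGTDM Coarseness capped at 1e6).
GLDM dependence counts the centre voxel plus identical 26-neighbours
(α = 0). All five families are verified against brute-force enumeration
oracles (exhaustive pair counts, run walking, flood-fill zone census,
direct neighbourhood sums) in the test suite.

### Feature selection and the model

The binary target is GP4Crib+ vs (GP3 or GP4Crib-). The table splits
60/20/20 with per-class largest-remainder rounding (ties resolved toward
the split with the largest global deficit, which reproduces 279/93/93 for
class counts 242/176/47) and volume balancing: within each class, rows are
ordered by volume, allocated by a proportional quota walk and shuffled
within 5-row windows by the seed.

mRMR ranking uses the MID (difference) scheme — the canonical default of
the algorithm: step k maximizes `I(f; y) − mean over selected s of
I(f; s)`, with mutual information estimated on 10 equal-frequency bins,
capped at 20 features for interpretability, ties broken by lexicographic
feature name. The feature count k is chosen by stratified threefold
cross-validated balanced accuracy. The source protocol determines k "in
the validation set using threefold cross-validation", which cannot be
taken literally for 93 validation rows with 9 positives split into 3
folds; the package pools training + validation for the CV (the
`cv_pool = "validation_only"` switch restores the literal reading), and
the final model is refit on the pooled rows with the chosen k.

The classifier is logistic regression maximizing the class-weighted
log-likelihood with an L2 penalty of strength 1/C on the coefficients
(intercept unpenalized), fitted by BFGS with analytic gradients from a
zero start — deterministic given data. Defaults follow the reference
configuration: C = 1, max_iter = 10, 'balanced' class weights
`n/(2 n_class)`, intercept on, convergence tolerance 1e-4, probability
threshold 0.5. The search domain for `tune_hyperparameters()` also lists
l1/elasticnet penalties; only the L2 family is implemented (it is the
selected final model and the only penalty the fitting contract specifies),
so the grid is searched within l2. Features are *not* standardized before
fitting: ADC features are carried in 1e-3 mm²/s so a single-feature
model's coefficients live on the same scale as the printed cutoff
(boundary = −w₀/w₁).

### Evaluation

Balanced accuracy (mean of sensitivity and specificity — the headline
metric under 10% prevalence), ROC AUC (Mann–Whitney form, ties half), and
PR AUC (step-wise average precision) on the held-out test rows.
Uncertainty via percentile bootstrap: regions resampled with replacement
1000 times, 2.5–97.5% CIs; replicates that lose a class are redrawn (and
counted) so exactly `n_boot` valid replicates enter every interval.
Percentile intervals were chosen as the simplest method consistent with
asymmetric intervals around proportions. The baseline comparison is
one-sided exceedance over the all-negative classifier's balanced accuracy
of exactly 0.5: `p = fraction of replicates with (BA − 0.5) ≤ 0`.

## The phantom generator

`phantom_spec()` defines the study conditions; the defaults are fixed
choices, not tuning knobs:

* **Grids**: DWI/ADC 64 × 64 × 20 at 1.03 × 1.03 × 2.73 mm (the ADC
  resampling target), T2w at 0.27 × 0.27 × 3 mm over the same field of
  view. A fixed ~44 cc prostate ellipsoid bounds region placement.
* **Class mix**: regions sampled at 45/40/15 (GP3/GP4Crib-/GP4Crib+), the
  cohort's *pre-erosion* mix; erosion then removes small cribriform
  regions preferentially so the analyzed set lands near the post-erosion
  52/38/10.
* **Volumes**: log-normal with per-label medians 0.16/0.20/0.08 cc and
  log-sd 0.8 (the source cohort's volume range spans four orders of
  magnitude; 0.8 keeps the tail at desk scale while preserving the
  ordering and the erosion-survival differences). Regions are random-axis
  ellipsoids, flat along z (z semi-axis 4.5–9 mm) as whole-mount-derived
  regions spanning a few 3 mm slices are.
* **Tissue contrast**: voxelwise Gaussian diffusion coefficients with
  means 1.20/1.05/0.85 (benign 1.60) ×10⁻³ mm²/s, sd 0.10×10⁻³ — chosen
  once to reproduce the qualitative cribriform-lowest ordering; no
  quantitative per-sub-pattern ADC distributions are published, so these
  are documented synthetic stand-ins. Perfusion fractions 0.07/0.08/0.10
  (benign 0.05), D* = 20×10⁻³ mm²/s. T2w means are *equal* across the
  three cancer classes (300, benign 400, sd 30), so the diffusion maps
  carry the class signal — matching the finding that an ADC feature, not
  a T2w feature, drives the eroded-region model.
* **Noise**: Rician, |S + ε₁ + iε₂| with ε ~ N(0, σ), σ = 5 on a b=0
  signal of ~100 (SNR ≈ 20, a typical prostate DWI regime); σ = 0 enables
  exact tests. DWI channels are IVIM evaluations of the sampled fields;
  the truth maps store the sampled D and f.
* **Seeding**: one master seed; per-case streams derived from
  (seed, case index), so any case is reproducible in isolation and the
  cohort is a pure function of its spec.

What the phantom does **not** emulate: zonal anatomy, histology-slide
deformation and co-registration error, scanner artifacts beyond Rician
noise, spatial intensity texture with class information (T2w voxels are
iid within tissue), or inter-scanner heterogeneity. Passing tests
therefore demonstrate that the *pipeline machinery* recovers a designed
diffusion contrast under realistic geometry, censoring and noise — not
that the published effect size would replicate on clinical data.

## Problem sizes used by the tests and scripts

The test suite runs the full pipeline on cohorts of 110 cases
(~270 regions) on a 48 × 48 × 20 grid across 20 seeds for the end-to-end
recovery property, a 150-case cohort for generator statistics, and
200 meta-replicates of n = 100 regions for bootstrap coverage; the
acceptance script runs one 160-case cohort (~300 regions) at the default
64 × 64 × 20 grid. These sizes were chosen so the distributional claims
under test (label frequencies within binomial bounds, median volumes
within 20%, coverage within ±4 points) are sharp at desk scale.

## Known limitations

* Only the L2-penalized logistic family is implemented; the l1/elasticnet
  arms of the hyperparameter domain are not searchable.
* The face-count surface area (hence Sphericity) carries the documented
  1.5× bias for round bodies.
* The mirror-boundary B-spline resampler is exact for smooth fields only
  away from image edges; regions near the field-of-view border would see
  boundary effects (none of the phantom regions do).
* Per-angle texture averaging and the level-count conventions are fixed
  choices; other radiomics software makes other choices, so absolute
  texture values are comparable only within this package.
* 26 of 153 features are near-degenerate at the default settings (ADC/fBV
  Entropy/Uniformity; shape features duplicated across ADC and fBV grids
  differ only via grid geometry), which is faithful to default-settings
  extraction but means the effective feature pool is smaller than 153.
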