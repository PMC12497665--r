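# cribromics

Region-level MRI radiomics for differentiating cribriform prostate cancer
growth.

Cribriform growth (GP4Crib+) is a Gleason pattern 4 sub-pattern associated
with adverse outcomes. Its densely cellular, sieve-like architecture
restricts water diffusion, so cribriform regions show lower apparent
diffusion coefficient (ADC) values than Gleason 3 or non-cribriform
Gleason 4 tissue. This package implements the full region-level analysis
that exploits that contrast:

1. **IVIM maps** — ADC and fractional blood volume (fBV) from a multi-b
   DWI stack by the segmented fit: OLS of ln S(b) on b over the
   200–800 s/mm² window gives ADC; fBV = 1 − e^A / S(0) from the
   intercept deficit; negative voxels clamped to zero.
2. **Region erosion** — co-registered histopathology region masks on the
   ADC grid lose their edge slices (delineation-uncertain) and are eroded
   in-plane with a disk removing one acquisition voxel; regions left with
   fewer than 2 voxels are dropped with reason codes.
3. **Radiomics** — 153 features per region: shape + first-order from ADC
   and fBV; shape + first-order + five texture families
   (GLCM/GLRLM/GLSZM/NGTDM/GLDM, 75 features) from z-score-normalized,
   resampled T2w.
4. **Model** — 60/20/20 class- and volume-balanced split; mRMR (MID)
   feature ranking capped at 20; feature count by stratified threefold
   cross-validated balanced accuracy; class-weighted L2 logistic
   regression P = 1/(1 + e^−(w₀ + Σ wᵢxᵢ)) at a 0.5 threshold.
5. **Evaluation** — balanced accuracy, ROC AUC, PR AUC, sensitivity,
   specificity with 1000-replicate percentile bootstrap CIs and a
   one-sided comparison against the all-negative baseline (balanced
   accuracy 0.5).

Because cohorts with whole-mount sub-pattern histology are not openly
available, the package includes a seeded phantom generator
(`phantom_spec()`, `generate_cohort()`) that emulates the cohort
structure — class mix, per-label volume medians, IVIM-form signal, Rician
noise — so every stage is testable end to end. See the methods vignette
(`vignettes/cribriform-radiomics-pipeline.Rmd`) for the models,
parameters, and what phantom results do and do not show.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # phantom cases as NIfTI + manifest
Rscript analysis/02_ivim_maps.R         # ADC / fBV maps per case
Rscript analysis/03_erode_extract.R     # erosion, filtering, 153 features
Rscript analysis/04_train_model.R       # split, mRMR, CV, logistic fit
Rscript analysis/05_evaluate.R          # bootstrap test-set report
```

On the 30-case demo cohort this prints, in order: the per-label ADC means
recovered by the segmented fit (1e-3 mm²/s, fitted vs truth —
GP3 1.202/1.201, GP4Crib- 1.043/1.051, GP4Crib+ 0.859/0.852: the
cribriform-lowest ordering survives fitting and noise); the erosion
census (57 regions in, 46 kept, 10 empty after erosion, 1 single-voxel);
the model choice — a **single** ADC first-order feature with a negative
coefficient:

```
Chosen feature count k = 1
Model: intercept 2.041
adc_firstorder_Mean
             -2.051
Single-feature model; decision boundary at 0.995
```

i.e. regions whose ADC summary falls below ~1.0 ×10⁻³ mm²/s are called
cribriform; and the test-set report:

```
Bootstrap metric report (n_boot = 1000 )
  balanced_accuracy  0.94  (95% CI 0.79-1.00)
  roc_auc            1.00  (95% CI 1.00-1.00)
  pr_auc             1.00  (95% CI 1.00-1.00)
  sensitivity        1.00  (95% CI 1.00-1.00)
  specificity        0.88  (95% CI 0.57-1.00)
  baseline delta     0.44  (one-sided p = 0.001)
```

The phantom's diffusion contrast is a designed synthetic effect, so these
metrics read as a machinery check (the pipeline finds the contrast it
should), not as clinical performance.

Programmatic use mirrors the scripts:

```r
library(cribromics)
cfg <- pipeline_config(phantom = phantom_spec(n_cases = 60, seed = 1),
                       n_boot = 1000, seed = 1)
res <- run_pipeline(cfg, out_dir = "results/run1")
res$ranking$features[1]   # top mRMR feature
res$model$coefficients
print(res$report)
```

## Conventions

Voxel indices are 1-based in R arrays; physical coordinates are
`origin + (index − 1) × spacing` in mm, axis-aligned (synthetic cases are
emitted co-registered). Volumes are NIfTI-1 (`.nii.gz`), b-values FSL
bval text, tables CSV, models/reports JSON, configuration YAML. ADC is
reported in 1e-3 mm²/s in feature tables and model coefficients.
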