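#!/usr/bin/env Rscript
# Apply the slice-aware cylindrical erosion to every region mask (edge
# slices removed, one acquisition voxel eroded in-plane), drop regions
# left with fewer than 2 voxels, and extract the 153-feature radiomics
# vector per surviving region (shape + first-order from ADC and fBV;
# shape + first-order + 5 texture families from normalized T2w).

suppressMessages(library(cribromics))
suppressMessages(library(data.table))

cohort_dir <- "results/cohort"
man <- fread(file.path(cohort_dir, "manifest.csv"))
es <- erosion_spec(acquisition_inplane_mm = 1.03, grid_inplane_mm = 1.03)
settings <- extraction_settings()

feat_rows <- list()
drop_rows <- list()
for (cid in unique(man$case_id)) {
  cdir <- file.path(cohort_dir, cid)
  adc <- read_volume_nifti(file.path(cdir, "adc.nii.gz"))
  fbv <- read_volume_nifti(file.path(cdir, "fbv.nii.gz"))
  t2w <- read_volume_nifti(file.path(cdir, "t2w.nii.gz"))
  regs <- lapply(which(man$case_id == cid), function(r) {
    mk <- read_volume_nifti(file.path(cdir, sprintf(
      "mask_r%s.nii.gz", sub(".*_r", "", man$region_id[r]))))
    region_mask(mk$data > 0.5, mk$spacing, mk$origin,
                label = man$label[r], region_id = man$region_id[r],
                case_id = cid)
  })
  eroded <- lapply(regs, erode_region, spec = es)
  flt <- filter_regions(eroded)
  drop_rows[[cid]] <- flt$dropped
  if (length(flt$kept))
    feat_rows[[cid]] <- extract_feature_table(flt$kept, adc, fbv, t2w,
                                              settings)
}
features <- rbindlist(feat_rows)
dropped <- rbindlist(drop_rows)
fwrite(features, "results/features.csv")
fwrite(dropped, "results/dropped_regions.csv")

cat("Regions in:", nrow(man), "| kept:", nrow(features),
    "| dropped:", nrow(dropped), "\n")
print(table(dropped$reason))
cat("\nErosion removes small regions preferentially; the surviving\n")
cat("class mix is:\n")
print(round(prop.table(table(features$label)), 2))
cat("\nFeature table written to results/features.csv (",
    ncol(features) - 4, "features per region)\n")
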