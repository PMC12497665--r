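#' Radiomics extraction settings
#'
#' Mirrors the extraction configuration used throughout the analysis:
#' T2w is z-score normalized (scale 100) and discretized with bin width 3
#' (chosen so most scans produce roughly 10-100 bins); the diffusion maps
#' are left in physical units and use the default bin width 25. All images
#' are resampled to the cohort median voxel size: 0.27 x 0.27 x 3 mm (T2w)
#' and 1.03 x 1.03 x 2.73 mm (ADC and fBV), image values by cubic B-spline,
#' masks by nearest neighbour. ADC first-order features are reported in
#' units of 1e-3 mm^2/s (the scale on which model coefficients and the
#' decision boundary are quoted).
#'
#' @param t2w_normalize normalize T2w (logical).
#' @param t2w_normalize_scale multiplier after standardisation.
#' @param t2w_bin_width bin width on normalized T2w intensities.
#' @param adc_fbv_bin_width bin width on ADC (1e-3 mm^2/s units) and fBV.
#' @param t2w_resample_mm,adc_fbv_resample_mm target spacings, mm.
#' @param geometry_tolerance spacing comparison tolerance, mm.
#' @return An `extraction_settings` list.
#' @export
extraction_settings <- function(t2w_normalize = TRUE,
                                t2w_normalize_scale = 100,
                                t2w_bin_width = 3,
                                adc_fbv_bin_width = 25,
                                t2w_resample_mm = c(0.27, 0.27, 3),
                                adc_fbv_resample_mm = c(1.03, 1.03, 2.73),
                                geometry_tolerance = 1e-4) {
  if (t2w_bin_width <= 0 || adc_fbv_bin_width <= 0)
    stop("bin widths must be > 0")
  if (any(t2w_resample_mm <= 0) || any(adc_fbv_resample_mm <= 0))
    stop("resample spacings must be > 0")
  structure(list(t2w_normalize = t2w_normalize,
                 t2w_normalize_scale = t2w_normalize_scale,
                 t2w_bin_width = t2w_bin_width,
                 adc_fbv_bin_width = adc_fbv_bin_width,
                 t2w_resample_mm = t2w_resample_mm,
                 adc_fbv_resample_mm = adc_fbv_resample_mm,
                 geometry_tolerance = geometry_tolerance),
            class = "extraction_settings")
}

crop_to_mask <- function(values, mask_voxels) {
  # region bounding box, values NA outside the region
  idx <- which(mask_voxels, arr.ind = TRUE)
  rng <- lapply(1:3, function(a) min(idx[, a]):max(idx[, a]))
  v <- values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  m <- mask_voxels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  dim(v) <- dim(m) <- vapply(rng, length, 0L)
  v[!m] <- NA
  v
}

map_feature_block <- function(image, mask, bin_width, with_texture,
                              tolerance = 1e-4) {
  if (!same_geometry(image, mask, tolerance))
    stop("image and mask geometries differ beyond tolerance")
  if (sum(mask$voxels) < 2) stop("region has fewer than 2 voxels")
  vals <- image$data[mask$voxels]
  fo <- first_order_features(vals, bin_width,
                             voxel_volume = prod(image$spacing))
  sh <- shape_features(mask)
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(sh, paste0("shape_", names(sh))))
  if (with_texture) {
    cropped <- crop_to_mask(image$data, mask$voxels)
    disc <- discretize_fixed_bin_width(cropped[!is.na(cropped)], bin_width)
    lev <- cropped
    lev[!is.na(lev)] <- disc$gray_levels
    storage.mode(lev) <- "integer"
    out <- c(out, texture_features(lev, disc$n_levels))
  }
  out
}

#' Extract the full radiomics vector for one region
#'
#' From the ADC and fBV maps: 19 first-order + 7 shape features each (the
#' diffusion maps' lower resolution does not support texture). From the
#' normalized, resampled T2w image: 19 first-order + 7 shape + 75 texture
#' features. 153 features per region, named `<map>_<family>_<feature>`.
#' ADC intensities enter in units of 1e-3 mm^2/s.
#'
#' @param region a post-filter [region_mask()] on the ADC grid.
#' @param adc,fbv [volume_grid()] parameter maps (ADC in mm^2/s).
#' @param t2w the raw T2w [volume_grid()].
#' @param settings an [extraction_settings()].
#' @return named numeric vector of 153 features.
#' @export
extract_region_features <- function(region, adc, fbv, t2w,
                                    settings = extraction_settings()) {
  prep <- prepare_extraction_images(adc, fbv, t2w, settings)
  extract_region_features_prepared(region, prep, settings)
}

# normalize / resample the per-case images once, not per region
prepare_extraction_images <- function(adc, fbv, t2w, settings) {
  adc_r <- resample_image(adc, settings$adc_fbv_resample_mm)
  adc_r$data <- adc_r$data * 1000               # 1e-3 mm^2/s units
  fbv_r <- resample_image(fbv, settings$adc_fbv_resample_mm)
  t2 <- t2w
  if (settings$t2w_normalize)
    t2 <- znormalize_image(t2, settings$t2w_normalize_scale)
  t2 <- resample_image(t2, settings$t2w_resample_mm)
  list(adc = adc_r, fbv = fbv_r, t2w = t2)
}

extract_region_features_prepared <- function(region, prep, settings) {
  stopifnot(inherits(settings, "extraction_settings"))
  tol <- settings$geometry_tolerance
  mask_d <- if (same_geometry(region, prep$adc, tol)) region else
    resample_mask_to_grid(region, prep$adc)
  if (sum(mask_d$voxels) < 2)
    stop(sprintf("region %s: fewer than 2 voxels on the diffusion grid",
                 region$region_id))
  f_adc <- map_feature_block(prep$adc, mask_d, settings$adc_fbv_bin_width,
                             with_texture = FALSE, tol)
  f_fbv <- map_feature_block(prep$fbv, mask_d, settings$adc_fbv_bin_width,
                             with_texture = FALSE, tol)
  mask_t <- resample_mask_to_grid(region, prep$t2w)
  if (sum(mask_t$voxels) < 2)
    stop(sprintf("region %s: fewer than 2 voxels on the T2w grid",
                 region$region_id))
  f_t2 <- map_feature_block(prep$t2w, mask_t, settings$t2w_bin_width,
                            with_texture = TRUE, tol)
  c(stats::setNames(f_adc, paste0("adc_", names(f_adc))),
    stats::setNames(f_fbv, paste0("fbv_", names(f_fbv))),
    stats::setNames(f_t2, paste0("t2w_", names(f_t2))))
}

#' Extract the feature table for a list of regions
#'
#' @param regions list of [region_mask()] (post [filter_regions()]).
#' @param adc,fbv,t2w as in [extract_region_features()].
#' @param settings an [extraction_settings()].
#' @return data.table: case_id, region_id, label, volume_cc + 153 feature
#'   columns in stable order.
#' @export
extract_feature_table <- function(regions, adc, fbv, t2w,
                                  settings = extraction_settings()) {
  prep <- prepare_extraction_images(adc, fbv, t2w, settings)
  rows <- lapply(regions, function(r) {
    f <- extract_region_features_prepared(r, prep, settings)
    c(list(case_id = r$case_id, region_id = r$region_id, label = r$label,
           volume_cc = r$volume_cc), as.list(f))
  })
  data.table::rbindlist(rows)
}
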