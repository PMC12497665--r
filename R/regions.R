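#' Erosion specification
#'
#' The erosion radius is chosen so that one acquisition voxel is removed
#' isotropically in-plane: `radius_voxels = ceiling(acquisition_inplane_mm /
#' grid_inplane_mm)`, at least 1. Keeping both spacings explicit records
#' whether the radius derives from the native acquisition voxel or the
#' resampled grid voxel.
#'
#' @param acquisition_inplane_mm native acquisition in-plane voxel size, mm.
#' @param grid_inplane_mm in-plane voxel size of the (ADC) grid the mask
#'   lives on, mm.
#' @return An `erosion_spec` with derived integer `radius_voxels`.
#' @export
erosion_spec <- function(acquisition_inplane_mm = 1.03,
                         grid_inplane_mm = 1.03) {
  if (acquisition_inplane_mm <= 0 || grid_inplane_mm <= 0)
    stop("spacings must be positive")
  r <- max(1L, as.integer(ceiling(acquisition_inplane_mm / grid_inplane_mm)))
  structure(list(acquisition_inplane_mm = acquisition_inplane_mm,
                 grid_inplane_mm = grid_inplane_mm,
                 radius_voxels = r),
            class = "erosion_spec")
}

target_geometry <- function(target) {
  if (inherits(target, "volume_grid"))
    list(dim = dim(target$data), spacing = target$spacing,
         origin = target$origin)
  else if (is.list(target) && all(c("dim", "spacing") %in% names(target)))
    list(dim = as.integer(target$dim), spacing = as.numeric(target$spacing),
         origin = as.numeric(target$origin %||% c(0, 0, 0)))
  else stop("target must be a volume_grid or a list(dim, spacing, origin)")
}

#' Resample a region mask onto another grid (nearest neighbour)
#'
#' Each target voxel takes the value of the source voxel whose centre is
#' nearest to it (per-axis nearest centre, ties toward the higher index).
#' Used when the segmentation mask and the feature image do not share a
#' grid, e.g. DWI-grid masks transferred to the T2w grid.
#'
#' @param mask a [region_mask()].
#' @param target a [volume_grid()] or `list(dim, spacing, origin)`.
#' @return A [region_mask()] on the target grid; may be empty (with a
#'   warning).
#' @export
resample_mask_to_grid <- function(mask, target) {
  tg <- target_geometry(target)
  src_lo <- mask$origin - mask$spacing / 2
  src_hi <- mask$origin + (dim(mask$voxels) - 0.5) * mask$spacing
  tgt_lo <- tg$origin - tg$spacing / 2
  tgt_hi <- tg$origin + (tg$dim - 0.5) * tg$spacing
  if (any(src_hi < tgt_lo) || any(tgt_hi < src_lo))
    stop("source and target grids have disjoint physical extents")

  idx <- lapply(1:3, function(a) {
    tx <- tg$origin[a] + (seq_len(tg$dim[a]) - 1) * tg$spacing[a]
    floor((tx - mask$origin[a]) / mask$spacing[a] + 0.5) + 1
  })
  out <- array(FALSE, tg$dim)
  occ <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(occ) > 0) {
    # gather only the target block whose nearest source voxels can be set
    bb_lo <- apply(occ, 2, min)
    bb_hi <- apply(occ, 2, max)
    tr <- lapply(1:3, function(a)
      which(idx[[a]] >= bb_lo[a] & idx[[a]] <= bb_hi[a]))
    if (all(lengths(tr) > 0))
      out[tr[[1]], tr[[2]], tr[[3]]] <-
        mask$voxels[idx[[1]][tr[[1]]], idx[[2]][tr[[2]]], idx[[3]][tr[[3]]],
                    drop = FALSE]
  }
  res <- region_mask(out, tg$spacing, tg$origin, label = mask$label,
                     region_id = mask$region_id, case_id = mask$case_id)
  if (sum(res$voxels) == 0)
    warning(sprintf("region %s is empty after resampling", mask$region_id))
  res
}

# in-plane disk offsets (di, dj) with di^2 + dj^2 <= r^2
disk_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
}

shift2d <- function(m, di, dj) {
  # shift a logical matrix, padding with FALSE
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(FALSE, n1, n2)
  i1 <- max(1, 1 + di); i2 <- min(n1, n1 + di)
  j1 <- max(1, 1 + dj); j2 <- min(n2, n2 + dj)
  if (i1 <= i2 && j1 <= j2)
    out[i1:i2, j1:j2] <- m[(i1:i2) - di, (j1:j2) - dj, drop = FALSE]
  out
}

#' Slice-aware cylindrical erosion of a region mask
#'
#' Mitigates histology-to-MRI co-registration and partial-volume
#' uncertainty at region boundaries: (i) slices that do not have an
#' occupied slice both directly above and directly below (judged on the
#' region's own occupancy) are removed entirely — edge slices are the most
#' delineation-uncertain; (ii) every remaining slice is eroded in 2D with a
#' disk structuring element: voxel (i, j) survives iff every in-plane voxel
#' within Euclidean distance `radius_voxels * grid_inplane_mm` of it was
#' set. The result may be empty.
#'
#' @param mask a [region_mask()] on the ADC grid.
#' @param spec an [erosion_spec()].
#' @return the eroded [region_mask()].
#' @export
erode_region <- function(mask, spec) {
  stopifnot(inherits(mask, "region_mask"), inherits(spec, "erosion_spec"))
  if (abs(mask$spacing[1] - mask$spacing[2]) > 1e-6)
    stop("erosion assumes isotropic in-plane spacing")
  if (abs(mask$spacing[1] - spec$grid_inplane_mm) > 1e-6)
    stop("mask is not on the grid the erosion spec was derived for")
  v <- mask$voxels
  nz <- dim(v)[3]
  occ <- apply(v, 3, any)
  keep <- occ
  for (z in seq_len(nz)) {
    has_up <- z < nz && occ[z + 1]
    has_dn <- z > 1 && occ[z - 1]
    keep[z] <- occ[z] && has_up && has_dn
  }
  out <- array(FALSE, dim(v))
  offs <- disk_offsets(spec$radius_voxels)
  for (z in which(keep)) {
    sl <- v[, , z]
    er <- sl
    for (o in seq_len(nrow(offs))) {
      er <- er & shift2d(sl, offs$di[o], offs$dj[o])
      if (!any(er)) break
    }
    out[, , z] <- er
  }
  region_mask(out, mask$spacing, mask$origin, label = mask$label,
              region_id = mask$region_id, case_id = mask$case_id)
}

#' Filter post-erosion regions by voxel count
#'
#' Radiomics extraction needs at least 2 voxels: empty regions (nothing
#' survived erosion) and single-voxel regions are dropped with a reason
#' code.
#'
#' @param regions list of [region_mask()].
#' @return list with `kept` (list of masks) and `dropped` (data.table:
#'   region_id, label, reason).
#' @export
filter_regions <- function(regions) {
  nv <- vapply(regions, function(m) sum(m$voxels), 0L)
  reason <- ifelse(nv == 0, "empty_after_erosion",
                   ifelse(nv == 1, "single_voxel", NA_character_))
  drop <- !is.na(reason)
  dropped <- data.table::data.table(
    region_id = vapply(regions[drop], `[[`, "", "region_id"),
    label = vapply(regions[drop], `[[`, "", "label"),
    reason = reason[drop])
  list(kept = regions[!drop], dropped = dropped)
}
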