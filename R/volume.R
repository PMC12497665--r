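#' 3D scalar volume with voxel-spacing metadata
#'
#' `volume_grid` is the carrier for every image in the pipeline (T2w, DWI
#' channels, ADC, fBV, ground-truth maps). It is a plain 3D numeric array
#' plus an axis-aligned geometry: voxel spacing and the physical position of
#' the centre of voxel (1,1,1), both in mm. Voxel (i,j,k) sits at
#' `origin + (c(i,j,k) - 1) * spacing`. Oblique orientations are out of
#' scope: synthetic cases are emitted co-registered and axis-aligned.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3 voxel size in mm, all > 0.
#' @param origin numeric length-3 physical position (mm) of the first voxel
#'   centre.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param grid a `volume_grid` or `region_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data %||% a$voxels), dim(b$data %||% b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Labeled binary region mask tied to a grid geometry
#'
#' A single delineated histopathology region carried on an image grid:
#' binary voxel occupancy, the geometry it lives on, its Gleason-pattern
#' label and provenance identifiers. `volume_cc` is always derived from the
#' current voxel count (1 cc = 1000 mm^3).
#'
#' @param voxels logical 3D array of region occupancy.
#' @param spacing,origin geometry in mm, as for [volume_grid()].
#' @param label Gleason pattern: one of `"GP3"`, `"GP4Crib-"`, `"GP4Crib+"`,
#'   or `"prostate"` for whole-gland support masks.
#' @param region_id,case_id provenance strings.
#' @return A `region_mask` object with derived field `volume_cc`.
#' @export
region_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                        label = "GP3", region_id = "r1", case_id = "c1") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "logical"
  voxels[is.na(voxels)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  labels_ok <- c("GP3", "GP4Crib-", "GP4Crib+", "benign", "prostate")
  if (!label %in% labels_ok)
    stop("unknown region label: ", label)
  m <- structure(list(voxels = voxels, spacing = spacing,
                      origin = as.numeric(origin), label = label,
                      region_id = region_id, case_id = case_id),
                 class = "region_mask")
  m$volume_cc <- mask_volume_cc(m)
  m
}

#' @rdname region_mask
#' @param mask a `region_mask`.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %s %s/%s: %d voxels, %.4g cc>\n",
              x$label, x$case_id, x$region_id, sum(x$voxels), x$volume_cc))
  invisible(x)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti keeping the pipeline's axis-aligned geometry
#' convention (spacing in pixdim, origin via the sform translation).
#'
#' @param grid a `volume_grid`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns a `volume_grid`.
#' @export
write_volume_nifti <- function(grid, path) {
  img <- RNifti::asNifti(grid$data)
  xf <- diag(c(grid$spacing, 1))
  xf[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3],
              origin = xf[1:3, 4])
}
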