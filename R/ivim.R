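#' Multi-b diffusion-weighted stack
#'
#' @param volumes named list of [volume_grid()], names are b-values in
#'   s/mm^2; must share geometry, contain b = 0 and at least two b-values
#'   >= 200 (the ADC fit window).
#' @param mask optional [region_mask()] restricting the fit support
#'   (typically the prostate).
#' @return A `dwi_stack`.
#' @export
dwi_stack <- function(volumes, mask = NULL) {
  b <- as.numeric(names(volumes))
  if (any(is.na(b))) stop("volume names must be numeric b-values")
  if (!0 %in% b) stop("stack must contain b = 0")
  if (sum(b >= 200 & b <= 800) < 2)
    stop("stack must contain at least two b-values in [200, 800] s/mm^2")
  for (v in volumes)
    if (!same_geometry(v, volumes[[1]]))
      stop("all DWI volumes must share geometry")
  if (!is.null(mask) && !same_geometry(mask, volumes[[1]]))
    stop("mask must share the DWI geometry")
  structure(list(volumes = volumes[order(b)], mask = mask),
            class = "dwi_stack")
}

#' Read a DWI stack from a 4D NIfTI plus a b-value sidecar
#'
#' The sidecar is a plain text file of b-values (FSL bval dialect:
#' whitespace- or newline-separated, one value per DWI channel).
#'
#' @param dwi_path 4D NIfTI file.
#' @param bval_path text file of b-values.
#' @return A [dwi_stack()].
#' @export
read_dwi_stack <- function(dwi_path, bval_path) {
  img <- RNifti::readNifti(dwi_path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI, got ", length(d), "D")
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (length(b) != d[4])
    stop(sprintf("bval count (%d) does not match DWI channels (%d)",
                 length(b), d[4]))
  sp <- RNifti::pixdim(img)[1:3]
  org <- RNifti::xform(img)[1:3, 4]
  vols <- lapply(seq_len(d[4]), function(k)
    volume_grid(array(as.numeric(img[, , , k]), d[1:3]), sp, org))
  names(vols) <- as.character(b)
  dwi_stack(vols)
}

#' Segmented IVIM fit: ADC and fractional blood volume maps
#'
#' Per voxel: (i) ordinary least squares of `ln S(b)` on `b`, restricted to
#' the high-b window 200-800 s/mm^2 (boundaries inclusive), gives slope
#' `-D` and intercept `A`; the ADC is `D`. (ii) The perfusion fraction is
#' estimated from the intercept deficit, `fBV = 1 - exp(A) / S(0)`, using
#' the measured b = 0 signal. Voxels with a non-positive signal at b = 0 or
#' anywhere in the fit window are flagged and set to ADC = 0, fBV = 0
#' rather than fitted. Negative fitted values are clamped to zero and fBV is
#' capped at 1 ([clamp_nonphysical()]), as they lack physical significance.
#'
#' @param stack a [dwi_stack()].
#' @param b_window inclusive ADC fit window in s/mm^2.
#' @return A `parameter_maps` list: `adc` and `fbv` [volume_grid()]s and
#'   `fit_log`, an integer array of per-voxel flags (0 = fitted,
#'   1 = non-positive signal, 2 = outside mask).
#' @export
fit_segmented_ivim <- function(stack, b_window = c(200, 800)) {
  stopifnot(inherits(stack, "dwi_stack"))
  b <- as.numeric(names(stack$volumes))
  sel <- b >= b_window[1] & b <= b_window[2]
  if (sum(sel) < 2)
    stop("fewer than 2 usable b-values in the fit window")
  g0 <- stack$volumes[[which(b == 0)]]
  dims <- dim(g0$data)
  bs <- b[sel]
  S <- lapply(stack$volumes[sel], function(v) v$data)

  support <- if (!is.null(stack$mask)) stack$mask$voxels else
    array(TRUE, dims)
  bad <- g0$data <= 0
  for (s in S) bad <- bad | (s <= 0)

  fit <- support & !bad
  n <- length(bs)
  bbar <- mean(bs)
  sxx <- sum((bs - bbar)^2)
  # vectorised OLS over all fitted voxels
  ybar <- array(0, dims)
  sxy <- array(0, dims)
  logS <- vector("list", n)
  for (k in seq_len(n)) {
    lk <- array(0, dims)
    lk[fit] <- log(S[[k]][fit])
    logS[[k]] <- lk
    ybar <- ybar + lk
  }
  ybar <- ybar / n
  for (k in seq_len(n)) sxy <- sxy + (bs[k] - bbar) * (logS[[k]] - ybar)
  slope <- sxy / sxx
  A <- ybar - slope * bbar

  adc <- array(0, dims)
  fbv <- array(0, dims)
  adc[fit] <- -slope[fit]
  fbv[fit] <- 1 - exp(A[fit]) / g0$data[fit]

  flags <- array(0L, dims)
  flags[support & bad] <- 1L
  flags[!support] <- 2L

  maps <- structure(list(adc = volume_grid(adc, g0$spacing, g0$origin),
                         fbv = volume_grid(fbv, g0$spacing, g0$origin),
                         fit_log = flags),
                    class = "parameter_maps")
  clamp_nonphysical(maps)
}

#' Clamp non-physical map values
#'
#' Negative ADC and fBV voxels are set to exactly 0; fBV is additionally
#' capped at 1. Idempotent.
#'
#' @param maps a `parameter_maps` object.
#' @return the clamped `parameter_maps`.
#' @export
clamp_nonphysical <- function(maps) {
  stopifnot(inherits(maps, "parameter_maps"))
  maps$adc$data[maps$adc$data < 0] <- 0
  maps$fbv$data[maps$fbv$data < 0] <- 0
  maps$fbv$data[maps$fbv$data > 1] <- 1
  maps
}
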