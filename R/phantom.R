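#' IVIM forward signal model
#'
#' Biexponential intravoxel incoherent motion signal
#' `S(b) = S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))`,
#' mixing perfusion-driven pseudo-diffusion (fraction `f`, coefficient
#' `Dstar`) with tissue diffusion `D`. All diffusivities in mm^2/s, `b` in
#' s/mm^2. Vectorised over any argument.
#'
#' @param S0 nonnegative signal at b = 0.
#' @param b diffusion weighting, s/mm^2, >= 0.
#' @param D tissue diffusion coefficient, mm^2/s, >= 0.
#' @param Dstar pseudo-diffusion coefficient, mm^2/s, >= D.
#' @param f perfusion fraction in [0, 1].
#' @return signal, same shape as the broadcast arguments; nonnegative and
#'   non-increasing in `b`.
#' @export
ivim_signal <- function(S0, b, D, Dstar, f) {
  if (any(S0 < 0)) stop("S0 must be >= 0")
  if (any(b < 0)) stop("b must be >= 0")
  if (any(D < 0)) stop("D must be >= 0")
  if (any(f < 0 | f > 1)) stop("f must be in [0, 1]")
  if (any(Dstar < D)) stop("Dstar must be >= D")
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

#' DWI acquisition protocol for the phantom generator
#'
#' @param b_values ascending diffusion weightings in s/mm^2; must contain 0
#'   and at least two values >= 200 (the ADC fit window).
#' @param dwi_spacing,t2w_spacing voxel sizes in mm.
#' @param noise_sigma Gaussian channel noise level used for Rician
#'   corruption of DWI magnitudes (same arbitrary units as S0).
#' @param field_label free-text scanner field strength.
#' @return An `acquisition_protocol` list.
#' @export
acquisition_protocol <- function(b_values = c(0, 200, 800),
                                 dwi_spacing = c(1.03, 1.03, 2.73),
                                 t2w_spacing = c(0.27, 0.27, 3),
                                 noise_sigma = 5,
                                 field_label = "3T") {
  b_values <- as.numeric(b_values)
  if (is.unsorted(b_values, strictly = TRUE))
    stop("b_values must be strictly ascending")
  if (!0 %in% b_values) stop("b_values must contain 0")
  if (sum(b_values >= 200) < 2)
    stop("b_values must contain at least two values >= 200 s/mm^2")
  if (any(dwi_spacing <= 0) || any(t2w_spacing <= 0))
    stop("spacings must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(b_values = b_values,
                 dwi_spacing = as.numeric(dwi_spacing),
                 t2w_spacing = as.numeric(t2w_spacing),
                 noise_sigma = noise_sigma, field_label = field_label),
            class = "acquisition_protocol")
}

#' Per-class tissue parameter distributions
#'
#' Voxelwise generative distributions for one tissue class. The diffusion
#' contrast between classes (cribriform lowest) reproduces, qualitatively,
#' the lower water diffusion of densely cellular cribriform growth; the
#' numeric values are synthetic stand-ins, not calibrated measurements.
#'
#' @param label tissue class.
#' @param D_mean,D_sd diffusion coefficient distribution, mm^2/s.
#' @param f_mean,f_sd perfusion-fraction distribution, unitless in [0, 1).
#' @param Dstar_mean pseudo-diffusion coefficient, mm^2/s, > D_mean.
#' @param t2w_mean,t2w_sd T2w intensity distribution (arbitrary units).
#' @param volume_median_cc target median region volume in cc.
#' @return A `tissue_class_params` list.
#' @export
tissue_class_params <- function(label, D_mean, D_sd = 0.10e-3,
                                f_mean = 0.08, f_sd = 0.02,
                                Dstar_mean = 20e-3,
                                t2w_mean = 300, t2w_sd = 30,
                                volume_median_cc = 0.15) {
  if (D_mean <= 0) stop("D_mean must be > 0")
  if (f_mean < 0 || f_mean >= 1) stop("f_mean must be in [0, 1)")
  if (Dstar_mean <= D_mean) stop("Dstar_mean must exceed D_mean")
  if (volume_median_cc <= 0) stop("volume_median_cc must be > 0")
  structure(list(label = label, D_mean = D_mean, D_sd = D_sd,
                 f_mean = f_mean, f_sd = f_sd, Dstar_mean = Dstar_mean,
                 t2w_mean = t2w_mean, t2w_sd = t2w_sd,
                 volume_median_cc = volume_median_cc),
            class = "tissue_class_params")
}

#' Default tissue parameters for the phantom cohort
#'
#' Diffusion means are ordered GP4Crib+ < GP4Crib- < GP3 < benign, the
#' qualitative ordering reported for cribriform growth; T2w means are equal
#' across the three cancer classes so that, as in the source cohort, the
#' diffusion maps carry the discriminative signal. Median region volumes
#' follow the cohort's per-class medians (0.16 / 0.20 / 0.08 cc).
#'
#' @return named list of [tissue_class_params()] keyed by label.
#' @export
default_tissue_params <- function() {
  list(
    "GP3"      = tissue_class_params("GP3",      D_mean = 1.20e-3,
                                     f_mean = 0.07, volume_median_cc = 0.16),
    "GP4Crib-" = tissue_class_params("GP4Crib-", D_mean = 1.05e-3,
                                     f_mean = 0.08, volume_median_cc = 0.20),
    "GP4Crib+" = tissue_class_params("GP4Crib+", D_mean = 0.85e-3,
                                     f_mean = 0.10, volume_median_cc = 0.08),
    "benign"   = tissue_class_params("benign",   D_mean = 1.60e-3,
                                     f_mean = 0.05, t2w_mean = 400,
                                     volume_median_cc = 1)
  )
}

#' Specification of a synthetic phantom cohort
#'
#' Defines the study conditions the generator emulates: the pre-erosion
#' class mix (45/40/15, which erosion thins towards roughly 52/38/10 because
#' small cribriform regions are removed preferentially), region multiplicity
#' per case, the acquisition protocol and tissue contrast, and a master seed
#' from which per-case streams are derived.
#'
#' @param n_cases number of phantom cases (>= 1).
#' @param class_proportions named fractions over the three Gleason labels,
#'   summing to 1.
#' @param regions_per_case named probabilities for 1, 2 or 3 regions per
#'   case.
#' @param protocol an [acquisition_protocol()].
#' @param tissue_params named list of [tissue_class_params()]; must cover
#'   `benign` and every label in `class_proportions`.
#' @param seed master random seed (integer).
#' @param grid_dim DWI grid dimension.
#' @param volume_sdlog log-sd of the log-normal region-volume draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_cases = 160,
                         class_proportions = c("GP3" = 0.45,
                                               "GP4Crib-" = 0.40,
                                               "GP4Crib+" = 0.15),
                         regions_per_case = c("1" = 0.4, "2" = 0.3,
                                              "3" = 0.3),
                         protocol = acquisition_protocol(),
                         tissue_params = default_tissue_params(),
                         seed = 1L,
                         grid_dim = c(64, 64, 20),
                         volume_sdlog = 0.8) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  if (abs(sum(regions_per_case) - 1) > 1e-8)
    stop("regions_per_case must sum to 1")
  need <- c(names(class_proportions), "benign")
  if (!all(need %in% names(tissue_params)))
    stop("tissue_params must cover: ", paste(need, collapse = ", "))
  structure(list(n_cases = as.integer(n_cases),
                 class_proportions = class_proportions,
                 regions_per_case = regions_per_case,
                 protocol = protocol, tissue_params = tissue_params,
                 seed = as.integer(seed),
                 grid_dim = as.integer(grid_dim),
                 volume_sdlog = volume_sdlog),
            class = "phantom_spec")
}

# Derive a per-case RNG seed from (master seed, case index); keeps all seeds
# in 32-bit integer range and makes each case independently reproducible.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 +
               as.numeric(index) * 7919 + 17) %% 2147483647L
}

# Voxel-centre coordinate grids (mm) for an axis-aligned geometry.
coord_axes <- function(dim, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * spacing[a])
}

# the prostate ellipsoid raster depends only on the grid geometry, so it is
# shared across all cases of a cohort
.raster_cache <- new.env(parent = emptyenv())

rasterize_cached <- function(dim, spacing, centre, a, b, cz) {
  key <- paste(c(dim, round(spacing, 6), round(centre, 6), a, b, cz),
               collapse = "|")
  hit <- .raster_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- rasterize_ellipsoid(dim, spacing, c(0, 0, 0), centre, a, b, cz)
  .raster_cache[[key]] <- out
  out
}

# Rasterize an in-plane-rotated, z-aligned ellipsoid onto a grid.
# centre in mm; semi-axes (a, b) in-plane and c along z, in mm; theta in rad.
rasterize_ellipsoid <- function(dim, spacing, origin, centre, a, b, cz,
                                theta = 0) {
  ax <- coord_axes(dim, spacing, origin)
  dx <- ax[[1]] - centre[1]
  dy <- ax[[2]] - centre[2]
  dz <- ax[[3]] - centre[3]
  ct <- cos(theta); st <- sin(theta)
  # separable over z: in-plane quadratic form evaluated once
  u <- outer(dx, dy, function(x, y) ((ct * x + st * y) / a)^2 +
               ((-st * x + ct * y) / b)^2)
  out <- array(FALSE, dim)
  for (k in seq_len(dim[3])) {
    r2 <- 1 - (dz[k] / cz)^2
    if (r2 > 0) out[, , k] <- u <= r2
  }
  out
}

rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_index)`. Builds a prostate
#' ellipsoid on the DWI grid, places 1-3 connected ellipsoidal cancer
#' regions inside it (volumes log-normal around each label's median, flat
#' along z so that most regions span 3+ slices, as whole-mount histology
#' regions do), samples voxelwise D / f / T2w fields per tissue class,
#' evaluates the IVIM signal at each b-value and corrupts the magnitudes
#' with Rician noise. Ground-truth maps store the sampled D (as ADC) and f
#' (as fBV).
#'
#' @param spec a [phantom_spec()].
#' @param case_index 1-based case number, <= `spec$n_cases`.
#' @return A `phantom_case` list: `case_id`, `t2w`, `dwi` (named list of
#'   [volume_grid()] per b-value), `truth_adc`, `truth_fbv`,
#'   `prostate_mask`, `regions` (list of [region_mask()]).
#' @export
generate_phantom_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (case_index < 1 || case_index > spec$n_cases)
    stop("case_index out of range")
  case_id <- sprintf("case%04d", case_index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, case_index))

  dimv <- spec$grid_dim
  sp <- spec$protocol$dwi_spacing
  extent <- dimv * sp
  centre <- extent / 2

  # prostate: fixed ellipsoid, ~44 cc, comfortably inside the FOV
  pr_ax <- c(24, 20, 22)
  prostate <- rasterize_cached(dimv, sp, centre, pr_ax[1], pr_ax[2],
                               pr_ax[3])

  # benign background property fields
  nvox <- prod(dimv)
  tp <- spec$tissue_params
  bp <- tp[["benign"]]
  D <- array(pmax(stats::rnorm(nvox, bp$D_mean, bp$D_sd), 0.05e-3), dimv)
  f <- array(pmin(pmax(stats::rnorm(nvox, bp$f_mean, bp$f_sd), 0), 0.5), dimv)
  Dstar <- array(bp$Dstar_mean, dimv)

  n_regions <- sample(as.integer(names(spec$regions_per_case)), 1,
                      prob = spec$regions_per_case)
  labels <- sample(names(spec$class_proportions), n_regions, replace = TRUE,
                   prob = spec$class_proportions)
  regions <- vector("list", n_regions)
  occupied <- array(FALSE, dimv)
  for (r in seq_len(n_regions)) {
    cp <- tp[[labels[r]]]
    vol_mm3 <- 1000 * stats::rlnorm(1, log(cp$volume_median_cc),
                                    spec$volume_sdlog)
    cz <- stats::runif(1, 4.5, 9)                  # z semi-axis, mm
    q <- stats::runif(1, 0.6, 1)                   # in-plane aspect ratio
    a <- sqrt(3 * vol_mm3 / (4 * pi * cz * q))
    b2 <- q * a
    theta <- stats::runif(1, 0, pi)
    placed <- FALSE
    for (try in 1:50) {
      # centre within a shrunken prostate so the blob stays inside
      u <- stats::runif(3, -0.6, 0.6)
      ctr <- centre + u * pr_ax
      vox <- rasterize_ellipsoid(dimv, sp, c(0, 0, 0), ctr, a, b2, cz, theta)
      vox <- vox & prostate
      if (sum(vox) == 0) {       # sub-voxel region: keep the centre voxel
        idx <- pmin(pmax(round(ctr / sp + 0.5), 1), dimv)
        if (prostate[idx[1], idx[2], idx[3]]) {
          vox[idx[1], idx[2], idx[3]] <- TRUE
        }
      }
      if (sum(vox) > 0 && sum(vox & occupied) == 0) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place region %d of %s inside the prostate",
                   r, case_id))
    occupied <- occupied | vox
    nv <- sum(vox)
    D[vox] <- pmax(stats::rnorm(nv, cp$D_mean, cp$D_sd), 0.05e-3)
    f[vox] <- pmin(pmax(stats::rnorm(nv, cp$f_mean, cp$f_sd), 0), 0.5)
    Dstar[vox] <- cp$Dstar_mean
    regions[[r]] <- region_mask(vox, sp, c(0, 0, 0), label = labels[r],
                                region_id = sprintf("%s_r%d", case_id, r),
                                case_id = case_id)
  }

  # DWI stack: IVIM forward model + Rician noise
  S0 <- array(stats::rnorm(nvox, 100, 3), dimv)
  S0[S0 < 1] <- 1
  sigma <- spec$protocol$noise_sigma
  dwi <- lapply(spec$protocol$b_values, function(b) {
    s <- ivim_signal(S0, b, D, Dstar, f)
    volume_grid(array(rician(s, sigma), dimv), sp)
  })
  names(dwi) <- as.character(spec$protocol$b_values)

  # T2w on its own (finer) grid; tissue membership is transferred from the
  # DWI grid by nearest neighbour so the two grids stay consistent
  t2sp <- spec$protocol$t2w_spacing
  t2dim <- pmax(floor(extent / t2sp), 1)
  t2lab <- array(0L, t2dim)                      # 0 = outside prostate
  pr2 <- rasterize_cached(t2dim, t2sp, centre, pr_ax[1], pr_ax[2],
                          pr_ax[3])
  t2lab[pr2] <- 1L                               # benign gland
  for (r in seq_len(n_regions)) {
    rm2 <- resample_mask_to_grid(regions[[r]],
                                 list(dim = t2dim, spacing = t2sp,
                                      origin = c(0, 0, 0)))
    t2lab[rm2$voxels] <- 1L + r
  }
  mu_tab <- c(150, tp[["benign"]]$t2w_mean,
              vapply(labels, function(l) tp[[l]]$t2w_mean, 0))
  sd_tab <- c(20, tp[["benign"]]$t2w_sd,
              vapply(labels, function(l) tp[[l]]$t2w_sd, 0))
  code <- t2lab + 1L
  t2 <- mu_tab[code] + sd_tab[code] * stats::rnorm(prod(t2dim))
  dim(t2) <- t2dim

  list(case_id = case_id,
       t2w = volume_grid(t2, t2sp),
       dwi = dwi,
       truth_adc = volume_grid(D, sp),
       truth_fbv = volume_grid(f, sp),
       prostate_mask = region_mask(prostate, sp, label = "prostate",
                                   region_id = "prostate", case_id = case_id),
       regions = regions)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a phantom cohort with manifest
#'
#' Runs [generate_phantom_case()] over all cases. With `out_dir` set, every
#' volume is written as NIfTI-1 (`.nii.gz`), the manifest as CSV and the
#' cohort parameters as YAML; with `keep_cases = FALSE` the volumes are
#' dropped after writing so arbitrarily large cohorts fit in memory.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir optional output directory.
#' @param keep_cases keep the generated cases in the return value.
#' @return list with `manifest` (data.table: case_id, region_id, label,
#'   volume_cc, n_voxels, paths) and `cases` (list or NULL).
#' @export
generate_cohort <- function(spec, out_dir = NULL, keep_cases = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok || file.access(out_dir, 2) != 0)
      stop("output directory is not writable: ", out_dir)
  }
  rows <- vector("list", spec$n_cases)
  cases <- if (keep_cases) vector("list", spec$n_cases) else NULL
  for (i in seq_len(spec$n_cases)) {
    cs <- generate_phantom_case(spec, i)
    paths <- NA_character_
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, cs$case_id)
      dir.create(cdir, showWarnings = FALSE)
      write_volume_nifti(cs$t2w, file.path(cdir, "t2w.nii.gz"))
      write_volume_nifti(cs$truth_adc, file.path(cdir, "truth_adc.nii.gz"))
      write_volume_nifti(cs$truth_fbv, file.path(cdir, "truth_fbv.nii.gz"))
      for (b in names(cs$dwi))
        write_volume_nifti(cs$dwi[[b]],
                           file.path(cdir, sprintf("dwi_b%s.nii.gz", b)))
      writeLines(as.character(spec$protocol$b_values),
                 file.path(cdir, "bvals.txt"))
      for (r in seq_along(cs$regions)) {
        m <- cs$regions[[r]]
        write_volume_nifti(volume_grid(array(as.numeric(m$voxels),
                                             dim(m$voxels)), m$spacing),
                           file.path(cdir, sprintf("mask_r%d.nii.gz", r)))
      }
      paths <- cdir
    }
    rows[[i]] <- data.table::data.table(
      case_id = cs$case_id,
      region_id = vapply(cs$regions, `[[`, "", "region_id"),
      label = vapply(cs$regions, `[[`, "", "label"),
      volume_cc = vapply(cs$regions, `[[`, 0, "volume_cc"),
      n_voxels = vapply(cs$regions, function(m) sum(m$voxels), 0L),
      paths = paths)
    if (keep_cases) cases[[i]] <- cs
  }
  manifest <- data.table::rbindlist(rows)
  if (!is.null(out_dir)) {
    data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
    yaml::write_yaml(list(n_cases = spec$n_cases,
                          class_proportions = as.list(spec$class_proportions),
                          b_values = spec$protocol$b_values,
                          noise_sigma = spec$protocol$noise_sigma,
                          seed = spec$seed),
                     file.path(out_dir, "cohort_spec.yaml"))
  }
  list(manifest = manifest, cases = cases)
}
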