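#' Z-score normalize an image
#'
#' `scale * (x - mean) / sd`, with mean and sd computed over all image
#' voxels (not per region: normalization precedes region handling). Used
#' for T2w intensities, whose arbitrary units vary across scanners; the
#' diffusion maps are physical quantities and are not normalized.
#'
#' @param image a [volume_grid()].
#' @param scale multiplier after standardisation (default 100).
#' @return the normalized [volume_grid()].
#' @export
znormalize_image <- function(image, scale = 100) {
  stopifnot(inherits(image, "volume_grid"))
  x <- image$data
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot z-normalize a constant image")
  image$data <- scale * (x - mean(x)) / s
  image
}

# --- cubic B-spline interpolation (separable, mirror boundary) ------------

# Recursive prefilter along the first dimension of a matrix of lines
# (Unser et al.): converts samples to B-spline coefficients. x is
# len x nlines; returns same shape.
bspline_prefilter_lines <- function(x) {
  z <- sqrt(3) - 2
  len <- nrow(x)
  if (len == 1) return(x * 1)
  lambda <- 6
  x <- x * lambda
  c_ <- x
  # causal init: impulse response summed over the mirror-extended signal
  horizon <- ceiling(log(1e-12) / log(abs(z)))
  zk <- z^(seq_len(horizon) - 1)
  ext <- mirror_index(seq_len(horizon), len)
  c_[1, ] <- as.vector(zk %*% x[ext, , drop = FALSE])
  for (k in 2:len) c_[k, ] <- x[k, ] + z * c_[k - 1, ]
  # anticausal
  cp <- c_
  cp[len, ] <- (z / (z * z - 1)) * (c_[len, ] + z * c_[len - 1, ])
  for (k in (len - 1):1) cp[k, ] <- z * (cp[k + 1, ] - c_[k, ])
  cp
}

# Apply the prefilter along axis `axis` of a 3D array.
bspline_prefilter_axis <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- bspline_prefilter_lines(m)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

# Cubic B-spline kernel values for fractional offset t in [0,1): weights
# for coefficient indices floor(x)-1 .. floor(x)+2.
bspline_weights <- function(t) {
  w <- matrix(0, length(t), 4)
  w[, 1] <- (1 - t)^3 / 6
  w[, 2] <- (4 - 6 * t^2 + 3 * t^3) / 6
  w[, 3] <- (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6
  w[, 4] <- t^3 / 6
  w
}

mirror_index <- function(i, n) {
  # reflect indices into 1..n (mirror without repeating the edge sample)
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- (i - 1L) %% p
  i <- ifelse(i < 0, i + p, i)
  as.integer(ifelse(i >= n, p - i, i) + 1L)
}

# Separable cubic B-spline evaluation of a prefiltered coefficient array at
# per-axis continuous (1-based, voxel-index) positions.
bspline_eval_grid <- function(coef, pos) {
  d <- dim(coef)
  out <- coef
  for (axis in 1:3) {
    p <- pos[[axis]]
    i0 <- floor(p)
    t <- p - i0
    w <- bspline_weights(t)
    n <- dim(out)[axis]
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(out, perm)
    m <- matrix(a, nrow = n)
    res <- matrix(0, length(p), ncol(m))
    for (k in 0:3) {
      idx <- mirror_index(i0 - 1L + k, n)
      res <- res + w[, k + 1] * m[idx, , drop = FALSE]
    }
    nd <- dim(a)
    nd[1] <- length(p)
    a <- array(res, nd)
    out <- aperm(a, order(perm))
  }
  out
}

#' Resample an image to a new voxel spacing
#'
#' The output grid starts at the original origin and covers the original
#' physical extent at the requested spacing. Image values are interpolated
#' with a cubic B-spline (exact for polynomials up to degree 3, so linear
#' ramps are preserved); use [resample_mask_to_grid()] for masks, which
#' must stay binary. If the requested geometry equals the native one the
#' image is returned unchanged.
#'
#' @param image a [volume_grid()].
#' @param spacing target spacing, mm (length 3, > 0).
#' @return the resampled [volume_grid()].
#' @export
resample_image <- function(image, spacing) {
  stopifnot(inherits(image, "volume_grid"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  d <- dim(image$data)
  if (any(d < 1) || prod(d) == 0) stop("degenerate image extent")
  if (all(abs(spacing - image$spacing) < 1e-9)) return(image)
  extent <- d * image$spacing
  nd <- pmax(as.integer(floor(extent / spacing + 1e-9)), 1L)
  # continuous source voxel-index position of each target voxel centre
  pos <- lapply(1:3, function(a)
    ((seq_len(nd[a]) - 1) * spacing[a]) / image$spacing[a] + 1)
  coef <- image$data
  for (a in 1:3) if (d[a] > 1) coef <- bspline_prefilter_axis(coef, a)
  volume_grid(bspline_eval_grid(coef, pos), spacing, image$origin)
}

#' Discretize region intensities with a fixed bin width
#'
#' Gray level `level(x) = floor(x / w) - floor(min(x) / w) + 1`: bins are
#' anchored on an absolute `floor(x / w)` grid, so the number of bins a
#' scan produces is its intensity range divided by the width (e.g. a
#' first-order range starting at 6.81 with width 3 starts at bin bound
#' 6.81 / 3 = 2.27). Levels are consecutive integers from 1 up to
#' `n_levels` over the occupied range (intermediate levels may be empty).
#'
#' @param intensities numeric vector of region voxel intensities.
#' @param bin_width positive bin width in intensity units.
#' @return A `discretized_region`: `gray_levels` (integer per voxel),
#'   `n_levels`, `bin_width`, `level_edges` mapping level l to the
#'   interval `[edges[l], edges[l] + bin_width)`, and
#'   `approx_bin_interval`, the intensity range divided by the width.
#' @export
discretize_fixed_bin_width <- function(intensities, bin_width) {
  if (length(intensities) == 0) stop("empty region")
  if (bin_width <= 0) stop("bin_width must be > 0")
  base <- floor(min(intensities) / bin_width)
  lev <- as.integer(floor(intensities / bin_width) - base + 1)
  nl <- max(lev)
  structure(list(gray_levels = lev, n_levels = nl, bin_width = bin_width,
                 level_edges = (base + seq_len(nl) - 1) * bin_width,
                 approx_bin_interval = range(intensities) / bin_width),
            class = "discretized_region")
}
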