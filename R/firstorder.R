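#' First-order (intensity histogram) features
#'
#' The 19 standard first-order radiomics features of a region's intensity
#' multiset. Entropy and Uniformity are computed on the fixed-bin-width
#' discretization ([discretize_fixed_bin_width()]); everything else on the
#' raw intensities. Percentiles use linear interpolation between closest
#' ranks; moment-based features (Variance, StandardDeviation, Skewness,
#' Kurtosis, MeanAbsoluteDeviation) use the population (1/N) convention,
#' and Kurtosis is not excess-corrected (a normal sample gives ~3).
#'
#' @param x numeric vector of region voxel intensities (>= 2 voxels).
#' @param bin_width bin width for the Entropy/Uniformity histogram.
#' @param voxel_volume voxel volume in mm^3 (for TotalEnergy).
#' @return named numeric vector of 19 features.
#' @export
first_order_features <- function(x, bin_width, voxel_volume = 1) {
  if (length(x) < 2) stop("first-order features need >= 2 voxels")
  n <- length(x)
  mu <- mean(x)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                        type = 7)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  sel <- x >= qs[1] & x <= qs[5]
  # tiny regions can have no value strictly inside [P10, P90]; fall back
  # to the full set so the robust MAD degrades to the plain MAD
  xr <- if (any(sel)) x[sel] else x
  disc <- discretize_fixed_bin_width(x, bin_width)
  p <- tabulate(disc$gray_levels, disc$n_levels) / n
  p <- p[p > 0]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(xr - mean(xr))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
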