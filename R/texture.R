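#' @keywords internal
#' Gray-level texture matrices and features.
#'
#' All five families operate on a cropped 3D integer array of discretized
#' gray levels with NA outside the region, using 3D 26-connectivity at
#' Chebyshev distance 1 (13 unique angle offsets; GLCM and GLRLM are
#' symmetric per angle and their features are averaged over angles after
#' computation). Gray values entering the formulas are the discretization
#' levels themselves; normalisation constants that need "the number of
#' gray levels" use the number of levels actually occupied in the region.
#' Degenerate regions (a single gray level) return each feature's limiting
#' value; division-by-zero guards return the documented limit.
NULL

# offset (di,dj,dk) for each of the 13 unique 3D angles (one per
# antipodal pair: first nonzero component positive)
unique_angles <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

# shift a 3D array by offset o, padding with `fill`; out[v] = x[v - o]
shift_off <- function(x, o, fill = NA) {
  d <- dim(x)
  out <- array(fill, d)
  rng <- vector("list", 3)
  src <- vector("list", 3)
  for (a in 1:3) {
    i1 <- max(1, 1 + o[a]); i2 <- min(d[a], d[a] + o[a])
    if (i1 > i2) return(out)
    rng[[a]] <- i1:i2
    src[[a]] <- (i1:i2) - o[a]
  }
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    x[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

# ---------------------------------------------------------------- GLCM ---

glcm_matrix_angle <- function(lev, ng, off) {
  nb <- shift_off(lev, off)
  ok <- !is.na(lev) & !is.na(nb)
  if (!any(ok)) return(NULL)
  i <- lev[ok]; j <- nb[ok]
  counts <- matrix(tabulate(i + (j - 1L) * ng, ng * ng), ng, ng)
  counts + t(counts)                      # symmetric co-occurrence
}

# level-geometry matrices shared by every angle of one region; the level
# axis runs over the full 1..ng discretized range (empty levels carry zero
# probability), so ng in the Idn/Idmn normalisers is the region's
# discretized level count
glcm_geom <- function(ng) {
  iv <- matrix(seq_len(ng), ng, ng)
  jv <- t(iv)
  dmat <- abs(iv - jv)
  smat <- iv + jv
  inv_d2 <- ifelse(dmat > 0, 1 / dmat^2, 0)
  list(ng = ng, iv = iv, jv = jv, dmat = dmat, smat = smat,
       ivjv = iv * jv, d2 = (iv - jv)^2,
       w_idm = 1 / (1 + dmat^2), w_idmn = 1 / (1 + (dmat / ng)^2),
       w_id = 1 / (1 + dmat), w_idn = 1 / (1 + dmat / ng),
       inv_d2 = inv_d2,
       dgrp = as.vector(dmat) + 1L,         # groups 1..ng
       sgrp = as.vector(smat) - 1L)         # groups 1..2ng-1
}

glcm_features_one <- function(P, g) {
  p <- P / sum(P)
  ng <- g$ng
  vals <- seq_len(ng)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(vals * px); uy <- sum(vals * py)
  sx <- sqrt(sum((vals - ux)^2 * px)); sy <- sqrt(sum((vals - uy)^2 * py))

  pv <- as.vector(p)
  pxy_d <- drop(rowsum(pv, g$dgrp, reorder = TRUE))   # over k = 0..ng-1
  kd <- seq_len(ng) - 1
  pxy_s <- drop(rowsum(pv, g$sgrp, reorder = TRUE))   # over k = 2..2ng
  ks <- seq_len(2 * ng - 1) + 1

  HX <- -sum(px * safe_log2(px))
  HY <- -sum(py * safe_log2(py))
  HXY <- -sum(p * safe_log2(p))
  pxpy <- outer(px, py)
  HXY1 <- -sum(p * safe_log2(pxpy))
  HXY2 <- -sum(pxpy * safe_log2(pxpy))

  da <- sum(kd * pxy_d)
  corr <- if (sx > 0 && sy > 0)
    (sum(g$ivjv * p) - ux * uy) / (sx * sy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))

  occ <- which(px > 0)
  mcc <- if (length(occ) > 1) {
    ps <- p[occ, occ, drop = FALSE]
    A <- sweep(ps, 2, py[occ], `/`)
    Q <- sweep(A %*% t(ps), 1, px[occ], `/`)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  } else 1

  spp <- g$smat - ux - uy
  c(Autocorrelation = sum(g$ivjv * p),
    JointAverage = ux,
    ClusterProminence = sum(spp^4 * p),
    ClusterShade = sum(spp^3 * p),
    ClusterTendency = sum(spp^2 * p),
    Contrast = sum(g$d2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_d * safe_log2(pxy_d)),
    DifferenceVariance = sum((kd - da)^2 * pxy_d),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p * g$w_idm),
    Idmn = sum(p * g$w_idmn),
    Id = sum(p * g$w_id),
    Idn = sum(p * g$w_idn),
    InverseVariance = sum(p * g$inv_d2),
    MaximumProbability = max(p),
    SumAverage = sum(ks * pxy_s),
    SumEntropy = -sum(pxy_s * safe_log2(pxy_s)),
    SumSquares = sum((g$iv - ux)^2 * p),
    MCC = mcc)
}

glcm_features <- function(lev, ng) {
  angles <- unique_angles()
  g <- glcm_geom(ng)
  feats <- NULL
  n_used <- 0
  for (a in seq_len(nrow(angles))) {
    P <- glcm_matrix_angle(lev, ng, angles[a, ])
    if (is.null(P) || sum(P) == 0) next
    f <- glcm_features_one(P, g)
    feats <- if (is.null(feats)) f else feats + f
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no voxel pairs for GLCM")
  feats / n_used
}

# --------------------------------------------------------------- GLRLM ---

glrlm_matrix_angle <- function(lev, ng, off) {
  # chain counting: C_t(v) = TRUE iff v, v+o, ..., v+(t-1)o share a level;
  # maximal-run counts follow from r_l = n_l - 2 n_{l+1} + n_{l+2}
  inreg <- !is.na(lev)
  nb <- shift_off(lev, -off)
  same_next <- inreg & !is.na(nb) & (lev == nb)
  counts <- list()
  C <- inreg
  t <- 1L
  repeat {
    n_t <- tabulate(lev[C], ng)
    counts[[t]] <- n_t
    if (sum(n_t) == 0) break
    C <- same_next & shift_off(C, -off, fill = FALSE)
    t <- t + 1L
  }
  lmax <- length(counts)
  n <- do.call(cbind, counts)               # ng x lmax chain counts
  n <- cbind(n, 0, 0)
  R <- n[, 1:lmax, drop = FALSE] - 2 * n[, 2:(lmax + 1), drop = FALSE] +
    n[, 3:(lmax + 2), drop = FALSE]
  R[R < 0] <- 0
  # drop trailing all-zero lengths
  keep <- which(colSums(R) > 0)
  if (length(keep) == 0) return(NULL)
  R[, 1:max(keep), drop = FALSE]
}

rl_style_features <- function(M, vals, lens, np, prefix,
                              size_names = c("ShortRun", "LongRun",
                                             "RunLength", "Run")) {
  # shared feature body for run-length (and, renamed, size-zone) matrices
  ns <- sum(M)
  iv <- matrix(vals, nrow(M), ncol(M))
  lv <- matrix(lens, nrow(M), ncol(M), byrow = TRUE)
  pn <- M / ns
  mu_i <- sum(iv * pn); mu_l <- sum(lv * pn)
  gl_sum <- rowSums(M); len_sum <- colSums(M)
  f <- c(sum(M / lv^2) / ns,
         sum(M * lv^2) / ns,
         sum(gl_sum^2) / ns,
         sum(gl_sum^2) / ns^2,
         sum(len_sum^2) / ns,
         sum(len_sum^2) / ns^2,
         ns / np,
         sum(pn * (iv - mu_i)^2),
         sum(pn * (lv - mu_l)^2),
         -sum(pn * safe_log2(pn)),
         sum(M / iv^2) / ns,
         sum(M * iv^2) / ns,
         sum(M / (iv^2 * lv^2)) / ns,
         sum(M * iv^2 / lv^2) / ns,
         sum(M * lv^2 / iv^2) / ns,
         sum(M * iv^2 * lv^2) / ns)
  names(f) <- paste0(prefix, c(
    paste0(size_names[1], "Emphasis"),
    paste0(size_names[2], "Emphasis"),
    "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized",
    paste0(size_names[3], "NonUniformity"),
    paste0(size_names[3], "NonUniformityNormalized"),
    paste0(size_names[4], "Percentage"),
    "GrayLevelVariance",
    paste0(size_names[4], "Variance"),
    paste0(size_names[4], "Entropy"),
    "LowGrayLevel", "HighGrayLevel",
    paste0(size_names[1], "LowGrayLevel"),
    paste0(size_names[1], "HighGrayLevel"),
    paste0(size_names[2], "LowGrayLevel"),
    paste0(size_names[2], "HighGrayLevel")))
  f
}

glrlm_features <- function(lev, ng) {
  np <- sum(!is.na(lev))
  angles <- unique_angles()
  feats <- NULL
  n_used <- 0
  for (a in seq_len(nrow(angles))) {
    R <- glrlm_matrix_angle(lev, ng, angles[a, ])
    if (is.null(R)) next
    occ <- rowSums(R) > 0
    f <- rl_style_features(R[occ, , drop = FALSE], which(occ),
                           seq_len(ncol(R)), np, "",
                           c("ShortRun", "LongRun", "RunLength", "Run"))
    feats <- if (is.null(feats)) f else feats + f
    n_used <- n_used + 1
  }
  f <- feats / n_used
  names(f) <- sub("LowGrayLevel$", "LowGrayLevelRunEmphasis", names(f))
  names(f) <- sub("HighGrayLevel$", "HighGrayLevelRunEmphasis", names(f))
  names(f) <- sub("(ShortRun|LongRun)(Low|High)GrayLevel$",
                  "\\1\\2GrayLevelEmphasis", names(f))
  f
}

# --------------------------------------------------------------- GLSZM ---

label_zones <- function(lev) {
  # 26-connected components of equal gray level, by iterative min-label
  # propagation; returns an integer array of zone ids (NA outside region)
  d <- dim(lev)
  lab <- array(NA_integer_, d)
  inreg <- which(!is.na(lev))
  lab[inreg] <- seq_along(inreg)
  offs <- unique_angles()
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(offs))) {
      for (s in list(offs[a, ], -offs[a, ])) {
        nb_lab <- shift_off(lab, s)
        nb_lev <- shift_off(lev, s)
        upd <- !is.na(lab) & !is.na(nb_lab) & (lev == nb_lev) &
          (nb_lab < lab)
        if (any(upd)) {
          lab[upd] <- nb_lab[upd]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

glszm_features <- function(lev, ng) {
  np <- sum(!is.na(lev))
  lab <- label_zones(lev)
  ok <- !is.na(lab)
  ids <- lab[ok]; g <- lev[ok]
  o <- order(ids)
  r <- rle(ids[o])
  zone_size <- r$lengths
  zone_lev <- g[o][cumsum(r$lengths)]
  sizes <- sort(unique(zone_size))
  glv <- sort(unique(zone_lev))
  gi <- match(zone_lev, glv); si <- match(zone_size, sizes)
  M <- matrix(tabulate(gi + (si - 1L) * length(glv),
                       length(glv) * length(sizes)),
              length(glv), length(sizes))
  f <- rl_style_features(M, glv, sizes, np, "",
                         c("SmallArea", "LargeArea", "SizeZone", "Zone"))
  names(f) <- sub("LowGrayLevel$", "LowGrayLevelZoneEmphasis", names(f))
  names(f) <- sub("HighGrayLevel$", "HighGrayLevelZoneEmphasis", names(f))
  names(f) <- sub("(SmallArea|LargeArea)(Low|High)GrayLevel$",
                  "\\1\\2GrayLevelEmphasis", names(f))
  f
}

# --------------------------------------------------------------- NGTDM ---

ngtdm_features <- function(lev, ng) {
  inreg <- !is.na(lev)
  nvp <- sum(inreg)
  offs <- unique_angles()
  nb_sum <- array(0, dim(lev))
  nb_cnt <- array(0, dim(lev))
  lev0 <- lev; lev0[!inreg] <- 0L
  for (a in seq_len(nrow(offs))) {
    for (s in list(offs[a, ], -offs[a, ])) {
      nb_sum <- nb_sum + shift_off(lev0, s, fill = 0)
      nb_cnt <- nb_cnt + shift_off(inreg, s, fill = FALSE)
    }
  }
  A <- ifelse(nb_cnt > 0, nb_sum / nb_cnt, NA)
  use <- inreg & nb_cnt > 0
  gl <- lev[use]
  dev <- abs(gl - A[use])
  n_i <- tabulate(gl, ng)
  s_i <- numeric(ng)
  agg <- rowsum(dev, gl, reorder = TRUE)
  s_i[as.integer(rownames(agg))] <- agg
  nv <- sum(n_i)
  p_i <- n_i / nv
  present <- which(p_i > 0)
  ngp <- length(present)
  vals <- present
  pi_ <- p_i[present]; si_ <- s_i[present]

  coarse_den <- sum(pi_ * si_)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(pi_, pi_) * outer(vals, vals, `-`)^2) /
      (ngp * (ngp - 1)) * sum(si_) / nv
  } else 0
  busy_den <- sum(abs(outer(vals * pi_, vals * pi_, `-`)))
  busyness <- if (busy_den > 0) sum(pi_ * si_) / busy_den else 0
  cplx <- sum(abs(outer(vals, vals, `-`)) *
                (outer(pi_ * si_, pi_ * si_, `+`)) /
                outer(pi_, pi_, `+`)) / nv
  strength <- if (sum(si_) > 0)
    sum(outer(pi_, pi_, `+`) * outer(vals, vals, `-`)^2) / sum(si_) else 0

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cplx, Strength = strength)
}

# ---------------------------------------------------------------- GLDM ---

gldm_features <- function(lev, ng) {
  inreg <- !is.na(lev)
  np <- sum(inreg)
  offs <- unique_angles()
  dep <- array(0L, dim(lev))
  for (a in seq_len(nrow(offs))) {
    for (s in list(offs[a, ], -offs[a, ])) {
      nb <- shift_off(lev, s)
      dep <- dep + (inreg & !is.na(nb) & lev == nb)
    }
  }
  # dependence = centre voxel + identical 26-neighbours
  k <- dep[inreg] + 1L
  g <- lev[inreg]
  glv <- sort(unique(g))
  ks <- sort(unique(k))
  M <- matrix(tabulate(match(g, glv) + (match(k, ks) - 1L) * length(glv),
                       length(glv) * length(ks)),
              length(glv), length(ks))
  f <- rl_style_features(M, glv, ks, np, "",
                         c("SmallDependence", "LargeDependence",
                           "Dependence", "Dependence"))
  # GLDM reports no percentage/GLNN; rename and trim to the 14 standard
  names(f) <- sub("LowGrayLevel$", "LowGrayLevelEmphasis", names(f))
  names(f) <- sub("HighGrayLevel$", "HighGrayLevelEmphasis", names(f))
  names(f) <- sub("(SmallDependence|LargeDependence)(Low|High)GrayLevel$",
                  "\\1\\2GrayLevelEmphasis", names(f))
  f <- f[setdiff(names(f), c("DependencePercentage",
                             "GrayLevelNonUniformityNormalized"))]
  f
}

#' Texture features of a discretized region
#'
#' Computes the five gray-level texture families over region voxels:
#' GLCM (24), GLRLM (16), GLSZM (16), NGTDM (5) and GLDM (14) — 75 scalars.
#' See the package vignette for matrix definitions and degenerate-case
#' limits.
#'
#' @param lev integer 3D array of gray levels, NA outside the region
#'   (cropped to the region bounding box for efficiency).
#' @param n_levels number of discretization levels (max level).
#' @return named numeric vector of 75 features, names
#'   `<family>_<Feature>`.
#' @export
texture_features <- function(lev, n_levels) {
  if (sum(!is.na(lev)) < 2) stop("texture features need >= 2 voxels")
  fam <- list(glcm = glcm_features(lev, n_levels),
              glrlm = glrlm_features(lev, n_levels),
              glszm = glszm_features(lev, n_levels),
              ngtdm = ngtdm_features(lev, n_levels),
              gldm = gldm_features(lev, n_levels))
  unlist(lapply(names(fam), function(nm)
    stats::setNames(fam[[nm]], paste0(nm, "_", names(fam[[nm]])))),
    use.names = TRUE)
}
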