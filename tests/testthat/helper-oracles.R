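# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal possible formulation (voxel-by-
# voxel scans, exhaustive pair enumeration) and share no code with R/.

# erosion oracle: keep slice z iff slices z-1 and z+1 are occupied; a voxel
# survives iff every in-plane voxel within Euclidean distance r_vox of it
# (in voxel units, isotropic in-plane) is set
brute_erode <- function(v, r_vox) {
  d <- dim(v)
  occ <- apply(v, 3, any)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    if (!occ[z]) next
    if (z == 1 || z == d[3]) next
    if (!occ[z - 1] || !occ[z + 1]) next
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!v[i, j, z]) next
      ok <- TRUE
      for (di in -r_vox:r_vox) for (dj in -r_vox:r_vox) {
        if (di^2 + dj^2 > r_vox^2) next
        ii <- i + di; jj <- j + dj
        inside <- ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          v[ii, jj, z]
        if (!inside) { ok <- FALSE; break }
      }
      out[i, j, z] <- ok
    }
  }
  out
}

# GLCM oracle: enumerate every ordered voxel pair at the given offset
brute_glcm <- function(lev, off, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
      next
    if (is.na(lev[ii, jj, kk])) next
    a <- lev[i, j, k]; b <- lev[ii, jj, kk]
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1          # symmetric
  }
  M
}

# GLRLM oracle: walk every maximal run along the offset direction
brute_glrlm <- function(lev, off, ng) {
  d <- dim(lev)
  inb <- function(p) all(p >= 1) && all(p <= d)
  val <- function(p) lev[p[1], p[2], p[3]]
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k)
    if (is.na(val(p))) next
    prev <- p - off
    if (inb(prev) && !is.na(val(prev)) && val(prev) == val(p)) next
    len <- 1
    q <- p + off
    while (inb(q) && !is.na(val(q)) && val(q) == val(p)) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(val(p), len)
  }
  lmax <- max(vapply(runs, `[`, 0, 2))
  M <- matrix(0, ng, lmax)
  for (r in runs) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# GLSZM oracle: BFS flood fill of 26-connected equal-level zones
brute_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    g <- lev[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        if (is.na(lev[q[1], q[2], q[3]])) next
        if (lev[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)               # rows: (gray level, zone size)
}

# ROC AUC oracle: exhaustive pairwise comparison, ties counted half
brute_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random blob-ish test mask: union of a few boxes, plus salt
random_mask <- function(dim = c(9, 9, 6), p_fill = 0.35) {
  v <- array(stats::runif(prod(dim)) < p_fill, dim)
  v
}

# random discretized region on a small grid
random_level_region <- function(dim = c(6, 6, 3), ng = 4, p_na = 0.25) {
  lev <- array(sample.int(ng, prod(dim), replace = TRUE), dim)
  lev[stats::runif(prod(dim)) < p_na] <- NA
  storage.mode(lev) <- "integer"
  lev
}

small_mask <- function(v, spacing = c(1, 1, 1), label = "GP3",
                       region_id = "r", case_id = "c") {
  region_mask(v, spacing, label = label, region_id = region_id,
              case_id = case_id)
}
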