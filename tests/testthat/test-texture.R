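test_that("constant regions give the degenerate texture limits", {
  lev <- array(1L, c(4, 4, 2))
  f <- texture_features(lev, 1)
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_JointEnergy"]), 1)
  expect_equal(unname(f["glcm_Correlation"]), 1)
  expect_equal(unname(f["glcm_MaximumProbability"]), 1)
  # one zone of full size
  expect_equal(unname(f["glszm_ZonePercentage"]), 1 / 32)
  expect_equal(unname(f["glszm_LargeAreaEmphasis"]), 32^2)
  expect_equal(unname(f["ngtdm_Contrast"]), 0)
  expect_equal(unname(f["gldm_GrayLevelNonUniformity"]), 32)
})

test_that("the feature vector has 75 uniquely named entries per family count", {
  set.seed(1)
  lev <- random_level_region(c(6, 6, 3), ng = 4)
  f <- texture_features(lev, 4L)
  expect_length(f, 75)
  expect_false(any(duplicated(names(f))))
  counts <- table(sub("_.*", "", names(f)))
  expect_equal(counts[["glcm"]], 24)
  expect_equal(counts[["glrlm"]], 16)
  expect_equal(counts[["glszm"]], 16)
  expect_equal(counts[["ngtdm"]], 5)
  expect_equal(counts[["gldm"]], 14)
  expect_true(all(is.finite(f)))
})

test_that("GLCM counts match exhaustive pair enumeration", {
  # 2D checkerboard at distance 1, angle (1, 0): every horizontal pair
  # alternates levels, verified by enumerating all pairs
  lev <- array(NA_integer_, c(4, 4, 1))
  lev[, , 1] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  P <- cribromics:::glcm_matrix_angle(lev, 2L, c(1, 0, 0))
  expect_equal(P, brute_glcm(lev, c(1, 0, 0), 2L))
  expect_equal(P[1, 1], 0)            # no equal-level horizontal pairs
  expect_equal(sum(P), 2 * 12)        # 12 ordered pairs, symmetrised
  set.seed(2)
  angles <- cribromics:::unique_angles()
  for (i in 1:15) {
    lv <- random_level_region(c(5, 6, 3), ng = 3)
    if (sum(!is.na(lv)) < 2) next
    a <- angles[sample(nrow(angles), 1), ]
    expect_equal(cribromics:::glcm_matrix_angle(lv, 3L, a),
                 brute_glcm(lv, a, 3L))
  }
})

test_that("normalized GLCM probabilities sum to 1 over all angles", {
  set.seed(3)
  lev <- random_level_region(c(6, 5, 3), ng = 4, p_na = 0.2)
  angles <- cribromics:::unique_angles()
  for (a in seq_len(nrow(angles))) {
    P <- cribromics:::glcm_matrix_angle(lev, 4L, angles[a, ])
    if (is.null(P) || sum(P) == 0) next
    expect_equal(sum(P / sum(P)), 1, tolerance = 1e-12)
  }
})

test_that("GLRLM run counts match the run-walking oracle", {
  set.seed(4)
  angles <- cribromics:::unique_angles()
  for (i in 1:15) {
    lv <- random_level_region(c(6, 5, 4), ng = 3, p_na = 0.2)
    if (sum(!is.na(lv)) < 2) next
    a <- angles[sample(nrow(angles), 1), ]
    got <- cribromics:::glrlm_matrix_angle(lv, 3L, a)
    want <- brute_glrlm(lv, a, 3L)
    # pad to common length
    lmax <- max(ncol(got), ncol(want))
    pad <- function(m) cbind(m, matrix(0, nrow(m), lmax - ncol(m)))
    expect_equal(pad(got), pad(want), ignore_attr = TRUE)
  }
  # every voxel belongs to exactly one run: sum_i sum_l l * R(i,l) = Np
  lv <- random_level_region(c(7, 6, 3), ng = 4, p_na = 0.3)
  for (a in seq_len(nrow(angles))) {
    R <- cribromics:::glrlm_matrix_angle(lv, 4L, angles[a, ])
    expect_equal(sum(R %*% seq_len(ncol(R))), sum(!is.na(lv)))
  }
})

test_that("GLSZM zones match the flood-fill oracle and sum to region size", {
  set.seed(5)
  for (i in 1:10) {
    lv <- random_level_region(c(6, 6, 3), ng = 3, p_na = 0.25)
    if (sum(!is.na(lv)) < 2) next
    lab <- cribromics:::label_zones(lv)
    ids <- lab[!is.na(lab)]
    sizes_impl <- sort(as.vector(table(ids)))
    want <- brute_zones(lv)
    expect_equal(sizes_impl, sort(want[, 2]))
    expect_equal(sum(want[, 2]), sum(!is.na(lv)))
    # zone count by level also agrees
    lev_impl <- lv[!is.na(lab)][!duplicated(ids)]
    expect_equal(sort(table(lev_impl)), sort(table(want[, 1])),
                 ignore_attr = TRUE)
  }
})

test_that("NGTDM deviations match a direct per-voxel loop", {
  set.seed(6)
  lv <- random_level_region(c(5, 5, 3), ng = 3, p_na = 0.2)
  f <- cribromics:::ngtdm_features(lv, 3L)
  # direct oracle for coarseness: 1 / sum p_i s_i
  d <- dim(lv)
  s_i <- numeric(3); n_i <- numeric(3)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k])) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 ||
          kk > d[3]) next
      if (!is.na(lv[ii, jj, kk])) nb <- c(nb, lv[ii, jj, kk])
    }
    if (length(nb) == 0) next
    g <- lv[i, j, k]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  p_i <- n_i / sum(n_i)
  expect_equal(unname(f["Coarseness"]), 1 / sum(p_i * s_i),
               tolerance = 1e-9)
})

test_that("GLDM dependence counts match a direct per-voxel loop", {
  set.seed(7)
  lv <- random_level_region(c(5, 5, 3), ng = 3, p_na = 0.2)
  f <- cribromics:::gldm_features(lv, 3L)
  d <- dim(lv)
  deps <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k])) next
    dep <- 1
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 ||
          kk > d[3]) next
      if (!is.na(lv[ii, jj, kk]) && lv[ii, jj, kk] == lv[i, j, k])
        dep <- dep + 1
    }
    deps <- c(deps, dep)
  }
  # oracle for LargeDependenceEmphasis: mean of k^2 over voxels
  expect_equal(unname(f["LargeDependenceEmphasis"]), mean(deps^2),
               tolerance = 1e-9)
  expect_equal(unname(f["SmallDependenceEmphasis"]), mean(1 / deps^2),
               tolerance = 1e-9)
})

test_that("texture extraction is deterministic for identical input", {
  set.seed(8)
  lv <- random_level_region(c(6, 6, 3), ng = 4)
  expect_identical(texture_features(lv, 4L), texture_features(lv, 4L))
})
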