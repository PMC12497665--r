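make_stack <- function(signals, bvals, spacing = c(1, 1, 1)) {
  # signals: function(b) -> 3D array, or list of arrays named by b
  vols <- lapply(bvals, function(b)
    volume_grid(if (is.function(signals)) signals(b)
                else signals[[as.character(b)]], spacing))
  names(vols) <- as.character(bvals)
  dwi_stack(vols)
}

test_that("noiseless monoexponential signals are recovered exactly", {
  d <- c(5, 4, 3)
  D_true <- 1.0e-3
  st <- make_stack(function(b) array(100 * exp(-b * D_true), d),
                   c(0, 200, 800))
  maps <- fit_segmented_ivim(st)
  expect_equal(max(abs(maps$adc$data - D_true)) / D_true, 0,
               tolerance = 1e-9)
  expect_equal(max(abs(maps$fbv$data)), 0, tolerance = 1e-9)
})

test_that("voxelwise D and f recovery on a noiseless biexponential field", {
  # the fit window 200-800 still carries a little pseudo-diffusion at
  # b = 200, so D-hat is computed against the same two-point log-linear
  # closed form evaluated independently
  d <- c(4, 3, 2)
  set.seed(1)
  D <- array(runif(prod(d), 0.7e-3, 1.5e-3), d)
  f <- array(runif(prod(d), 0.05, 0.2), d)
  Ds <- 20e-3
  S <- function(b) array(ivim_signal(100, b, D, Ds, f), d)
  st <- make_stack(S, c(0, 200, 800))
  maps <- fit_segmented_ivim(st)
  D_hat <- (log(S(200)) - log(S(800))) / 600        # independent oracle
  A_hat <- log(S(200)) + 200 * D_hat
  f_hat <- 1 - exp(A_hat) / S(0)
  expect_equal(maps$adc$data, D_hat, tolerance = 1e-9)
  expect_equal(maps$fbv$data, pmin(pmax(f_hat, 0), 1), tolerance = 1e-9)
  # and the bias from residual pseudo-diffusion is small but positive
  expect_true(all(D_hat >= D))
})

test_that("f = 0 noiseless round-trip recovers D to 1e-6 and f to 1e-3", {
  d <- c(6, 6, 4)
  set.seed(2)
  D <- array(runif(prod(d), 0.5e-3, 2e-3), d)
  st <- make_stack(function(b) array(ivim_signal(80, b, D, 30e-3, 0), d),
                   c(0, 200, 500, 800))
  maps <- fit_segmented_ivim(st)
  expect_lt(max(abs(maps$adc$data - D)), 1e-6 * 1e-3)  # mm^2/s scale
  expect_lt(max(abs(maps$fbv$data)), 1e-3)
})

test_that("only b-values in 200-800 enter the ADC fit", {
  d <- c(3, 3, 2)
  base <- function(b) array(100 * exp(-b * 1.1e-3), d)
  st1 <- make_stack(base, c(0, 50, 300, 800))
  # corrupt only the b = 50 channel: maps must be identical
  sig <- lapply(c(0, 50, 300, 800), base)
  names(sig) <- c("0", "50", "300", "800")
  sig[["50"]] <- sig[["50"]] * 3
  st2 <- make_stack(sig, c(0, 50, 300, 800))
  m1 <- fit_segmented_ivim(st1)
  m2 <- fit_segmented_ivim(st2)
  expect_identical(m1$adc$data, m2$adc$data)
  expect_identical(m1$fbv$data, m2$fbv$data)
})

test_that("global signal scaling leaves ADC and fBV unchanged", {
  d <- c(4, 4, 2)
  set.seed(3)
  D <- array(runif(prod(d), 0.6e-3, 1.4e-3), d)
  f <- array(runif(prod(d), 0, 0.2), d)
  S <- function(b) array(ivim_signal(100, b, D, 20e-3, f), d)
  S2 <- function(b) 7.3 * S(b)
  m1 <- fit_segmented_ivim(make_stack(S, c(0, 200, 800)))
  m2 <- fit_segmented_ivim(make_stack(S2, c(0, 200, 800)))
  expect_equal(m1$adc$data, m2$adc$data, tolerance = 1e-12)
  expect_equal(m1$fbv$data, m2$fbv$data, tolerance = 1e-12)
})

test_that("non-physical fits are clamped and bad voxels flagged", {
  d <- c(2, 2, 1)
  # rising signal with b -> negative ADC -> clamped to 0
  sig <- list("0" = array(50, d), "200" = array(60, d),
              "800" = array(90, d))
  maps <- fit_segmented_ivim(make_stack(sig, c(0, 200, 800)))
  expect_true(all(maps$adc$data == 0))
  # a zero signal in the fit window flags the voxel
  sig2 <- list("0" = array(50, d), "200" = array(c(0, 40, 40, 40), d),
               "800" = array(20, d))
  maps2 <- fit_segmented_ivim(make_stack(sig2, c(0, 200, 800)))
  expect_equal(maps2$fit_log[1, 1, 1], 1L)
  expect_equal(maps2$adc$data[1, 1, 1], 0)
  expect_equal(maps2$fbv$data[1, 1, 1], 0)
})

test_that("clamping is idempotent and caps fBV at 1", {
  g <- function(x) volume_grid(array(x, c(2, 2, 1)), c(1, 1, 1))
  maps <- structure(list(adc = g(c(-2e-4, 1e-3, 0, 5e-4)),
                         fbv = g(c(-0.1, 0.5, 1.4, 0)),
                         fit_log = array(0L, c(2, 2, 1))),
                    class = "parameter_maps")
  c1 <- clamp_nonphysical(maps)
  expect_equal(as.vector(c1$adc$data), c(0, 1e-3, 0, 5e-4))
  expect_equal(as.vector(c1$fbv$data), c(0, 0.5, 1, 0))
  c2 <- clamp_nonphysical(c1)
  expect_identical(c1$adc$data, c2$adc$data)
  expect_identical(c1$fbv$data, c2$fbv$data)
  # no-negative map passes through unchanged
  ok <- structure(list(adc = g(c(1e-3, 2e-3, 0, 1e-4)),
                       fbv = g(c(0, 0.2, 1, 0.7)),
                       fit_log = array(0L, c(2, 2, 1))),
                  class = "parameter_maps")
  expect_identical(clamp_nonphysical(ok)$adc$data, ok$adc$data)
})

test_that("stack validation rejects unusable b-value sets", {
  d <- c(2, 2, 1)
  mk <- function(b) volume_grid(array(10, d), c(1, 1, 1))
  vols <- list("0" = mk(0), "100" = mk(100), "800" = mk(800))
  expect_error(dwi_stack(vols), "two b-values")
  vols2 <- list("200" = mk(200), "800" = mk(800))
  expect_error(dwi_stack(vols2), "b = 0")
})

test_that("a 4D NIfTI with bval sidecar round-trips into a stack", {
  d <- c(4, 4, 2)
  bv <- c(0, 200, 800)
  arr <- array(0, c(d, 3))
  for (k in 1:3) arr[, , , k] <- 100 * exp(-bv[k] * 1e-3)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1.03, 1.03, 2.73)
  dwi_path <- tempfile(fileext = ".nii.gz")
  bval_path <- tempfile(fileext = ".bval")
  RNifti::writeNifti(img, dwi_path)
  writeLines(paste(bv, collapse = " "), bval_path)
  st <- read_dwi_stack(dwi_path, bval_path)
  expect_named(st$volumes, c("0", "200", "800"))
  maps <- fit_segmented_ivim(st)
  expect_equal(unique(round(as.vector(maps$adc$data), 9)), 1e-3)
})
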