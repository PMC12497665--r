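test_that("IVIM forward signal matches the closed form", {
  # b = 0: mixture weights sum to 1, any parameters
  expect_equal(ivim_signal(100, 0, 1e-3, 20e-3, 0.37), 100)
  # pure monoexponential: 100 * exp(-0.8)
  expect_equal(ivim_signal(100, 800, 1e-3, 20e-3, 0), 100 * exp(-0.8),
               tolerance = 1e-12)
  # two-term formula, evaluated independently
  S0 <- 100; b <- 200; D <- 1e-3; Ds <- 20e-3; f <- 0.1
  expect_equal(ivim_signal(S0, b, D, Ds, f),
               S0 * (f * exp(-b * Ds) + (1 - f) * exp(-b * D)),
               tolerance = 1e-12)
})

test_that("IVIM signal is nonnegative, monotone in b, and validates input", {
  b <- seq(0, 1000, by = 50)
  s <- ivim_signal(100, b, 1.2e-3, 15e-3, 0.15)
  expect_true(all(s >= 0))
  expect_true(all(diff(s) <= 0))
  expect_error(ivim_signal(-1, 0, 1e-3, 2e-3, 0), "S0")
  expect_error(ivim_signal(1, -5, 1e-3, 2e-3, 0), "b")
  expect_error(ivim_signal(1, 0, 1e-3, 2e-3, 1.5), "f")
  expect_error(ivim_signal(1, 0, 2e-3, 1e-3, 0.1), "Dstar")
})

test_that("phantom cases are a pure function of (seed, case index)", {
  sp <- phantom_spec(n_cases = 3, seed = 11, grid_dim = c(48, 48, 20))
  a <- generate_phantom_case(sp, 2)
  b <- generate_phantom_case(sp, 2)
  expect_identical(a$t2w$data, b$t2w$data)
  expect_identical(a$dwi[["800"]]$data, b$dwi[["800"]]$data)
  expect_identical(lapply(a$regions, `[[`, "voxels"),
                   lapply(b$regions, `[[`, "voxels"))
  # different case index gives a different case
  c2 <- generate_phantom_case(sp, 3)
  expect_false(identical(a$t2w$data, c2$t2w$data))
})

test_that("noiseless DWI equals the IVIM evaluation of the truth maps", {
  proto <- acquisition_protocol(noise_sigma = 0)
  sp <- phantom_spec(n_cases = 1, seed = 5, protocol = proto,
                     grid_dim = c(48, 48, 20))
  cs <- generate_phantom_case(sp, 1)
  b0 <- cs$dwi[["0"]]$data
  b800 <- cs$dwi[["800"]]$data
  # at b = 0 the signal is exactly S0, so the monoexponential identity
  # S(800) = S(0) * [f e^{-800 D*} + (1-f) e^{-800 D}] holds voxelwise
  # D* is 20e-3 mm^2/s for every tissue class in the default parameters
  pred <- ivim_signal(b0, 800, cs$truth_adc$data, 20e-3, cs$truth_fbv$data)
  expect_equal(b800, pred, tolerance = 1e-12)
})

test_that("regions lie inside the prostate and carry valid labels", {
  sp <- phantom_spec(n_cases = 4, seed = 9, grid_dim = c(48, 48, 20))
  for (i in 1:4) {
    cs <- generate_phantom_case(sp, i)
    for (r in cs$regions) {
      expect_true(all(cs$prostate_mask$voxels[r$voxels]))
      expect_true(r$label %in% c("GP3", "GP4Crib-", "GP4Crib+"))
      expect_gt(sum(r$voxels), 0)
    }
  }
})

test_that("truth maps encode the configured diffusion contrast", {
  sp <- phantom_spec(n_cases = 20, seed = 3, grid_dim = c(48, 48, 20))
  vals <- list("GP3" = c(), "GP4Crib+" = c())
  for (i in 1:20) {
    cs <- generate_phantom_case(sp, i)
    for (r in cs$regions)
      if (r$label %in% names(vals))
        vals[[r$label]] <- c(vals[[r$label]], cs$truth_adc$data[r$voxels])
  }
  skip_if(length(vals[["GP3"]]) == 0 || length(vals[["GP4Crib+"]]) == 0)
  expect_lt(mean(vals[["GP4Crib+"]]), mean(vals[["GP3"]]))
})

test_that("cohort label mix and per-label volume medians match the spec", {
  co <- shared_cohort()
  man <- co$manifest
  expect_gt(nrow(man), 200)
  # empirical label frequencies within 99% binomial bounds
  n <- nrow(man)
  for (lb in names(co$spec$class_proportions)) {
    p <- co$spec$class_proportions[[lb]]
    k <- sum(man$label == lb)
    bounds <- stats::qbinom(c(0.005, 0.995), n, p)
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
  # median rasterized volume within 20% of each label's target median
  for (lb in names(co$spec$class_proportions)) {
    target <- co$spec$tissue_params[[lb]]$volume_median_cc
    med <- stats::median(man$volume_cc[man$label == lb])
    expect_lt(abs(med - target) / target, 0.20)
  }
})

test_that("generate_cohort writes NIfTI volumes, manifest and spec", {
  out <- file.path(tempdir(), "cohort_io_test")
  unlink(out, recursive = TRUE)
  sp <- phantom_spec(n_cases = 1, seed = 2, grid_dim = c(48, 48, 20))
  co <- generate_cohort(sp, out_dir = out)
  expect_gte(nrow(co$manifest), 1)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "cohort_spec.yaml")))
  cdir <- file.path(out, "case0001")
  expect_true(file.exists(file.path(cdir, "t2w.nii.gz")))
  expect_true(file.exists(file.path(cdir, "dwi_b0.nii.gz")))
  # round-trip preserves data and geometry
  rt <- read_volume_nifti(file.path(cdir, "truth_adc.nii.gz"))
  expect_equal(rt$data, co$cases[[1]]$truth_adc$data, tolerance = 1e-6)
  expect_equal(rt$spacing, co$cases[[1]]$truth_adc$spacing,
               tolerance = 1e-6)
  # different seeds give different manifests
  co2 <- generate_cohort(phantom_spec(n_cases = 1, seed = 3,
                                      grid_dim = c(48, 48, 20)),
                         keep_cases = FALSE)
  expect_false(identical(co$manifest$volume_cc, co2$manifest$volume_cc))
})
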