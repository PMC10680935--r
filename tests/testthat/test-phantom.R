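test_that("phantom tissue means and geometry match the requested parameters", {
  spec <- phantom_spec(shape = 24, texture_sd = 0.02)
  ph <- generate_phantom(spec, seed = 5)

  # class means within 2 * sd / sqrt(n) of the requested means
  for (k in 1:3) {
    vox <- ph$u$data[ph$labels == k]
    tol <- 2 * spec$texture_sd / sqrt(length(vox))
    expect_lt(abs(mean(vox) - spec$tissue_means[k]), tol + 1e-6)
  }

  # mask voxel count matches the analytic ellipsoid volume within 5%
  analytic <- 4 / 3 * pi * prod(spec$head_axes * spec$shape)
  expect_lt(abs(ph$mask$count - analytic) / analytic, 0.05)

  # determinism
  ph2 <- generate_phantom(spec, seed = 5)
  expect_identical(ph$u$data, ph2$u$data)
  expect_false(identical(ph$u$data, generate_phantom(spec, seed = 6)$u$data))

  # background zero, interior strictly positive
  expect_true(all(ph$u$data[!ph$mask$data] == 0))
  expect_true(all(ph$u$data[ph$mask$data] > 0))
})

test_that("bias fields are positive, amplitude-bounded and smooth", {
  shape <- c(16, 16, 16)
  for (family in c("gauss_random_field", "polynomial", "bspline")) {
    fs <- field_spec(family = family, log_amplitude = 0.3,
                     correlation_length = 4)
    for (seed in 1:10) {
      b <- generate_bias_field(fs, shape, seed = seed)
      expect_gt(min(b$data), 0)
      expect_lte(max(abs(log(b$data))), 0.3 + 1e-9)
    }
    # the rescaling contract is tight: the max is attained
    b <- generate_bias_field(fs, shape, seed = 3)
    expect_equal(max(abs(log(b$data))), 0.3, tolerance = 1e-9)
  }

  # discrete-Laplacian energy far below white noise of equal variance
  lap_energy <- function(x) {
    d <- dim(x)
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    l <- 6 * x[i, j, k] - x[i - 1, j, k] - x[i + 1, j, k] -
      x[i, j - 1, k] - x[i, j + 1, k] - x[i, j, k - 1] - x[i, j, k + 1]
    sum(l^2)
  }
  g <- log(generate_bias_field(field_spec("gauss_random_field",
                                          correlation_length = 4),
                               shape, seed = 9)$data)
  wn <- withr::with_seed(9, array(rnorm(prod(shape), 0, sd(g)), shape))
  expect_gt(lap_energy(wn) / lap_energy(g), 10)

  expect_error(field_spec("nope"), "arg")
})

test_that("samples satisfy the exact forward model", {
  # noise-free: a / b recovers u to 1e-6 relative on the mask
  s <- tiny_sample(seed = 77, noise_sd = 0)
  rel <- abs(s$acquired$data / s$field_truth$data -
             s$corrected_truth$data)[s$mask$data] /
    s$corrected_truth$data[s$mask$data]
  expect_lt(max(rel), 1e-6)

  # losses at ground truth are 0 noise-free
  logb <- log(s$field_truth$data)
  expect_equal(loss_field(logb, s$field_truth, s$mask), 0)
  expect_lt(loss_corrected(s$acquired, logb, s$corrected_truth, s$mask),
            1e-24)

  # with noise: losses at the truth are of order noise_sd^2, and the
  # empirical residual SD matches noise_sd within 5% at 48^3
  sn <- generate_sample(phantom_spec(shape = 48, noise_sd = 0.01),
                        tiny_fspec(), seed = 12)
  resid <- (sn$acquired$data - sn$corrected_truth$data *
              sn$field_truth$data)[sn$mask$data]
  expect_lt(abs(sd(resid) - 0.01) / 0.01, 0.05)
  lb <- loss_corrected(sn$acquired, log(sn$field_truth$data),
                       sn$corrected_truth, sn$mask)
  expect_lt(lb, 5 * 0.01^2)
})

test_that("datasets regenerate bit-identically from their manifest", {
  ds <- generate_dataset(3, tiny_pspec(), tiny_fspec(), seed = 42)
  expect_identical(nrow(ds$manifest), 3L)
  regen <- regenerate_from_manifest(ds$manifest, tiny_pspec(), tiny_fspec())
  for (i in 1:3) {
    expect_identical(ds$samples[[i]]$acquired$data, regen[[i]]$acquired$data)
    expect_identical(ds$samples[[i]]$field_truth$data,
                     regen[[i]]$field_truth$data)
  }
  # every sample satisfies the invariants
  for (s in ds$samples) {
    expect_true(all(s$field_truth$data > 0))
    expect_identical(dim(s$acquired$data), dim(s$mask$data))
    expect_gte(s$mask$count, 1)
  }
  # distinct samples differ
  expect_false(identical(ds$samples[[1]]$acquired$data,
                         ds$samples[[2]]$acquired$data))
})

test_that("dataset round trip through NIfTI preserves the quadruples", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, tiny_pspec(shape = 12), tiny_fspec(), seed = 3)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "nii.gz$"), 8L)
  back <- read_dataset(dir)
  expect_equal(back$samples[[1]]$acquired$data, ds$samples[[1]]$acquired$data)
  expect_identical(back$samples[[2]]$mask$count, ds$samples[[2]]$mask$count)
  expect_equal(back$manifest$seed, ds$manifest$seed)
})
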