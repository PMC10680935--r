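test_that("pad/crop centers content and its record inverts exactly", {
  set.seed(2)
  v <- as_volume(array(rnorm(8^3), c(8, 8, 8)))
  out <- pad_crop_to_shape(v, c(16, 16, 16))
  expect_identical(dim(out$volume$data), c(16L, 16L, 16L))
  expect_equal(out$record$pad_offsets[, "lo"], c(4L, 4L, 4L),
               ignore_attr = TRUE)
  expect_equal(out$volume$data[5:12, 5:12, 5:12], v$data)
  expect_equal(sum(abs(out$volume$data)) , sum(abs(v$data)))

  back <- invert_pad_crop(out$volume, out$record)
  expect_equal(back$data, v$data)

  # odd excess splits floor/ceil
  v2 <- as_volume(array(1, c(5, 5, 5)))
  out2 <- pad_crop_to_shape(v2, c(8, 8, 8))
  expect_equal(out2$record$pad_offsets[, "lo"], c(1L, 1L, 1L),
               ignore_attr = TRUE)
  expect_equal(out2$record$pad_offsets[, "hi"], c(2L, 2L, 2L),
               ignore_attr = TRUE)

  # cropping: 10^3 -> central 8^3, record marks 1-voxel crops
  v3 <- as_volume(array(rnorm(10^3), c(10, 10, 10)))
  out3 <- pad_crop_to_shape(v3, c(8, 8, 8))
  expect_equal(out3$record$crop_offsets[, "lo"], c(1L, 1L, 1L),
               ignore_attr = TRUE)
  expect_equal(out3$volume$data, v3$data[2:9, 2:9, 2:9])

  # mixed pad and crop per axis round-trips on the overlap
  v4 <- as_volume(array(rnorm(6 * 12 * 9), c(6, 12, 9)))
  out4 <- pad_crop_to_shape(v4, c(8, 8, 8))
  back4 <- invert_pad_crop(out4$volume, out4$record)
  kept2 <- 3:10   # axis 2 cropped 12 -> 8
  kept3 <- 1:8    # axis 3 cropped 9 -> 8 (floor/ceil split: 0 low, 1 high)
  expect_equal(back4$data[, kept2, kept3], v4$data[, kept2, kept3])

  expect_error(invert_pad_crop(as_volume(array(0, c(4, 4, 4))), out$record),
               "shape")
})

test_that("min-max normalization divides by the 99th percentile and clips", {
  ones <- as_volume(array(1, c(8, 8, 8)))
  expect_equal(minmax_normalize(ones)$volume$data, ones$data)

  # linear ramp of 1000 voxels over [0, 100]: compare with sort-based oracle
  ramp <- as_volume(array(seq(0, 100, length.out = 1000), c(10, 10, 10)))
  nm <- minmax_normalize(ramp)
  p99 <- sort_percentile(ramp$data, 0.99)
  expect_equal(nm$record$norm_xmax, p99)
  expect_equal(nm$volume$data, pmin(ramp$data / p99, 1))

  # everything above the percentile maps to exactly 1
  expect_true(all(nm$volume$data[ramp$data >= p99] == 1))
  expect_true(all(nm$volume$data >= 0 & nm$volume$data <= 1))

  expect_error(minmax_normalize(as_volume(array(0, c(6, 6, 6)))),
               "degenerate")
})

test_that("brain mask covers the phantom support and respects topology", {
  ph <- generate_phantom(phantom_spec(shape = 24, texture_sd = 0.02), seed = 3)
  b <- generate_bias_field(tiny_fspec(), c(24, 24, 24), seed = 4)
  a <- as_volume(ph$u$data * b$data)
  nm <- minmax_normalize(a)
  m <- compute_brain_mask(nm$volume)

  support <- ph$mask$data
  covered <- sum(m$data & support) / sum(support)
  spill <- sum(m$data & !support) / sum(!support)
  expect_gte(covered, 0.95)
  expect_lte(spill, 0.05)

  expect_error(compute_brain_mask(as_volume(array(0, c(8, 8, 8)))), "empty")

  # a single filled ellipsoid yields exactly one connected component
  lab <- cpp_label_components(m$data, dim(m$data))
  expect_identical(max(lab), 1L)
})

test_that("otsu threshold matches an exhaustive between-class search", {
  set.seed(9)
  x <- c(rnorm(400, 0.15, 0.03), rnorm(600, 0.7, 0.05))
  x <- pmin(pmax(x, 0), 1)
  thr <- biasnet:::otsu_threshold(x)
  # exhaustive continuous search over every observed split point
  cand <- sort(unique(x))
  bc <- vapply(cand, function(t) {
    w0 <- mean(x <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(x[x > t]) - mean(x[x <= t]))^2
  }, numeric(1))
  best <- cand[which.max(bc)]
  expect_lt(abs(thr - best), 0.05)
  # the cut falls between the two modes
  expect_true(thr > 0.15 && thr < 0.65)
})

test_that("restore_to_native inverts the preprocessing chain for fields", {
  native <- as_volume(analytic_field(c(20, 18, 16), c(1, 1.1, 1.25)),
                      spacing = c(1, 1.1, 1.25))
  prep <- preprocess_volume(native, target_spacing = c(2, 2, 2),
                            shape = c(16, 16, 16), mask = FALSE)

  # constant field comes back constant
  const <- as_volume(array(1, c(16, 16, 16)), spacing = c(2, 2, 2))
  rc <- restore_to_native(const, prep$record, native)
  expect_equal(range(rc$data), c(1, 1))
  expect_identical(dim(rc$data), dim(native$data))

  # a smooth analytic field sampled on the coarse grid restores to within 5%
  coarse <- resample_volume(native, c(2, 2, 2))
  coarse_pc <- pad_crop_to_shape(coarse, c(16, 16, 16))
  restored <- restore_to_native(coarse_pc$volume, prep$record, native,
                                fill = 0)
  rel <- abs(restored$data - native$data) / abs(native$data)
  expect_lt(max(rel), 0.05)

  expect_error(restore_to_native(as_volume(array(1, c(8, 8, 8))),
                                 prep$record, native), "shape")
})
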