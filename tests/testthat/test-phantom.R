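test_that("phantom reports the acquisition geometry it was asked for", {
  ph <- generate_phantom(phantom_spec())
  expect_equal(dim(ph$image$voxels)[3], 22L)
  expect_equal(ph$image$slice_thickness_mm, 10)
  expect_equal(ph$truth$slice_window, c(4L, 11L))
})

test_that("truth masks satisfy disjointness/subset invariants and exact voxel-count volumes", {
  for (seed in 1:5) {
    ph <- generate_phantom(small_spec(seed = seed, n_slices = 3L))
    t <- ph$truth
    expect_equal(sum(t$sat_mask * t$vat_mask), 0)
    expect_true(all(t$sat_mask <= t$torso_mask))
    expect_true(all(t$vat_mask <= t$torso_mask))
    expect_true(all(t$spine_fat_mask <= t$torso_mask))
    w <- t$slice_window[1]:t$slice_window[2]
    expect_identical(t$sat_volume_cm3,
                     sum(t$sat_mask[, , w]) * t$voxel_volume_mm3 / 1000)
    expect_identical(t$vat_volume_cm3,
                     sum(t$vat_mask[, , w]) * t$voxel_volume_mm3 / 1000)
  }
})

test_that("same spec and seed give bit-identical phantoms", {
  a <- generate_phantom(small_spec(seed = 42))
  b <- generate_phantom(small_spec(seed = 42))
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$truth$sat_mask, b$truth$sat_mask)
  c <- generate_phantom(small_spec(seed = 43))
  expect_false(identical(a$image$voxels, c$image$voxels))
})

test_that("VAT-free noiseless phantom has zero VAT and a SAT ring near its analytic volume", {
  sp <- phantom_spec(noise_sigma = 0, bias_field_amplitude = 0,
                     vat_blob_params = list(n = 0), spine_params = NULL)
  ph <- generate_phantom(sp)
  expect_identical(ph$truth$vat_volume_cm3, 0)
  # analytic ellipse-annulus volume over the window; digitized masks agree
  # to within the standard digitization bound (~perimeter x spacing per
  # slice)
  scl <- 1 + sp$torso_ellipse$taper * (seq_len(22) - 1) / 21
  w <- 4:11
  ana <- sum(sapply(scl[w], function(s) {
    ax <- sp$torso_ellipse$semi_axes_mm * s
    axi <- ax - sp$sat_ring_thickness_mm
    pi * (ax[1] * ax[2] - axi[1] * axi[2]) * sp$slice_thickness_mm / 1000
  }))
  perim <- 2 * pi * sqrt(mean(sp$torso_ellipse$semi_axes_mm^2))
  bound <- length(w) * perim * max(sp$pixel_spacing_mm) *
    sp$slice_thickness_mm / 1000
  expect_lt(abs(ph$truth$sat_volume_cm3 - ana), bound)
  expect_gt(ph$truth$sat_volume_cm3, 0.95 * ana)
})

test_that("noise-free phantom has exactly the three configured intensity levels", {
  ph <- generate_phantom(small_spec(seed = 2, noise_sigma = 0, bias = 0))
  expect_setequal(unique(as.vector(ph$image$voxels)), c(30, 300, 1000))
})

test_that("invalid phantom specs are rejected with the offending field named", {
  expect_error(phantom_spec(intensity_levels = c(air = 500, lean = 300, fat = 1000)),
               "fat > lean > air")
  expect_error(phantom_spec(torso_ellipse = list(semi_axes_mm = c(300, 300), taper = 0)),
               "torso_ellipse")
  expect_error(phantom_spec(pixel_spacing_mm = c(-1, 2)), "pixel_spacing_mm")
  expect_error(phantom_spec(bias_field_amplitude = 1.2), "bias_field_amplitude")
  expect_error(phantom_spec(sat_ring_thickness_mm = 0), "sat_ring_thickness_mm")
})
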