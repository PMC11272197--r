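test_that("with no VAT blobs the fat mask recovers the SAT ring", {
  ph <- generate_phantom(small_spec(seed = 8, n_slices = 2, noise_sigma = 0,
                                    bias = 0, n_blobs = 0, spine = FALSE))
  norm <- normalize_stack(ph$image)
  torso <- extract_torso(norm)
  fat <- segment_fat(norm, torso)
  for (i in 1:2)
    expect_gte(dice(fat[, , i], ph$truth$sat_mask[, , i]), 0.95)
})

test_that("a fixed threshold above the maximum yields an empty fat mask without error", {
  ph <- generate_phantom(small_spec(seed = 8, n_slices = 1))
  norm <- normalize_stack(ph$image)
  torso <- extract_torso(norm)
  expect_warning(
    fat <- segment_fat(norm, torso,
                       voxa_params(fat_threshold_mode = "fixed",
                                   fat_threshold = 99)),
    "outside the observed intensity range")
  expect_identical(sum(fat), 0L)
})

test_that("fat is always contained in the torso and respects threshold monotonicity", {
  for (seed in c(14, 15, 16)) {
    ph <- generate_phantom(small_spec(seed = seed, n_slices = 1))
    norm <- normalize_stack(ph$image)
    torso <- extract_torso(norm)
    fat <- segment_fat(norm, torso)
    expect_true(all(fat <= torso))
    counts <- sapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
      sum(segment_fat(norm, torso,
                      voxa_params(fat_threshold_mode = "fixed",
                                  fat_threshold = thr)))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("SAT and VAT recover their truth masks when a lean gap separates them", {
  ph <- generate_phantom(small_spec(seed = 18, n_slices = 2, noise_sigma = 0,
                                    bias = 0, spine = FALSE))
  norm <- normalize_stack(ph$image)
  torso <- extract_torso(norm)
  fat <- segment_fat(norm, torso)
  res <- split_sat_vat(fat, torso, geometry = ph$image)
  for (i in 1:2) {
    expect_gte(dice(res$sat[, , i], ph$truth$sat_mask[, , i]), 0.95)
    expect_gte(dice(res$vat[, , i], ph$truth$vat_mask[, , i]), 0.95)
  }
})

test_that("SAT/VAT is an exact partition of the fat mask over random phantoms", {
  for (seed in c(21, 22, 23, 24)) {
    ph <- generate_phantom(small_spec(seed = seed, n_slices = 1,
                                      n_blobs = (seed %% 4L) * 6L))
    norm <- normalize_stack(ph$image)
    torso <- extract_torso(norm)
    fat <- segment_fat(norm, torso)
    res <- split_sat_vat(fat, torso, geometry = ph$image)
    expect_identical((res$sat | res$vat) * 1L, adiposeg:::check_mask(fat))
    expect_identical(sum(res$sat & res$vat), 0L)
    expect_true(all((res$sat | res$vat | res$nonvat) <= res$torso))
  }
})

test_that("an empty fat mask yields empty compartments, and containment violations error", {
  ph <- generate_phantom(small_spec(seed = 8, n_slices = 1))
  norm <- normalize_stack(ph$image)
  torso <- extract_torso(norm)
  empty <- array(0L, dim(torso))
  res <- split_sat_vat(empty, torso, geometry = ph$image)
  expect_identical(sum(res$sat) + sum(res$vat) + sum(res$nonvat), 0L)
  vol <- compute_volumes(res, ph$image, c(1, 1))
  expect_identical(vol$sat_cm3, 0)
  expect_false(vol$ratio_defined)
  bad <- empty; bad[1, 1, 1] <- 1L   # fat voxel outside torso
  expect_error(split_sat_vat(bad, torso), "not a subset")
})

test_that("a slice with fat but no boundary contact yields empty SAT and a logged warning", {
  # synthetic fat blob in the middle of a large torso, far from the band
  nr <- 60
  torso <- array(0L, c(nr, nr, 1))
  torso[, , 1][(row(matrix(0, nr, nr)) - 30)^2 + (col(matrix(0, nr, nr)) - 30)^2 <= 25^2] <- 1L
  fat <- array(0L, c(nr, nr, 1))
  fat[, , 1][(row(matrix(0, nr, nr)) - 30)^2 + (col(matrix(0, nr, nr)) - 30)^2 <= 6^2] <- 1L
  res <- split_sat_vat(fat, torso)
  expect_identical(sum(res$sat), 0L)
  expect_identical(sum(res$vat), sum(fat))
  expect_match(res$log$note[res$log$stage == "split"], "no SAT found")
})

test_that("segmentation is equivariant under 90-degree grid rotation", {
  ph <- generate_phantom(small_spec(seed = 9, n_slices = 2))
  s <- voxa(ph$image)
  ri <- image_stack(rot90_stack(ph$image$voxels),
                    rev(ph$image$pixel_spacing_mm),
                    ph$image$slice_thickness_mm)
  sr <- voxa(ri)
  for (comp in c("sat", "vat", "nonvat", "torso"))
    expect_identical(sr[[comp]], adiposeg:::check_mask(rot90_stack(s[[comp]])))
})

test_that("identical inputs give bit-identical segmentations", {
  ph <- generate_phantom(small_spec(seed = 10, n_slices = 1))
  a <- voxa(ph$image)
  b <- voxa(ph$image)
  expect_identical(a$sat, b$sat)
  expect_identical(a$vat, b$vat)
  expect_identical(a$nonvat, b$nonvat)
  expect_identical(a$torso, b$torso)
})
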