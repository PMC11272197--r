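seg_for_edits <- function(seed = 19) {
  ph <- generate_phantom(small_spec(seed = seed, n_slices = 1))
  list(seg = voxa(ph$image), ph = ph)
}

test_that("an empty edit script is the identity", {
  x <- seg_for_edits()
  out <- apply_edits(x$seg, edit_script())
  expect_identical(out$sat, x$seg$sat)
  expect_identical(out$vat, x$seg$vat)
})

test_that("add followed by remove of the same region restores the masks", {
  x <- seg_for_edits()
  poly <- rbind(c(40, 40), c(40, 55), c(55, 55), c(55, 40))
  ed <- edit_script(edit_op(1, "VAT", "add", polygon = poly),
                    edit_op(1, "VAT", "remove", polygon = poly))
  out <- apply_edits(x$seg, ed)
  # removal deletes everything in the region, including pre-existing VAT,
  # so compare outside the region and emptiness inside
  region <- adiposeg:::edit_region_mask(ed[[1]], dim(x$seg$sat), 1)
  expect_identical(out$sat[, , 1][!region], x$seg$sat[, , 1][!region])
  expect_identical(sum(out$vat[, , 1][region]), 0L)
  expect_length(out$edits_applied, 2L)
})

test_that("adding a region claims its voxels exclusively for the target compartment", {
  x <- seg_for_edits()
  poly <- rbind(c(30, 30), c(30, 60), c(60, 60), c(60, 30))
  out <- apply_edits(x$seg, edit_script(edit_op(1, "SAT", "add", polygon = poly)))
  region <- adiposeg:::edit_region_mask(edit_op(1, "SAT", "add", polygon = poly),
                                        dim(out$sat), 1) & out$torso[, , 1] > 0
  expect_true(all(out$sat[, , 1][region] == 1L))
  expect_identical(sum(out$vat[, , 1][region]), 0L)
  adiposeg:::validate_voxa_seg(out)
})

test_that("removing the spinal region empties SAT and VAT of spine fat", {
  ph <- generate_phantom(small_spec(seed = 20, n_slices = 1))
  seg <- voxa(ph$image)
  sf <- ph$truth$spine_fat_mask[, , 1]
  # rectangle spanning the posterior spine area
  rows <- range(which(rowSums(sf) > 0)); cols <- range(which(colSums(sf) > 0))
  poly <- rbind(c(rows[1] - 1, cols[1] - 1), c(rows[1] - 1, cols[2] + 1),
                c(rows[2] + 1, cols[2] + 1), c(rows[2] + 1, cols[1] - 1))
  ed <- edit_script(edit_op(1, "SAT", "remove", polygon = poly),
                    edit_op(1, "VAT", "remove", polygon = poly))
  out <- apply_edits(seg, ed)
  expect_identical(sum(out$sat[, , 1] & sf), 0L)
  expect_identical(sum(out$vat[, , 1] & sf), 0L)
})

test_that("reassign moves voxels between SAT and VAT and preserves disjointness", {
  x <- seg_for_edits()
  vat_idx <- which(x$seg$vat[, , 1] > 0, arr.ind = TRUE)
  expect_gt(nrow(vat_idx), 0)
  ctr <- vat_idx[nrow(vat_idx) %/% 2L, ]
  poly <- rbind(ctr + c(-2, -2), ctr + c(-2, 2), ctr + c(2, 2), ctr + c(2, -2))
  out <- apply_edits(x$seg, edit_script(edit_op(1, "SAT", "reassign", polygon = poly)))
  region <- adiposeg:::edit_region_mask(edit_op(1, "SAT", "add", polygon = poly),
                                        dim(out$sat), 1)
  expect_identical(sum(out$vat[, , 1][region]), 0L)
  expect_gt(sum(out$sat[, , 1][region]), 0)
  expect_identical(sum(out$sat & out$vat), 0L)
  # total fat voxel count unchanged by reassignment
  expect_identical(sum(out$sat) + sum(out$vat), sum(x$seg$sat) + sum(x$seg$vat))
})

test_that("malformed edits are rejected with the offending index", {
  x <- seg_for_edits()
  out_poly <- rbind(c(-5, 10), c(-5, 20), c(5, 20))
  expect_error(apply_edits(x$seg, edit_script(edit_op(1, "SAT", "remove",
                                                      polygon = out_poly))),
               "edit 1: polygon outside grid")
  expect_error(apply_edits(x$seg, edit_script(edit_op(99, "SAT", "remove",
                                                      polygon = rbind(c(1, 1), c(1, 5), c(5, 5))))),
               "slice 99")
  bowtie <- rbind(c(10, 10), c(20, 20), c(10, 20), c(20, 10))
  expect_error(edit_op(1, "SAT", "add", polygon = bowtie), "self-intersecting")
})
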