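#' Bright adipose voxel identification within the torso
#'
#' Thresholds bright (adipose) voxels inside the torso mask, per slice. The
#' default threshold is Otsu computed on the intensities of torso voxels
#' only (a clean lean/fat bimodal sample, uncontaminated by air); a fixed
#' threshold may be supplied instead. Connected components smaller than
#' `min_component_vox` are discarded as speckle.
#'
#' @param stack a (normalized) [image_stack()].
#' @param torso torso mask from [extract_torso()].
#' @param params a [voxa_params()].
#' @return A binary mask array, a subset of `torso`, with attribute `"log"`.
#' @export
segment_fat <- function(stack, torso, params = voxa_params()) {
  stopifnot(inherits(stack, "image_stack"))
  torso <- check_mask(torso, stack, "segment_fat")
  d <- dim(stack$voxels)
  out <- array(0L, d)
  logs <- list()
  for (i in seq_len(d[3])) {
    sl <- stack$voxels[, , i]
    tm <- torso[, , i] > 0
    if (!any(tm))
      stopf("segment_fat: slice %d has an empty torso mask", i)
    thr <- if (params$fat_threshold_mode == "fixed") {
      check_fixed_threshold(params$fat_threshold, sl, "fat_threshold")
    } else {
      otsu_threshold(sl[tm])
    }
    fm <- (sl >= thr) & tm
    if (params$min_component_vox > 0L && any(fm)) {
      lab <- EBImage::bwlabel(fm * 1)
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < params$min_component_vox)
      if (length(drop)) fm[lab %in% drop] <- FALSE
    }
    out[, , i] <- as.integer(fm)
    logs[[i]] <- data.frame(stage = "fat", slice = i, voxels = sum(fm),
                            note = "", stringsAsFactors = FALSE)
  }
  attr(out, "log") <- do.call(rbind, logs)
  out
}

#' Separate subcutaneous from visceral fat by morphology
#'
#' Implements the morphological SAT/VAT separation, per slice: (1) the fat
#' mask is eroded by a disc of `erosion_radius_vox` to break thin bridges
#' between the subcutaneous ring and internal fat; (2) connected components
#' of the eroded mask are labelled; (3) components intersecting the band of
#' width `boundary_band_vox` just inside the torso boundary become SAT
#' seeds, all others VAT seeds; (4) seeds are restored to the full fat mask
#' by geodesic reconstruction (dilation constrained to the fat mask); (5)
#' fat voxels reachable from both classes — or from neither, e.g.
#' components erased entirely by the erosion — are assigned to the class
#' with the nearer seed under the Euclidean distance transform, with exact
#' ties going to SAT (conservative for the VAT/SAT ratio); (6) the non-VAT
#' compartment is the dark (non-fat) torso tissue enclosed by the inner
#' boundary of the SAT ring. SAT and VAT always partition the input fat
#' mask exactly.
#'
#' A fat component erased by the erosion in a slice where no seeds exist at
#' all is classified by direct boundary-band contact. If no component
#' touches the boundary band, the slice gets an empty SAT and a logged
#' warning (not an error).
#'
#' @param fat fat mask from [segment_fat()].
#' @param torso torso mask from [extract_torso()]; `fat` must be a subset.
#' @param params a [voxa_params()].
#' @param geometry an [image_stack()] supplying the geometry for the result.
#' @return A `voxa_seg` object: masks `sat`, `vat`, `nonvat`, `torso`,
#'   the `params`, an empty `edits_applied` script and a stage `log`.
#' @export
split_sat_vat <- function(fat, torso, params = voxa_params(), geometry = NULL) {
  if (is.null(dim(fat)) || length(dim(fat)) == 2L) dim(fat) <- c(dim(fat), 1L)
  torso <- check_mask(torso, NULL, "split_sat_vat")
  fat <- check_mask(fat, NULL, "split_sat_vat")
  if (!identical(dim(fat), dim(torso)))
    stopf("split_sat_vat: fat and torso masks differ in shape")
  if (any(fat > torso))
    stopf("split_sat_vat: fat mask is not a subset of the torso mask")
  d <- dim(fat)
  sat <- array(0L, d); vat <- array(0L, d); nonvat <- array(0L, d)
  kern_er <- disc_brush(params$erosion_radius_vox)
  logs <- list()
  for (i in seq_len(d[3])) {
    fm <- fat[, , i] > 0
    tm <- torso[, , i] > 0
    band <- tm & !(EBImage::erode(tm * 1, disc_brush(params$boundary_band_vox)) > 0)
    res <- split_slice(fm, tm, band, kern_er, params)
    sat[, , i] <- res$sat; vat[, , i] <- res$vat; nonvat[, , i] <- res$nonvat
    logs[[i]] <- data.frame(stage = "split", slice = i,
                            voxels = sum(fm), note = res$note,
                            stringsAsFactors = FALSE)
  }
  new_voxa_seg(sat, vat, nonvat, torso, params, geometry,
               log = do.call(rbind, logs))
}

split_slice <- function(fm, tm, band, kern_er, params) {
  if (!any(fm)) {
    z <- matrix(0L, nrow(fm), ncol(fm))
    return(list(sat = z, vat = z, nonvat = z, note = "empty fat mask"))
  }
  note <- ""
  er <- EBImage::erode(fm * 1, kern_er) > 0
  lab_fat <- EBImage::bwlabel(fm * 1)
  if (any(er)) {
    lab_seed <- EBImage::bwlabel(er * 1)
    seed_ids <- seq_len(max(lab_seed))
    touches <- unique(lab_seed[band & er])
    sat_seed <- er & (lab_seed %in% touches)
    vat_seed <- er & !(lab_seed %in% touches)
    if (length(touches) == 0L) note <- "no SAT found: no component touches the boundary band"
  } else {
    # erosion erased everything: classify whole components by band contact
    touch_ids <- unique(lab_fat[band & fm])
    sat_seed <- fm & (lab_fat %in% touch_ids)
    vat_seed <- fm & !(lab_fat %in% touch_ids)
    note <- "fat too thin for erosion; classified by direct band contact"
    if (length(touch_ids) == 0L) note <- "no SAT found: no component touches the boundary band"
  }

  # geodesic reconstruction: a fat component reachable from seeds of only
  # one class belongs to it wholesale; mixed or seedless components are
  # resolved voxel-wise by Euclidean distance to the nearest seed (ties to
  # SAT). Equivalent to reconstruct-by-dilation followed by the EDT rule,
  # and guarantees SAT u VAT == fat exactly.
  satm <- sat_seed
  vatm <- vat_seed
  unresolved <- fm & !satm & !vatm
  if (any(unresolved)) {
    comp_has_sat <- unique(lab_fat[satm])
    comp_has_vat <- unique(lab_fat[vatm])
    need_edt <- FALSE
    lab_un <- lab_fat[unresolved]
    to_sat <- lab_un %in% comp_has_sat & !(lab_un %in% comp_has_vat)
    to_vat <- lab_un %in% comp_has_vat & !(lab_un %in% comp_has_sat)
    idx <- which(unresolved)
    satm[idx[to_sat]] <- TRUE
    vatm[idx[to_vat]] <- TRUE
    rest <- idx[!(to_sat | to_vat)]
    if (length(rest)) {
      if (any(satm) && any(vatm)) {
        dsat <- EBImage::distmap(1 - sat_seed * 1)
        dvat <- EBImage::distmap(1 - vat_seed * 1)
        satm[rest] <- dsat[rest] <= dvat[rest]
        vatm[rest] <- !satm[rest]
      } else if (any(satm) || any(sat_seed)) {
        satm[rest] <- TRUE
      } else if (any(vatm)) {
        vatm[rest] <- TRUE
      } else {
        satm[rest] <- TRUE   # nothing to compare against; ties go to SAT
      }
    }
  }

  # non-VAT: dark tissue enclosed by the inner boundary of the SAT ring
  cavity <- (EBImage::fillHull(satm * 1) > 0) & !satm & tm
  nonvat <- cavity & !fm
  list(sat = matrix(as.integer(satm), nrow(fm)),
       vat = matrix(as.integer(vatm), nrow(fm)),
       nonvat = matrix(as.integer(nonvat), nrow(fm)),
       note = note)
}
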