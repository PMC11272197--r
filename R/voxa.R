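new_voxa_seg <- function(sat, vat, nonvat, torso, params, geometry,
                         log = NULL, edits = edit_script()) {
  res <- structure(list(sat = sat, vat = vat, nonvat = nonvat, torso = torso,
                        params = params, geometry = geometry,
                        edits_applied = edits,
                        log = if (is.null(log)) {
                          data.frame(stage = character(), slice = integer(),
                                     voxels = integer(), note = character())
                        } else log),
                   class = "voxa_seg")
  validate_voxa_seg(res)
  res
}

validate_voxa_seg <- function(res) {
  if (any(res$sat & res$vat) || any(res$sat & res$nonvat) ||
      any(res$vat & res$nonvat))
    stopf("voxa_seg: compartments are not pairwise disjoint")
  if (any((res$sat | res$vat | res$nonvat) > res$torso))
    stopf("voxa_seg: compartments are not contained in the torso")
  invisible(res)
}

#' Adipose tissue segmentation of an axial abdominal T1 stack
#'
#' Runs the full semi-automatic segmentation pipeline on an image stack:
#' intensity normalization ([normalize_stack()]), torso extraction by radial
#' region growing ([extract_torso()]), bright-voxel adipose identification
#' ([segment_fat()]), morphological SAT/VAT separation ([split_sat_vat()])
#' and, optionally, a scripted edit pass ([apply_edits()]) standing in for
#' interactive manual correction (e.g. removal of spinal-region fat).
#'
#' @param stack an [image_stack()].
#' @param params a [voxa_params()].
#' @param edits an optional [edit_script()].
#' @return A `voxa_seg` object holding the `sat`, `vat`, `nonvat` and
#'   `torso` masks, the parameters, the applied edits and a per-stage log.
#' @examples
#' ph <- generate_phantom(phantom_spec(n_slices = 2, grid_shape = c(96, 96),
#'                                     pixel_spacing_mm = c(4.5, 4.5)))
#' seg <- voxa(ph$image)
#' summary(seg)
#' @export
voxa <- function(stack, params = voxa_params(), edits = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  norm <- normalize_stack(stack, params)
  torso <- extract_torso(norm, params)
  fat <- segment_fat(norm, torso, params)
  res <- split_sat_vat(fat, torso, params, geometry = stack)
  res$log <- rbind(attr(torso, "log"), attr(fat, "log"), res$log)
  res$log <- res$log[order(res$log$slice), ]
  rownames(res$log) <- NULL
  if (!is.null(edits)) res <- apply_edits(res, edits)
  res
}

#' @export
print.voxa_seg <- function(x, ...) {
  d <- dim(x$sat)
  cat(sprintf("<voxa_seg> %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  torso %d, SAT %d, VAT %d, non-VAT %d voxels\n",
              sum(x$torso), sum(x$sat), sum(x$vat), sum(x$nonvat)))
  cat(sprintf("  %d edit%s applied\n", length(x$edits_applied),
              if (length(x$edits_applied) == 1) "" else "s"))
  invisible(x)
}

#' @export
summary.voxa_seg <- function(object, ...) {
  d <- dim(object$sat)
  per_slice <- data.frame(
    slice = seq_len(d[3]),
    torso_vox = apply(object$torso, 3, sum),
    sat_vox = apply(object$sat, 3, sum),
    vat_vox = apply(object$vat, 3, sum),
    nonvat_vox = apply(object$nonvat, 3, sum))
  out <- list(per_slice = per_slice,
              edits = length(object$edits_applied),
              geometry = object$geometry)
  class(out) <- "summary.voxa_seg"
  out
}

#' @export
print.summary.voxa_seg <- function(x, ...) {
  cat("Per-slice voxel counts:\n")
  print(x$per_slice, row.names = FALSE)
  if (!is.null(x$geometry)) {
    vv <- voxel_volume_mm3(x$geometry)
    cat(sprintf("voxel volume %.4g mm3; whole-stack SAT %.1f cm3, VAT %.1f cm3\n",
                vv, sum(x$per_slice$sat_vox) * vv / 1000,
                sum(x$per_slice$vat_vox) * vv / 1000))
  }
  invisible(x)
}

#' Display one segmented slice
#'
#' Shows the intensity slice in grey with SAT, VAT and non-VAT compartments
#' tinted.
#'
#' @param x a `voxa_seg` object (with geometry attached).
#' @param slice slice index to display.
#' @param ... ignored.
#' @export
plot.voxa_seg <- function(x, slice = 1L, ...) {
  if (is.null(x$geometry)) stopf("plot.voxa_seg: no geometry attached")
  sl <- x$geometry$voxels[, , slice]
  sl <- (sl - min(sl)) / max(1e-12, diff(range(sl)))
  img <- array(rep(sl, 3L), c(dim(sl), 3L))
  tint <- function(img, mask, rgb) {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[mask] <- 0.5 * pl[mask] + 0.5 * rgb[ch]
      img[, , ch] <- pl
    }
    img
  }
  img <- tint(img, x$sat[, , slice] > 0, c(1, 0.85, 0))
  img <- tint(img, x$vat[, , slice] > 0, c(1, 0.2, 0.2))
  img <- tint(img, x$nonvat[, , slice] > 0, c(0.2, 0.4, 1))
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("slice %d (SAT gold, VAT red, non-VAT blue)", slice))
  graphics::rasterImage(img, 0, 0, 1, 1)
  invisible(x)
}
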