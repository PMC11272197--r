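#' Compartment volumes over a slice window
#'
#' Converts the SAT and VAT masks of a segmentation to volumes by voxel
#' counting over an inclusive 1-based slice window, and forms the VAT/SAT
#' ratio. The default window, slices 4 to 11 of a 22-slice acquisition,
#' covers the eight slices used for abdominal adipose quantification.
#' Voxels are counted all-or-nothing (no partial-volume weighting), so
#' `sat_cm3` is exactly `count * voxel_volume_mm3 / 1000`. The ratio is
#' defined only when the SAT volume is positive; otherwise it is `NA` with
#' `ratio_defined = FALSE` (no division error).
#'
#' @param result a `voxa_seg` object.
#' @param geometry an [image_stack()] providing voxel geometry; defaults to
#'   the geometry attached to `result`.
#' @param window inclusive (first, last) slice indices; defaults to
#'   `c(4, 11)` clipped into the stack when the stack is shorter.
#' @return An object of class `volume_report`.
#' @export
compute_volumes <- function(result, geometry = result$geometry,
                            window = NULL) {
  stopifnot(inherits(result, "voxa_seg"))
  if (is.null(geometry)) stopf("compute_volumes: no geometry available")
  d <- dim(result$sat)
  if (is.null(window)) window <- c(min(4L, d[3]), min(11L, d[3]))
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2])
    stopf("compute_volumes: window must be (first, last) with first <= last")
  if (window[1] < 1L || window[2] > d[3])
    stopf("compute_volumes: window %d-%d outside stack (1..%d)",
          window[1], window[2], d[3])
  vox_mm3 <- voxel_volume_mm3(geometry)
  sl <- window[1]:window[2]
  per_slice <- data.frame(
    slice = sl,
    sat_area_mm2 = apply(result$sat[, , sl, drop = FALSE], 3, sum) *
      geometry$pixel_spacing_mm[1] * geometry$pixel_spacing_mm[2],
    vat_area_mm2 = apply(result$vat[, , sl, drop = FALSE], 3, sum) *
      geometry$pixel_spacing_mm[1] * geometry$pixel_spacing_mm[2])
  sat_cm3 <- sum(result$sat[, , sl]) * vox_mm3 / 1000
  vat_cm3 <- sum(result$vat[, , sl]) * vox_mm3 / 1000
  structure(list(sat_cm3 = sat_cm3,
                 vat_cm3 = vat_cm3,
                 vat_sat_ratio = if (sat_cm3 > 0) vat_cm3 / sat_cm3 else NA_real_,
                 ratio_defined = sat_cm3 > 0,
                 slice_window = window,
                 voxel_volume_mm3 = vox_mm3,
                 per_slice_breakdown = per_slice),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> slices %d-%d (voxel %.4g mm3)\n",
              x$slice_window[1], x$slice_window[2], x$voxel_volume_mm3))
  cat(sprintf("  Subcutaneous fat, cm3: %.2f\n", x$sat_cm3))
  cat(sprintf("  Visceral fat, cm3:     %.2f\n", x$vat_cm3))
  cat(sprintf("  VAT/SAT ratio:         %s\n",
              if (x$ratio_defined) sprintf("%.4f", x$vat_sat_ratio) else
                "undefined (no SAT)"))
  invisible(x)
}

#' @export
as.data.frame.volume_report <- function(x, ...) {
  data.frame(sat_cm3 = x$sat_cm3, vat_cm3 = x$vat_cm3,
             vat_sat_ratio = x$vat_sat_ratio,
             window_first = x$slice_window[1],
             window_last = x$slice_window[2])
}

#' Write volume reports as delimited text
#'
#' One record per subject, with explicit cm3 units in the headers.
#'
#' @param reports a named list of `volume_report` objects (names are subject
#'   identifiers), or a single report.
#' @param path output file path (CSV).
#' @return The path, invisibly.
#' @export
write_volume_reports <- function(reports, path) {
  if (inherits(reports, "volume_report")) reports <- list(subject = reports)
  rows <- do.call(rbind, lapply(reports, as.data.frame))
  rows <- cbind(subject = names(reports), rows)
  names(rows)[names(rows) == "sat_cm3"] <- "subcutaneous_fat_cm3"
  names(rows)[names(rows) == "vat_cm3"] <- "visceral_fat_cm3"
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}
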