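#' Axial image stack
#'
#' Container for an ordered stack of axial slices with acquisition geometry.
#' Slices are ordered caudal to cranial: slice 1 is the most caudal (at the
#' S1-L5 vertebral level in the acquisition the package targets) and indices
#' increase proximally. Voxel data are stored as a rows x cols x slices array.
#'
#' @param voxels numeric 3-D array (rows, cols, slices) of non-negative,
#'   finite intensities.
#' @param pixel_spacing_mm length-2 numeric, in-plane (row, col) spacing in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param metadata optional named list of acquisition metadata (e.g. TR, TE);
#'   carried along, never interpreted.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                        metadata = list()) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stopf("image_stack: voxels must be a 3-D array (rows, cols, slices)")
  if (!all(is.finite(voxels)))
    stopf("image_stack: intensities must be finite")
  if (any(voxels < 0))
    stopf("image_stack: intensities must be non-negative")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stopf("image_stack: pixel_spacing_mm must be two strictly positive numbers")
  slice_thickness_mm <- as.numeric(slice_thickness_mm)
  if (length(slice_thickness_mm) != 1L || slice_thickness_mm <= 0)
    stopf("image_stack: slice_thickness_mm must be a strictly positive scalar")
  structure(list(voxels = voxels,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d voxels, %d slice%s\n",
              d[1], d[2], d[3], if (d[3] == 1) "" else "s"))
  cat(sprintf("  pixel spacing %.3g x %.3g mm, slice thickness %.3g mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

voxel_volume_mm3 <- function(stack) {
  stack$pixel_spacing_mm[1] * stack$pixel_spacing_mm[2] * stack$slice_thickness_mm
}

# binary mask stack aligned to an image_stack: plain 0/1 integer array with
# the same dim; helper validates alignment
check_mask <- function(mask, stack = NULL, what = "mask") {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (!all(mask %in% c(0, 1)))
    stopf("%s: mask values must be 0/1", what)
  if (!is.null(stack) && !identical(dim(mask), dim(stack$voxels)))
    stopf("%s: mask shape does not match image stack", what)
  d <- dim(mask)
  attributes(mask) <- NULL
  dim(mask) <- d
  storage.mode(mask) <- "integer"
  mask
}

empty_mask <- function(stack) {
  array(0L, dim(stack$voxels))
}

slice_of <- function(arr, i) arr[, , i]
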