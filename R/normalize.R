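#' Segmentation parameters
#'
#' Tuning constants for the adipose segmentation pipeline. Defaults are the
#' package's reference configuration; all are per-slice 2-D settings because
#' the target acquisition is thick-slice (10 mm) 2-D, where 3-D morphology
#' would couple unrelated anatomy across slices.
#'
#' @param air_threshold_mode `"otsu"` (per-slice Otsu on the whole slice) or
#'   `"fixed"`.
#' @param fat_threshold_mode `"otsu_within_torso"` (Otsu on intensities inside
#'   the torso mask) or `"fixed"`.
#' @param air_threshold,fat_threshold numeric thresholds used in `"fixed"`
#'   modes; on the normalized \[0, 1\] scale when normalization is on.
#' @param erosion_radius_vox disc radius (voxels) of the erosion that breaks
#'   thin bridges between the subcutaneous ring and internal fat.
#' @param dilation_radius_vox disc radius (voxels) for the geodesic
#'   reconstruction that restores eroded voxels.
#' @param boundary_band_vox width (voxels) of the band inside the torso
#'   boundary; eroded fat components touching it are seeded as SAT.
#' @param min_component_vox fat components smaller than this are discarded
#'   as speckle.
#' @param ray_stop_run number of consecutive below-threshold voxels that
#'   terminates a radial ray during torso growing.
#' @param n_rays number of radial directions for torso growing (kept a
#'   multiple of 4 so that axis-aligned rotations map rays onto rays).
#' @param normalization `"on"` or `"off"`.
#' @param norm_degree polynomial degree of the per-slice log-bias model.
#' @param norm_tol,norm_maxit fixed-point tolerance and iteration cap for
#'   normalization.
#' @return An object of class `voxa_params`.
#' @export
voxa_params <- function(air_threshold_mode = c("otsu", "fixed"),
                        fat_threshold_mode = c("otsu_within_torso", "fixed"),
                        air_threshold = NULL,
                        fat_threshold = NULL,
                        erosion_radius_vox = 2L,
                        dilation_radius_vox = 2L,
                        boundary_band_vox = 3L,
                        min_component_vox = 5L,
                        ray_stop_run = 3L,
                        n_rays = 360L,
                        normalization = c("on", "off"),
                        norm_degree = 2L,
                        norm_tol = 1e-9,
                        norm_maxit = 40L) {
  p <- list(air_threshold_mode = match.arg(air_threshold_mode),
            fat_threshold_mode = match.arg(fat_threshold_mode),
            air_threshold = air_threshold,
            fat_threshold = fat_threshold,
            erosion_radius_vox = as.integer(erosion_radius_vox),
            dilation_radius_vox = as.integer(dilation_radius_vox),
            boundary_band_vox = as.integer(boundary_band_vox),
            min_component_vox = as.integer(min_component_vox),
            ray_stop_run = as.integer(ray_stop_run),
            n_rays = as.integer(n_rays),
            normalization = match.arg(normalization),
            norm_degree = as.integer(norm_degree),
            norm_tol = norm_tol,
            norm_maxit = as.integer(norm_maxit))
  if (p$erosion_radius_vox < 1L || p$dilation_radius_vox < 1L ||
      p$boundary_band_vox < 1L)
    stopf("voxa_params: radii and boundary band must be >= 1 voxel")
  if (p$min_component_vox < 0L)
    stopf("voxa_params: min_component_vox must be >= 0")
  if (p$air_threshold_mode == "fixed" && is.null(p$air_threshold))
    stopf("voxa_params: air_threshold required in fixed mode")
  if (p$fat_threshold_mode == "fixed" && is.null(p$fat_threshold))
    stopf("voxa_params: fat_threshold required in fixed mode")
  if (p$n_rays %% 4L != 0L)
    stopf("voxa_params: n_rays must be a multiple of 4")
  class(p) <- "voxa_params"
  p
}

# 2-D polynomial basis of the given degree in centred [-1,1] coordinates;
# the spanned space is invariant under 90-degree grid rotations.
poly_basis <- function(nr, nc, degree) {
  u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  cols <- list(rep(1, nr * nc))
  for (d in seq_len(degree)) {
    for (i in 0:d) cols[[length(cols) + 1L]] <- as.vector(u)^(d - i) * as.vector(v)^i
  }
  do.call(cbind, cols)
}

# One flatten + stretch pass on a single slice. The bias field is estimated
# on the log scale over tissue voxels (air excluded) as a low-order
# polynomial surface shared by the two tissue classes, with a free per-class
# level offset so the surface tracks the multiplicative bias rather than the
# fat/lean anatomy. The surface (the "heavily smoothed copy" of the slice)
# then divides the whole slice on the linear scale, which leaves exact zeros
# untouched, and a 1st/99th-percentile contrast stretch with type-1
# quantiles maps the result to [0, 1].
normalize_pass <- function(sl, X) {
  t1 <- otsu_threshold(sl)
  fat <- sl >= t1
  lean <- !fat & sl >= air_threshold(sl, t1)
  # guard against the air class leaking into the fit on near-binary slices:
  # lean tissue must sit at a plausible fraction of the fat level
  if (any(lean) &&
      stats::median(sl[lean]) < 0.15 * stats::median(sl[fat]))
    lean[] <- FALSE
  tissue <- fat | lean
  # shared bias surface with a per-class level offset: log y = poly + b*lean
  Xa <- cbind(X, as.numeric(lean))
  beta <- stats::lm.fit(Xa[tissue, , drop = FALSE], log(sl[tissue]))$coefficients
  beta[is.na(beta)] <- 0
  fit <- matrix(X %*% beta[-length(beta)], nrow(sl), ncol(sl))
  sl2 <- sl * exp(mean(fit[fat]) - fit)
  q1 <- quantile1(sl2, 0.01)
  q99 <- quantile1(sl2, 0.99)
  if (q99 - q1 <= 0) return(NULL)
  pmin(pmax((sl2 - q1) / (q99 - q1), 0), 1)
}

#' Intensity normalization of an image stack
#'
#' Per slice, brightens dark intensities and darkens bright ones by (i)
#' flattening the multiplicative bias field — dividing the slice by a heavily
#' smoothed copy of itself, modelled as the exponential of a low-order
#' polynomial fit to the log intensities — and (ii) a percentile contrast
#' stretch mapping the 1st percentile to 0 and the 99th to 1, clipping
#' outside. The flatten/stretch pair is iterated to its fixed point so the
#' whole operation is idempotent: renormalizing a normalized stack changes no
#' voxel by more than the convergence tolerance.
#'
#' @param stack an [image_stack()].
#' @param params a [voxa_params()]; `normalization = "off"` returns the input
#'   unchanged.
#' @return An [image_stack()] with per-slice intensities in \[0, 1\].
#' @export
normalize_stack <- function(stack, params = voxa_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (params$normalization == "off") return(stack)
  out <- stack$voxels
  X <- poly_basis(dim(out)[1], dim(out)[2], params$norm_degree)
  for (i in seq_len(n_slices(stack))) {
    sl <- out[, , i]
    if (max(sl) - min(sl) <= 0 ||
        quantile1(sl, 0.99) - quantile1(sl, 0.01) <= 0)
      stopf("normalize_stack: slice %d has zero dynamic range", i)
    for (it in seq_len(params$norm_maxit)) {
      sl2 <- normalize_pass(sl, X)
      if (is.null(sl2))
        stopf("normalize_stack: slice %d has zero dynamic range", i)
      delta <- max(abs(sl2 - sl))
      sl <- sl2
      if (delta < params$norm_tol) break
    }
    out[, , i] <- sl
  }
  image_stack(out, stack$pixel_spacing_mm, stack$slice_thickness_mm,
              stack$metadata)
}
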