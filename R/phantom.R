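#' Specification of a synthetic abdominal MRI phantom
#'
#' Describes a schematic axial abdominal T1 phantom: an elliptical torso with
#' a bright subcutaneous fat (SAT) ring, a lean-tissue cavity containing
#' bright visceral fat (VAT) blobs, dark organ regions (lean intensity, kept
#' free of VAT), and an optional posterior spine structure (lean vertebral
#' body plus small paraspinal fat pockets). Intensities follow T1 fl2d
#' contrast: fat bright, lean tissue intermediate, air dark. Rician noise and
#' a multiplicative low-order bias field are applied after compositing.
#'
#' Default geometry emulates the acquisition the package targets: 22 axial
#' slices of 10 mm starting at S1-L5, with in-plane size chosen so that SAT
#' and VAT volumes over the standard 8-slice analysis window land near
#' population-scale values (SAT on the order of 1.5 L, VAT/SAT ratio ~0.4).
#' The in-plane matrix and spacing are artifact choices and fully
#' configurable.
#'
#' @param grid_shape in-plane voxels (rows, cols).
#' @param n_slices number of axial slices.
#' @param pixel_spacing_mm in-plane (row, col) voxel spacing in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param torso_ellipse list with `semi_axes_mm` (row, col), optional
#'   `center_mm` (default grid centre) and `taper` (linear scale increase
#'   from slice 1 to the last slice).
#' @param sat_ring_thickness_mm thickness of the subcutaneous fat ring in mm.
#' @param vat_blob_params list: `n` blobs, `r_mm` in-plane semi-axis range,
#'   `z_mm` through-plane semi-axis range, `margin_mm` minimum clearance from
#'   the inner SAT boundary. `n = 0` gives a VAT-free phantom.
#' @param organ_params list: `n` organs and `r_mm` semi-axis range; organs are
#'   lean-intensity ellipsoids in the cavity that exclude VAT.
#' @param spine_params list with `body_mm` (row, col semi-axes of the
#'   vertebral body), `pocket_r_mm` (paraspinal fat pocket radius) and
#'   `pocket_offset_mm`; `NULL` disables the spine structure.
#' @param intensity_levels named numeric: mean intensities for `air`, `lean`,
#'   `fat`; must satisfy fat > lean > air.
#' @param noise_sigma Rician noise scale, as a fraction of the fat level.
#' @param bias_field_amplitude amplitude of the per-slice multiplicative
#'   second-order polynomial bias field, in `[0, 1)`.
#' @param seed integer RNG seed; all randomness in generation flows from it.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L),
                         n_slices = 22L,
                         pixel_spacing_mm = c(3.5, 3.5),
                         slice_thickness_mm = 10,
                         torso_ellipse = list(semi_axes_mm = c(110, 150),
                                              center_mm = NULL,
                                              taper = 0.05),
                         sat_ring_thickness_mm = 25,
                         vat_blob_params = list(n = 25L, r_mm = c(14, 28),
                                                z_mm = c(15, 50),
                                                margin_mm = 8),
                         organ_params = list(n = 2L, r_mm = c(18, 35)),
                         spine_params = list(body_mm = c(14, 16),
                                             pocket_r_mm = 4,
                                             pocket_offset_mm = 26),
                         intensity_levels = c(air = 30, lean = 300, fat = 1000),
                         noise_sigma = 0.05,
                         bias_field_amplitude = 0.15,
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         n_slices = as.integer(n_slices),
                         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                         slice_thickness_mm = as.numeric(slice_thickness_mm),
                         torso_ellipse = torso_ellipse,
                         sat_ring_thickness_mm = sat_ring_thickness_mm,
                         vat_blob_params = vat_blob_params,
                         organ_params = organ_params,
                         spine_params = spine_params,
                         intensity_levels = intensity_levels,
                         noise_sigma = noise_sigma,
                         bias_field_amplitude = bias_field_amplitude,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lv <- spec$intensity_levels
  if (!all(c("air", "lean", "fat") %in% names(lv)))
    stopf("phantom_spec: intensity_levels must name air, lean and fat")
  if (!(lv["fat"] > lv["lean"] && lv["lean"] > lv["air"]))
    stopf("phantom_spec: intensity_levels must satisfy fat > lean > air")
  if (any(spec$pixel_spacing_mm <= 0))
    stopf("phantom_spec: pixel_spacing_mm must be strictly positive")
  if (spec$slice_thickness_mm <= 0)
    stopf("phantom_spec: slice_thickness_mm must be strictly positive")
  if (spec$n_slices < 1L)
    stopf("phantom_spec: n_slices must be at least 1")
  if (spec$noise_sigma < 0)
    stopf("phantom_spec: noise_sigma must be non-negative")
  if (spec$bias_field_amplitude < 0 || spec$bias_field_amplitude >= 1)
    stopf("phantom_spec: bias_field_amplitude must lie in [0, 1)")
  te <- spec$torso_ellipse
  taper <- if (is.null(te$taper)) 0 else te$taper
  smax <- max(1, 1 + taper)
  half_extent <- (spec$grid_shape / 2 - 2) * spec$pixel_spacing_mm
  if (any(te$semi_axes_mm * smax >= half_extent))
    stopf(paste("phantom_spec: torso_ellipse does not fit inside the grid",
                "with a 2-voxel air margin"))
  if (spec$sat_ring_thickness_mm <= 0 ||
      spec$sat_ring_thickness_mm >= min(te$semi_axes_mm))
    stopf("phantom_spec: sat_ring_thickness_mm must be positive and thinner than the torso")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d x %d slices @ %.3gx%.3g mm / %.3g mm, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], x$n_slices,
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, x$seed))
  cat(sprintf("  torso %.0fx%.0f mm, SAT ring %.3g mm, %d VAT blobs, noise %.3g, bias %.3g\n",
              2 * x$torso_ellipse$semi_axes_mm[1], 2 * x$torso_ellipse$semi_axes_mm[2],
              x$sat_ring_thickness_mm, x$vat_blob_params$n,
              x$noise_sigma, x$bias_field_amplitude))
  invisible(x)
}

# label codes used while compositing
.LBL <- c(air = 0L, lean = 1L, sat = 2L, vat = 3L, spine_fat = 4L)

#' Generate a synthetic abdominal MRI phantom with ground truth
#'
#' Composites the phantom described by `spec` into a noise-free label map,
#' derives ground-truth masks and volumes from it, then applies the bias
#' field and Rician noise to produce the observed image. The truth masks are
#' always the noise-free labels. Identical specs (including seed) give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (an [image_stack()]) and `truth`
#'   (class `phantom_truth`: `torso_mask`, `sat_mask`, `vat_mask`,
#'   `spine_fat_mask`, exact voxel-count volumes `sat_volume_cm3` /
#'   `vat_volume_cm3` over `slice_window`).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]; ns <- spec$n_slices
  spr <- spec$pixel_spacing_mm[1]; spc <- spec$pixel_spacing_mm[2]
  te <- spec$torso_ellipse
  center <- if (is.null(te$center_mm)) c(0, 0) else te$center_mm
  taper <- if (is.null(te$taper)) 0 else te$taper

  # voxel-centre coordinates in mm, origin at grid centre; rows are the
  # anterior->posterior axis, columns left->right
  xr <- ((seq_len(nr)) - (nr + 1) / 2) * spr
  xc <- ((seq_len(nc)) - (nc + 1) / 2) * spc
  R <- matrix(xr, nr, nc) - center[1]
  C <- matrix(xc, nr, nc, byrow = TRUE) - center[2]

  labels <- array(.LBL["air"], c(nr, nc, ns))
  scl <- if (ns > 1) 1 + taper * (seq_len(ns) - 1) / (ns - 1) else 1

  inner_ax <- function(s) te$semi_axes_mm * s - spec$sat_ring_thickness_mm
  for (i in seq_len(ns)) {
    ax <- te$semi_axes_mm * scl[i]
    axi <- inner_ax(scl[i])
    din <- (R / axi[1])^2 + (C / axi[2])^2
    dout <- (R / ax[1])^2 + (C / ax[2])^2
    sl <- matrix(.LBL["air"], nr, nc)
    sl[dout <= 1] <- .LBL["sat"]
    sl[din <= 1] <- .LBL["lean"]
    labels[, , i] <- sl
  }

  zc <- (seq_len(ns) - (ns + 1) / 2) * spec$slice_thickness_mm
  height <- ns * spec$slice_thickness_mm

  # paint a 3-D ellipsoid into `labels` with label `code`, restricted to
  # voxels currently labelled `over`
  paint_ellipsoid <- function(ctr, semi, code, over) {
    zrel <- (zc - ctr[3]) / semi[3]
    for (i in which(abs(zrel) < 1)) {
      rad <- sqrt(1 - zrel[i]^2)
      d <- (((R + center[1]) - ctr[1]) / (semi[1] * rad))^2 +
           (((C + center[2]) - ctr[2]) / (semi[2] * rad))^2
      sl <- labels[, , i]
      sl[d <= 1 & sl %in% over] <- code
      labels[, , i] <<- sl
    }
  }
  # TRUE iff the full in-plane extent of an ellipsoid stays `margin` mm
  # inside the cavity (inner SAT boundary) on every slice it touches
  fits_cavity <- function(ctr, semi, margin) {
    zrel <- (zc - ctr[3]) / semi[3]
    for (i in which(abs(zrel) < 1)) {
      axi <- inner_ax(scl[i]) - margin
      if (any(axi <= 0)) return(FALSE)
      rad <- sqrt(1 - zrel[i]^2)
      # conservative: bounding box corner of the blob must satisfy the
      # ellipse inequality
      dr <- abs(ctr[1] - center[1]) + semi[1] * rad
      dc <- abs(ctr[2] - center[2]) + semi[2] * rad
      if ((dr / axi[1])^2 + (dc / axi[2])^2 > 1) return(FALSE)
    }
    TRUE
  }

  organ_boxes <- list()   # exclusion regions for VAT placement
  with_seed(spec$seed, {
    # organs: lean ellipsoids (no intensity contrast with cavity background,
    # but VAT must avoid them)
    op <- spec$organ_params
    if (!is.null(op) && op$n > 0) {
      for (k in seq_len(op$n)) {
        for (try in 1:50) {
          semi <- c(runif(2, op$r_mm[1], op$r_mm[2]), runif(1, height / 4, height / 2))
          ctr <- c(runif(1, -0.35, 0.1) * te$semi_axes_mm[1] + center[1],
                   runif(1, -0.4, 0.4) * te$semi_axes_mm[2] + center[2],
                   runif(1, zc[1], zc[length(zc)]))
          if (fits_cavity(ctr, semi, 2)) {
            organ_boxes[[length(organ_boxes) + 1L]] <- list(ctr = ctr, semi = semi)
            break
          }
        }
      }
    }

    # spine structure: lean vertebral body at the posterior inner wall plus
    # two small paraspinal fat pockets beside it
    spn <- spec$spine_params
    spine_ctr <- NULL
    if (!is.null(spn)) {
      ax1 <- inner_ax(1)
      spine_ctr <- c(center[1] + ax1[1] - spn$body_mm[1] - 2, center[2])
      paint_ellipsoid(c(spine_ctr, 0), c(spn$body_mm, height), .LBL["lean"],
                      over = .LBL["lean"])
    }

    vp <- spec$vat_blob_params
    nb <- if (is.null(vp)) 0L else vp$n
    if (nb > 0) {
      clear_of <- function(ctr, semi, boxes, gap) {
        for (b in boxes) {
          if (all(abs(ctr - b$ctr) < semi + b$semi + gap)) return(FALSE)
        }
        TRUE
      }
      spine_boxes <- if (!is.null(spine_ctr)) {
        list(list(ctr = c(spine_ctr, 0),
                  semi = c(spn$body_mm[1] + spn$pocket_r_mm * 2 + 4,
                           spn$pocket_offset_mm + spn$pocket_r_mm + 4, height)))
      } else list()
      for (k in seq_len(nb)) {
        for (try in 1:80) {
          semi <- c(runif(2, vp$r_mm[1], vp$r_mm[2]),
                    runif(1, vp$z_mm[1], vp$z_mm[2]))
          ctr <- c(runif(1, -0.7, 0.7) * te$semi_axes_mm[1] + center[1],
                   runif(1, -0.7, 0.7) * te$semi_axes_mm[2] + center[2],
                   runif(1, zc[1], zc[length(zc)]))
          if (fits_cavity(ctr, semi, vp$margin_mm) &&
              clear_of(ctr, semi, organ_boxes, 4) &&
              clear_of(ctr, semi, spine_boxes, 0)) {
            paint_ellipsoid(ctr, semi, .LBL["vat"], over = .LBL["lean"])
            break
          }
        }
      }
    }

    if (!is.null(spn)) {
      for (sgn in c(-1, 1)) {
        pk <- c(spine_ctr[1] - 2, spine_ctr[2] + sgn * spn$pocket_offset_mm)
        paint_ellipsoid(c(pk, 0), c(spn$pocket_r_mm, spn$pocket_r_mm, height),
                        .LBL["spine_fat"], over = .LBL["lean"])
      }
    }

    # compositing done: freeze truth, then corrupt the observed image
    lv <- spec$intensity_levels
    img <- array(lv[["air"]], dim(labels))
    img[labels == .LBL["lean"]] <- lv[["lean"]]
    img[labels %in% .LBL[c("sat", "vat", "spine_fat")]] <- lv[["fat"]]

    if (spec$bias_field_amplitude > 0) {
      U <- matrix(seq(-1, 1, length.out = nr), nr, nc)
      V <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
      for (i in seq_len(ns)) {
        cf <- rnorm(5)
        g <- cf[1] * U + cf[2] * V + cf[3] * U * V +
          cf[4] * (U^2 - 1 / 3) + cf[5] * (V^2 - 1 / 3)
        g <- g / max(abs(g))
        img[, , i] <- img[, , i] * (1 + spec$bias_field_amplitude * g)
      }
    }
    if (spec$noise_sigma > 0) {
      s <- spec$noise_sigma * lv[["fat"]]
      img <- sqrt((img + rnorm(length(img), 0, s))^2 +
                    rnorm(length(img), 0, s)^2)
      dim(img) <- dim(labels)
    }
  })

  stack <- image_stack(img, spec$pixel_spacing_mm, spec$slice_thickness_mm,
                       metadata = list(TR_ms = 286, TE_ms = 3.34,
                                       sequence = "T1 fl2d (synthetic phantom)"))
  window <- if (ns >= 11L) c(4L, 11L) else c(1L, ns)
  vox_cm3 <- voxel_volume_mm3(stack) / 1000
  wsl <- window[1]:window[2]
  truth <- structure(list(
    torso_mask = check_mask((labels != .LBL["air"]) * 1L),
    sat_mask = check_mask((labels == .LBL["sat"]) * 1L),
    vat_mask = check_mask((labels == .LBL["vat"]) * 1L),
    spine_fat_mask = check_mask((labels == .LBL["spine_fat"]) * 1L),
    slice_window = window,
    voxel_volume_mm3 = voxel_volume_mm3(stack)), class = "phantom_truth")
  truth$sat_volume_cm3 <- sum(truth$sat_mask[, , wsl]) *
    truth$voxel_volume_mm3 / 1000
  truth$vat_volume_cm3 <- sum(truth$vat_mask[, , wsl]) *
    truth$voxel_volume_mm3 / 1000
  list(image = stack, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> window %d-%d: SAT %.1f cm3, VAT %.1f cm3\n",
              x$slice_window[1], x$slice_window[2],
              x$sat_volume_cm3, x$vat_volume_cm3))
  invisible(x)
}
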