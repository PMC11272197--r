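#' Torso extraction by radial region growing
#'
#' Per slice: voxels are classified air/tissue (per-slice hierarchical Otsu
#' by default, or a fixed threshold), the bounding box of tissue voxels is
#' computed, and a region is grown from its centroid along radial rays.
#' Rays are discrete: every voxel is assigned to one of `n_rays` angular
#' sectors around the centroid and visited in order of increasing radius; a
#' ray stops at the first run of `ray_stop_run` consecutive air voxels. The
#' grown region is then morphologically closed, hole-filled, and reduced to
#' its largest connected component, so the returned torso mask is simply
#' connected with no interior holes.
#'
#' If the centroid itself falls on air (e.g. a hollow slice) the method
#' falls back to the largest connected tissue component containing the
#' bounding-box centre, recording a warning in the attached log. A slice
#' with no tissue voxels at all is an error.
#'
#' @param stack a (normalized) [image_stack()].
#' @param params a [voxa_params()].
#' @return A binary mask array (same dim as the stack) with attribute
#'   `"log"`, a data.frame of per-slice stage records.
#' @export
extract_torso <- function(stack, params = voxa_params()) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  out <- array(0L, d)
  logs <- list()
  for (i in seq_len(d[3])) {
    sl <- stack$voxels[, , i]
    thr <- if (params$air_threshold_mode == "fixed") {
      check_fixed_threshold(params$air_threshold, sl, "air_threshold")
    } else {
      tryCatch(air_threshold(sl),
               error = function(e) Inf)  # flat slice: nothing above air
    }
    fg <- sl >= thr
    if (!any(fg))
      stopf("extract_torso: slice %d contains no above-threshold voxels", i)
    rows <- range(which(rowSums(fg) > 0))
    cols <- range(which(colSums(fg) > 0))
    cr <- (rows[1] + rows[2]) / 2
    cc <- (cols[1] + cols[2]) / 2
    note <- ""
    m <- radial_grow(fg, cr, cc, params$n_rays, params$ray_stop_run)
    if (sum(m & fg) < 0.5 * sum(fg)) {
      # the centroid sits on background (e.g. a hollow slice): radial rays
      # die immediately, so fall back to the largest connected tissue
      # component, preferring the one under the bounding-box centre
      lab <- EBImage::bwlabel(fg)
      rs <- c(floor(cr), ceiling(cr)); cs <- c(floor(cc), ceiling(cc))
      ctr_lab <- setdiff(unique(as.vector(lab[rs, cs])), 0L)
      if (length(ctr_lab) == 0L) {
        sizes <- tabulate(lab[lab > 0])
        ctr_lab <- which.max(sizes)
        note <- "centroid on background; using largest tissue component"
      } else {
        sizes <- tabulate(lab[lab > 0])
        ctr_lab <- ctr_lab[which.max(sizes[ctr_lab])]
        note <- "centroid on background; using component at bounding-box centre"
      }
      m <- lab == ctr_lab
    }
    m <- EBImage::closing(m * 1, disc_brush(2L))
    m <- EBImage::fillHull(m)
    lab <- EBImage::bwlabel(m)
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0])
      m <- (lab == which.max(sizes)) * 1
      m <- EBImage::fillHull(m)
    }
    out[, , i] <- as.integer(m > 0)
    logs[[i]] <- data.frame(stage = "torso", slice = i,
                            voxels = sum(out[, , i]),
                            note = note, stringsAsFactors = FALSE)
  }
  attr(out, "log") <- do.call(rbind, logs)
  out
}

check_fixed_threshold <- function(thr, sl, what) {
  if (is.null(thr)) stopf("%s: fixed threshold not supplied", what)
  if (thr < min(sl) || thr > max(sl))
    warnf("%s %.4g lies outside the observed intensity range [%.4g, %.4g]",
          what, thr, min(sl), max(sl))
  thr
}

# Discrete radial region growing. Voxels are binned by angle around
# (cr, cc) into n_rays sectors and walked outward by radius; a sector stops
# accepting at the first run of `stop_run` consecutive background voxels.
# Ordering within a sector is by (radius, signed angular offset), a total
# order that is exactly preserved under 90-degree grid rotations when
# n_rays is a multiple of 4.
radial_grow <- function(fg, cr, cc, n_rays, stop_run) {
  nr <- nrow(fg); nc <- ncol(fg)
  dr <- as.vector(row(fg)) - cr
  dc <- as.vector(col(fg)) - cc
  rad <- sqrt(dr^2 + dc^2)
  # Sector assignment is made exactly equivariant under 90-degree grid
  # rotations: each direction is first rotated into the canonical quadrant
  # (a > 0, b >= 0) by exact (swap, negate) quarter turns, the angle is
  # binned inside that quadrant, and the quarter-turn count offsets the
  # sector index. A rotated image therefore yields identically binned rays.
  nq <- n_rays %/% 4L
  a <- dr; b <- dc
  q <- integer(length(a))
  for (turn in 1:3) {
    todo <- !(a > 0 & b >= 0) & !(a == 0 & b == 0)
    if (!any(todo)) break
    tmp <- a[todo]
    a[todo] <- b[todo]
    b[todo] <- -tmp
    q[todo] <- q[todo] + 1L
  }
  theta <- atan2(b, a)                      # [0, pi/2) in the canonical quadrant
  bin <- pmin(floor(theta / (pi / 2) * nq), nq - 1L)
  sector <- q * nq + bin
  off <- theta - (bin + 0.5) * (pi / 2) / nq  # offset from sector centre
  # Walk each sector outward over its tissue voxels only. A ray stops at
  # the first radial air gap of >= stop_run voxel units (the sampled-ray
  # equivalent of a run of stop_run consecutive background voxels); the
  # sector's torso extent is the last tissue radius accepted before the
  # gap, and every voxel inside that extent (tissue or small interior gap)
  # belongs to the region.
  keep <- logical(nr * nc)
  fgv <- as.vector(fg)
  o <- order(sector, rad, off, method = "radix")
  o_fg <- o[fgv[o]]
  sec_fg <- sector[o_fg]
  starts <- c(1L, which(diff(sec_fg) != 0) + 1L, length(o_fg) + 1L)
  r_stop <- rep(-1, n_rays)   # sector extent; -1 = nothing accepted
  for (s in seq_len(length(starts) - 1L)) {
    idx <- o_fg[starts[s]:(starts[s + 1L] - 1L)]
    last_fg <- 0
    for (j in idx) {
      if (rad[j] - last_fg >= stop_run) break
      last_fg <- rad[j]
    }
    r_stop[sector[idx[1]] + 1L] <- last_fg
  }
  keep <- rad <= r_stop[sector + 1L]
  matrix(keep, nr, nc)
}
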