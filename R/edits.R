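#' Scripted manual edits
#'
#' Interactive mask editing is replaced by an ordered, reproducible edit
#' script: each operation names a slice, a target compartment, an action and
#' a region. `add` inserts the region's voxels into the target compartment
#' (removing them from any other compartment first; voxels outside the torso
#' are ignored so compartments stay inside it), `remove` deletes them from
#' the target, and `reassign` moves region voxels from the other fat
#' compartment into the target.
#'
#' @param slice 1-based slice index.
#' @param compartment `"SAT"` or `"VAT"`.
#' @param action `"add"`, `"remove"` or `"reassign"`.
#' @param polygon an n x 2 matrix of (row, col) voxel coordinates tracing a
#'   simple (non-self-intersecting) polygon; voxels whose centres fall
#'   inside are affected. Alternatively supply `mask`.
#' @param mask a binary slice mask (same in-plane shape as the stack).
#' @return An `edit_op` / `edit_script` object.
#' @export
edit_op <- function(slice, compartment = c("SAT", "VAT"),
                    action = c("add", "remove", "reassign"),
                    polygon = NULL, mask = NULL) {
  compartment <- match.arg(compartment)
  action <- match.arg(action)
  if (is.null(polygon) == is.null(mask))
    stopf("edit_op: supply exactly one of polygon or mask")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2L || nrow(polygon) < 3L)
      stopf("edit_op: polygon must be an n x 2 matrix with n >= 3")
    if (polygon_self_intersects(polygon))
      stopf("edit_op: polygon is self-intersecting")
  }
  structure(list(slice = as.integer(slice), compartment = compartment,
                 action = action, polygon = polygon, mask = mask),
            class = "edit_op")
}

#' @param ... for `edit_script()`: `edit_op` objects (or a single list of
#'   them).
#' @rdname edit_op
#' @export
edit_script <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && !inherits(ops[[1]], "edit_op")) ops <- ops[[1]]
  if (!all(vapply(ops, inherits, TRUE, "edit_op")))
    stopf("edit_script: all elements must be edit_op objects")
  structure(ops, class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("<edit_script> %d operation%s\n", length(x),
              if (length(x) == 1) "" else "s"))
  for (i in seq_along(x)) {
    op <- x[[i]]
    cat(sprintf("  %d: %s %s on slice %d (%s)\n", i, op$action,
                op$compartment, op$slice,
                if (is.null(op$polygon)) "mask" else
                  sprintf("polygon, %d vertices", nrow(op$polygon))))
  }
  invisible(x)
}

# segment-pair crossing test for polygon simplicity; shared endpoints of
# adjacent segments are not crossings
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (isTRUE(all.equal(p[1, ], p[n, ]))) { p <- p[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 4L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  crosses <- function(a, b) {
    d <- function(p1, p2, p3) {
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    }
    a1 <- a[1:2]; a2 <- a[3:4]; b1 <- b[1:2]; b2 <- b[3:4]
    d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
    d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next      # adjacent around the wrap
      if (crosses(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

# rasterize an edit region to a logical slice mask
edit_region_mask <- function(op, d, edit_index) {
  if (!is.null(op$mask)) {
    m <- op$mask
    if (!identical(dim(m), d[1:2]))
      stopf("edit %d: mask shape does not match the stack", edit_index)
    return(m > 0)
  }
  p <- op$polygon
  if (any(p[, 1] < 0.5 | p[, 1] > d[1] + 0.5 | p[, 2] < 0.5 | p[, 2] > d[2] + 0.5))
    stopf("edit %d: polygon outside grid", edit_index)
  ctr <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  inside <- mgcv::in.out(rbind(p, p[1, ]), ctr)
  matrix(inside, d[1], d[2])
}

#' Apply an edit script to a segmentation result
#'
#' Edits are applied in order; the returned result records them in
#' `edits_applied`. An empty script returns the input unchanged.
#'
#' @param result a `voxa_seg` object.
#' @param edits an [edit_script()].
#' @return The edited `voxa_seg`.
#' @export
apply_edits <- function(result, edits) {
  stopifnot(inherits(result, "voxa_seg"))
  if (inherits(edits, "edit_op")) edits <- edit_script(edits)
  stopifnot(inherits(edits, "edit_script"))
  if (length(edits) == 0L) return(result)
  d <- dim(result$sat)
  for (k in seq_along(edits)) {
    op <- edits[[k]]
    if (op$slice < 1L || op$slice > d[3])
      stopf("edit %d: slice %d outside stack (1..%d)", k, op$slice, d[3])
    region <- edit_region_mask(op, d, k)
    i <- op$slice
    tgt <- tolower(op$compartment)
    oth <- if (tgt == "sat") "vat" else "sat"
    switch(op$action,
      add = {
        region <- region & result$torso[, , i] > 0
        result[[oth]][, , i][region] <- 0L
        result$nonvat[, , i][region] <- 0L
        result[[tgt]][, , i][region] <- 1L
      },
      remove = {
        result[[tgt]][, , i][region] <- 0L
      },
      reassign = {
        mv <- region & result[[oth]][, , i] > 0
        result[[oth]][, , i][mv] <- 0L
        result[[tgt]][, , i][mv] <- 1L
      })
    result$log <- rbind(result$log,
                        data.frame(stage = "edit", slice = i,
                                   voxels = sum(region),
                                   note = sprintf("%s %s", op$action, op$compartment),
                                   stringsAsFactors = FALSE))
  }
  result$edits_applied <- edit_script(c(unclass(result$edits_applied),
                                        unclass(edits)))
  result
}
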