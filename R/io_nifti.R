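#' Read an image stack from NIfTI or a DICOM series
#'
#' `path` may be a NIfTI file (`.nii` / `.nii.gz`) or a directory holding a
#' single-frame-per-slice DICOM series. Slices are ordered caudal to
#' cranial using spatial position metadata (never file names), and pixel
#' spacing and slice thickness are taken from the headers; a series without
#' thickness or spacing metadata is a format error, never a silent default.
#'
#' @param path file or directory path.
#' @return An [image_stack()].
#' @export
read_image <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stopf("read_image: no such path '%s'", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(pd[1:3] <= 0))
    stopf("read_image: NIfTI '%s' lacks positive voxel dimensions", path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  image_stack(a, pixel_spacing_mm = pd[1:2], slice_thickness_mm = pd[3])
}

#' Write an image stack as NIfTI
#'
#' @param stack an [image_stack()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_image_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  a <- stack$voxels
  attr(a, "pixdim") <- c(stack$pixel_spacing_mm, stack$slice_thickness_mm)
  img <- RNifti::asNifti(a, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write segmentation masks as NIfTI label volumes with provenance
#'
#' Writes one geometry-aligned NIfTI label volume per compartment (`sat`,
#' `vat`, `nonvat`, `torso`) plus a YAML provenance sidecar recording the
#' segmentation parameters, applied edits, package version and optional
#' seed.
#'
#' @param result a `voxa_seg`.
#' @param out_dir output directory (created if missing).
#' @param geometry an [image_stack()]; defaults to the result's geometry.
#' @param seed optional seed to record in the sidecar.
#' @return Named character vector of written paths, invisibly.
#' @export
write_masks <- function(result, out_dir, geometry = result$geometry,
                        seed = NULL) {
  stopifnot(inherits(result, "voxa_seg"))
  if (is.null(geometry)) stopf("write_masks: no geometry available")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("write_masks: cannot create directory '%s'", out_dir)
  paths <- c()
  for (comp in c("sat", "vat", "nonvat", "torso")) {
    a <- result[[comp]]
    storage.mode(a) <- "integer"
    attr(a, "pixdim") <- c(geometry$pixel_spacing_mm,
                           geometry$slice_thickness_mm)
    p <- file.path(out_dir, paste0(comp, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(a, datatype = "int16"), p)
    paths[comp] <- p
  }
  prov <- list(
    software = paste0("adiposeg ",
                      as.character(utils::packageVersion("adiposeg"))),
    params = unclass(result$params),
    edits_applied = serialize_edits(result$edits_applied),
    seed = seed)
  sidecar <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(prov, sidecar)
  paths["provenance"] <- sidecar
  invisible(paths)
}

#' Read compartment masks written by [write_masks()]
#'
#' @param dir directory written by [write_masks()].
#' @return A `voxa_seg` with masks, parameters (from the sidecar) and no log.
#' @export
read_masks <- function(dir) {
  sidecar <- file.path(dir, "provenance.yaml")
  if (!file.exists(sidecar))
    stopf("read_masks: no provenance sidecar in '%s'", dir)
  prov <- yaml::read_yaml(sidecar)
  rd <- function(comp) {
    p <- file.path(dir, paste0(comp, ".nii.gz"))
    if (!file.exists(p)) stopf("read_masks: missing %s", p)
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    check_mask(a)
  }
  params <- do.call(voxa_params, prov$params[
    setdiff(names(prov$params), character())])
  new_voxa_seg(rd("sat"), rd("vat"), rd("nonvat"), rd("torso"),
               params, geometry = NULL,
               edits = deserialize_edits(prov$edits_applied))
}

serialize_edits <- function(edits) {
  lapply(unclass(edits), function(op) {
    list(slice = op$slice, compartment = op$compartment, action = op$action,
         polygon = if (!is.null(op$polygon)) {
           list(row = as.numeric(op$polygon[, 1]),
                col = as.numeric(op$polygon[, 2]))
         },
         mask_rle = if (!is.null(op$mask)) {
           r <- rle(as.integer(op$mask))
           list(lengths = r$lengths, values = r$values,
                dim = dim(op$mask))
         })
  })
}

deserialize_edits <- function(lst) {
  ops <- lapply(lst, function(e) {
    edit_op(e$slice, e$compartment, e$action,
            polygon = if (!is.null(e$polygon))
              cbind(e$polygon$row, e$polygon$col),
            mask = if (!is.null(e$mask_rle)) {
              m <- inverse.rle(structure(list(
                lengths = as.integer(e$mask_rle$lengths),
                values = as.integer(e$mask_rle$values)), class = "rle"))
              matrix(m, e$mask_rle$dim[1], e$mask_rle$dim[2])
            })
  })
  edit_script(ops)
}

#' Read/write an edit script as YAML
#'
#' @param edits an [edit_script()] (for writing).
#' @param path file path.
#' @return `write_edit_script()` the path; `read_edit_script()` an
#'   [edit_script()].
#' @export
write_edit_script <- function(edits, path) {
  stopifnot(inherits(edits, "edit_script"))
  yaml::write_yaml(serialize_edits(edits), path)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  deserialize_edits(yaml::read_yaml(path))
}

#' Write / read a cohort table as comma-delimited text
#'
#' Missing values are encoded as empty fields; the glucose unit is carried
#' in a `# glucose_unit:` comment header line.
#'
#' @param cohort a cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort()` the path; `read_cohort()` the data.frame.
#' @export
write_cohort <- function(cohort, path) {
  unit <- attr(cohort, "glucose_unit") %||% "mg/dL"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# glucose_unit: %s", unit), con)
  write.csv(cohort, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- "mg/dL"
  skip <- 0L
  if (grepl("^# glucose_unit:", first)) {
    unit <- trimws(sub("^# glucose_unit:", "", first))
    skip <- 1L
  }
  out <- read.csv(path, skip = skip, na.strings = "")
  attr(out, "glucose_unit") <- unit
  out
}
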