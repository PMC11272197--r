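# Minimal single-frame DICOM support (explicit VR little endian only).
# Scope: write a phantom stack as one MR Image Storage file per slice with
# geometry populated, and read such a series back, ordering slices by
# ImagePositionPatient. Not a general DICOM implementation: sequences,
# compressed transfer syntaxes and implicit VR are rejected.

UID_ROOT <- "1.2.826.0.1.3680043.9.7484"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"

dcm_uid <- function(...) paste(UID_ROOT, ..., sep = ".")

pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L) c(raw, pad) else raw
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value) {
  body <- switch(vr,
    UI = pad_even(charToRaw(value), as.raw(0)),
    DS = , IS = , CS = , PN = , LO = , SH = pad_even(charToRaw(value)),
    US = u16(value),
    UL = u32(value),
    OB = pad_even(value, as.raw(0)),
    OW = value,
    stopf("dcm_element: unsupported VR %s", vr))
  head <- c(u16(group), u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)), u32(length(body)), body)
  } else {
    if (length(body) > 65535L) stopf("dcm_element: value too long for VR %s", vr)
    c(head, u16(length(body)), body)
  }
}

ds_fmt <- function(x) paste(vapply(x, function(v) sprintf("%.8g", v), ""),
                            collapse = "\\")

#' Write an image stack as a single-frame DICOM series
#'
#' One explicit-VR little-endian MR Image Storage file per slice, with
#' Rows/Columns, PixelSpacing, SliceThickness, ImagePositionPatient,
#' ImageOrientationPatient and InstanceNumber populated. Pixel values are
#' rounded to 16-bit unsigned integers (intensities must lie in
#' `[0, 65535]`). File names are deliberately unrelated to slice order;
#' readers must sort by position.
#'
#' @param stack an [image_stack()].
#' @param out_dir output directory (created if missing).
#' @param series_number integer series number.
#' @param omit_thickness for testing degraded metadata: drop SliceThickness.
#' @return Character vector of file paths (in slice order), invisibly.
#' @export
write_dicom_series <- function(stack, out_dir, series_number = 1L,
                               omit_thickness = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$voxels) > 65535)
    stopf("write_dicom_series: intensities exceed 16-bit range")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("write_dicom_series: cannot create '%s'", out_dir)
  d <- dim(stack$voxels)
  study_uid <- dcm_uid(1, series_number, 0)
  series_uid <- dcm_uid(2, series_number, 0)
  paths <- character(d[3])
  for (i in seq_len(d[3])) {
    sop_uid <- dcm_uid(3, series_number, i)
    z <- (i - 1) * stack$slice_thickness_mm
    px <- as.integer(round(t(stack$voxels[, , i])))  # row-major pixel order
    px[px > 32767L] <- px[px > 32767L] - 65536L      # two's complement for writeBin
    meta <- c(
      dcm_element(2L, 1L, "OB", as.raw(c(0, 1))),
      dcm_element(2L, 2L, "UI", SOP_MR),
      dcm_element(2L, 3L, "UI", sop_uid),
      dcm_element(2L, 16L, "UI", TS_EXPLICIT_LE))
    dataset <- c(
      dcm_element(0x0008, 0x0016, "UI", SOP_MR),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "MR"),
      dcm_element(0x0010, 0x0010, "PN", "PHANTOM"),
      if (!omit_thickness)
        dcm_element(0x0018, 0x0050, "DS", ds_fmt(stack$slice_thickness_mm)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0011, "IS", as.character(series_number)),
      dcm_element(0x0020, 0x0013, "IS", as.character(i)),
      dcm_element(0x0020, 0x0032, "DS", ds_fmt(c(0, 0, z))),
      dcm_element(0x0020, 0x0037, "DS", ds_fmt(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[1]),
      dcm_element(0x0028, 0x0011, "US", d[2]),
      dcm_element(0x0028, 0x0030, "DS", ds_fmt(stack$pixel_spacing_mm)),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      c(u16(0x7FE0), u16(0x0010), charToRaw("OW"), as.raw(c(0, 0)),
        u32(2L * length(px)),
        writeBin(px, raw(), size = 2, endian = "little")))
    # scramble names on purpose: ordering must come from position tags
    fname <- sprintf("img_%02d_%03d.dcm", (i * 37L) %% 11L, i)
    paths[i] <- file.path(out_dir, fname)
    con <- file(paths[i], "wb")
    writeBin(c(raw(128), charToRaw("DICM"),
               dcm_element(2L, 0L, "UL", length(meta)), meta, dataset), con)
    close(con)
  }
  invisible(paths)
}

# parse one explicit-VR little-endian DICOM file into a tag list
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 160L || rawToChar(raw[129:132]) != "DICM")
    stopf("read_dicom_file: '%s' is not a DICOM part-10 file", path)
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  rd16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  rd32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                               endian = "little")
  while (pos + 7L <= length(raw)) {
    group <- rd16(pos); elem <- rd16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stopf("read_dicom_file: '%s' is not explicit-VR little endian", path)
    if (vr %in% long_vrs) {
      len <- rd32(pos + 8L); body_at <- pos + 12L
    } else {
      len <- rd16(pos + 6L); body_at <- pos + 8L
    }
    if (len < 0 || body_at + len - 1L > length(raw))
      stopf("read_dicom_file: truncated element in '%s'", path)
    body <- if (len > 0) raw[body_at:(body_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, body = body)
    if (group == 0x0002 && elem == 0x0010) {
      ts <- rawToChar(body[body != as.raw(0)])
      if (ts != TS_EXPLICIT_LE)
        stopf("read_dicom_file: unsupported transfer syntax '%s'", ts)
    }
    pos <- body_at + len
  }
  tags
}

tag_string <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$body[t$body != as.raw(0)]))
}

tag_ds <- function(tags, key) {
  s <- tag_string(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$body, "integer", n = length(t$body) / 2L, size = 2,
          endian = "little", signed = FALSE)
}

#' Read a single-frame DICOM series as an image stack
#'
#' Reads every `.dcm` file in `dir`, checks the series is geometrically
#' consistent, and orders slices caudal to cranial by the axial component
#' of ImagePositionPatient (file names are ignored). Missing pixel spacing
#' or slice thickness, or mixed orientations, are format errors.
#'
#' @param dir directory containing the series.
#' @return An [image_stack()].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    stopf("read_dicom_series: no .dcm files in '%s'", dir)
  parsed <- lapply(files, read_dicom_file)
  thick <- unique(unlist(lapply(parsed, function(t) tag_ds(t, "0018,0050"))))
  if (length(thick) == 0L)
    stopf("read_dicom_series: series is missing slice thickness metadata")
  if (length(thick) > 1L)
    stopf("read_dicom_series: inconsistent slice thickness in series")
  spacings <- lapply(parsed, function(t) tag_ds(t, "0028,0030"))
  if (any(vapply(spacings, is.null, TRUE)))
    stopf("read_dicom_series: series is missing pixel spacing metadata")
  sp <- unique(do.call(rbind, spacings))
  if (nrow(sp) > 1L)
    stopf("read_dicom_series: inconsistent pixel spacing in series")
  orients <- unique(do.call(rbind, lapply(parsed, function(t) {
    o <- tag_ds(t, "0020,0037")
    if (is.null(o)) stopf("read_dicom_series: missing image orientation")
    o
  })))
  if (nrow(orients) > 1L)
    stopf("read_dicom_series: mixed orientations in series")
  zpos <- vapply(parsed, function(t) {
    p <- tag_ds(t, "0020,0032")
    if (is.null(p) || length(p) != 3L)
      stopf("read_dicom_series: missing image position metadata")
    p[3]
  }, 0)
  ord <- order(zpos)
  parsed <- parsed[ord]
  dims <- t(vapply(parsed, function(t)
    c(tag_us(t, "0028,0010"), tag_us(t, "0028,0011")), c(0L, 0L)))
  if (nrow(unique(dims)) > 1L)
    stopf("read_dicom_series: inconsistent matrix sizes in series")
  nr <- dims[1, 1]; nc <- dims[1, 2]
  vox <- array(0, c(nr, nc, length(parsed)))
  for (i in seq_along(parsed)) {
    t <- parsed[[i]]
    px <- t[["7fe0,0010"]]
    if (is.null(px)) stopf("read_dicom_series: missing pixel data")
    v <- readBin(px$body, "integer", n = nr * nc, size = 2,
                 endian = "little", signed = FALSE)
    vox[, , i] <- matrix(v, nr, nc, byrow = TRUE)   # row-major on disk
  }
  image_stack(vox, pixel_spacing_mm = sp[1, ], slice_thickness_mm = thick)
}
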