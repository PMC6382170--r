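## Minimal DICOM codec: explicit and implicit VR little endian, nested
## sequences with defined or undefined lengths. Covers the tag set needed
## to read single-frame image series and RT-struct contours; not a general
## DICOM implementation.

.u16 <- function(r, off) {
  as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
}
.u32 <- function(r, off) {
  as.numeric(r[off + 1]) + 256 * as.numeric(r[off + 2]) +
    65536 * as.numeric(r[off + 3]) + 16777216 * as.numeric(r[off + 4])
}

.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

## parse a dataset from raw vector `r` starting at byte offset `pos`
## (0-based), not passing `end`; returns list(elements, pos)
.dcm_parse <- function(r, pos, end, explicit) {
  out <- list()
  while (pos + 8 <= end) {
    grp <- .u16(r, pos); ele <- .u16(r, pos + 2)
    if (grp == 0xFFFE && ele == 0xE00D) { pos <- pos + 8; break }  # item end
    if (grp == 0xFFFE && ele == 0xE0DD) { pos <- pos + 8; break }  # seq end
    tag <- sprintf("%04x%04x", grp, ele)
    vr <- NA_character_
    if (explicit && grp != 0xFFFE) {
      vr <- rawToChar(r[(pos + 5):(pos + 6)])
      if (vr %in% .long_vrs) {
        len <- .u32(r, pos + 8); pos <- pos + 12
      } else {
        len <- .u16(r, pos + 6); pos <- pos + 8
      }
    } else {
      len <- .u32(r, pos + 4); pos <- pos + 8
    }
    undefined <- len >= 4294967295
    is_seq <- identical(vr, "SQ") ||
      (!explicit && (undefined || tag %in% .known_sq_tags))
    if (is_seq) {
      seq_end <- if (undefined) end else pos + len
      items <- list()
      while (pos + 8 <= seq_end) {
        igrp <- .u16(r, pos); iele <- .u16(r, pos + 2)
        if (igrp == 0xFFFE && iele == 0xE0DD) { pos <- pos + 8; break }
        if (!(igrp == 0xFFFE && iele == 0xE000))
          stop("format error: malformed DICOM sequence", call. = FALSE)
        ilen <- .u32(r, pos + 4); pos <- pos + 8
        iend <- if (ilen >= 4294967295) seq_end else pos + ilen
        res <- .dcm_parse(r, pos, iend, explicit)
        items[[length(items) + 1L]] <- res$elements
        pos <- res$pos
      }
      out[[tag]] <- items
    } else {
      if (undefined)
        stop("format error: undefined length on non-sequence element",
             call. = FALSE)
      out[[tag]] <- if (len > 0) r[(pos + 1):(pos + len)] else raw(0)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos)
}

.known_sq_tags <- c("30060039", "30060040", "30060010", "30060020",
                    "30060080")

## read one DICOM file into a named element list (meta group merged in)
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("format error: not a DICOM file: ", path, call. = FALSE)
  pos <- 132
  ## file meta group is always explicit VR; its group-length element comes
  ## first (12 bytes) and delimits the group
  gl <- .dcm_parse(r, pos, pos + 12, explicit = TRUE)
  glraw <- gl$elements[["00020000"]]
  if (is.null(glraw))
    stop("format error: DICOM meta header without group length",
         call. = FALSE)
  glen <- .u32(glraw, 0)
  meta <- .dcm_parse(r, pos, pos + 12 + glen, explicit = TRUE)
  ts <- .dcm_str(meta$elements, "00020010")
  explicit <- !identical(ts, "1.2.840.10008.1.2")
  body <- .dcm_parse(r, meta$pos, length(r), explicit = explicit)
  c(meta$elements, body$elements)
}

.dcm_str <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(v), useBytes = TRUE))
}
.dcm_nums <- function(el, tag) {
  s <- .dcm_str(el, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  .u16(v, 0)
}

#' Read a DICOM image series from a directory
#'
#' The directory must hold exactly one series (one SeriesInstanceUID);
#' slices are ordered by their ImagePositionPatient along the slice axis,
#' never by filename, and slice spacing is derived from consecutive
#' positions. Rescale slope and intercept are always applied.
#'
#' @param path directory containing the series.
#' @return An [image_volume()].
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- list()
  for (f in files) {
    el <- tryCatch(read_dicom_file(f), error = function(e) NULL)
    if (!is.null(el) && !is.null(el[["7fe00010"]]))
      parsed[[length(parsed) + 1L]] <- el
  }
  if (!length(parsed))
    stop("format error: no DICOM image slices found in ", path,
         call. = FALSE)
  uids <- unique(vapply(parsed, function(el)
    .dcm_str(el, "0020000e") %||% "", character(1)))
  if (length(uids) > 1)
    stop("multiplicity error: directory holds ", length(uids),
         " DICOM series; store each series in its own folder",
         call. = FALSE)
  zs <- vapply(parsed, function(el) .dcm_nums(el, "00200032")[3],
               numeric(1))
  ord <- order(zs)
  parsed <- parsed[ord]; zs <- zs[ord]
  el1 <- parsed[[1]]
  rows <- .dcm_us(el1, "00280010"); cols <- .dcm_us(el1, "00280011")
  ps <- .dcm_nums(el1, "00280030")          # (row spacing, col spacing)
  dz <- if (length(zs) > 1) {
    dzi <- diff(zs)
    if (max(dzi) - min(dzi) > 1e-3)
      stop("format error: non-uniform DICOM slice spacing", call. = FALSE)
    mean(dzi)
  } else 1
  nz <- length(parsed)
  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    el <- parsed[[k]]
    bits <- .dcm_us(el, "00280100") %||% 16L
    signed <- (.dcm_us(el, "00280103") %||% 0L) == 1L
    pix <- el[["7fe00010"]]
    vals <- readBin(pix, "integer", n = rows * cols,
                    size = bits %/% 8, endian = "little", signed = signed)
    slope <- (.dcm_nums(el, "00281053") %||% 1)[1]
    inter <- (.dcm_nums(el, "00281052") %||% 0)[1]
    arr[, , k] <- matrix(vals * slope + inter, cols, rows)
  }
  ipp <- .dcm_nums(el1, "00200032")
  mod <- switch(.dcm_str(el1, "00080060") %||% "OT",
                PT = "PET", CT = "CT", MR = "MR", "OTHER")
  image_volume(arr, spacing = c(ps[2], ps[1], dz), origin = ipp,
               modality = mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- writer -------------------------------------------------------------

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
.w32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                             endian = "little")

.dcm_elem <- function(grp, ele, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  hdr <- c(.w16(grp), .w16(ele), charToRaw(vr))
  if (vr %in% .long_vrs)
    c(hdr, as.raw(c(0, 0)), .w32(length(value)), value)
  else
    c(hdr, .w16(length(value)), value)
}

.dcm_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    sprintf("2.25.%d.%d", as.integer(Sys.time()) %% 100000000L, counter)
  }
})

#' Write a volume as a DICOM image series
#'
#' One explicit-VR little-endian secondary-capture file per slice, with
#' spatial metadata (ImagePositionPatient, PixelSpacing) and a rescale
#' slope/intercept mapping the doubles onto int16 storage. Mainly intended
#' to exercise DICOM ingestion end-to-end with synthetic data.
#'
#' @param vol an [image_volume()].
#' @param dir output directory (created if needed).
#' @param modality DICOM modality code (e.g. `"CT"`, `"PT"`).
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(vol, dir, modality = "CT") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$values)
  series_uid <- .dcm_uid()
  study_uid <- .dcm_uid()
  rng <- range(vol$values)
  slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 60000 else 1
  if (slope < 1 && all(vol$values == round(vol$values)) &&
      rng[2] <= 32000 && rng[1] >= -32000) slope <- 1
  inter <- if (rng[1] >= 0 && rng[2] / slope <= 32000) 0 else rng[1]
  for (k in seq_len(d[3])) {
    slice <- vol$values[, , k]
    stored <- as.integer(round((slice - inter) / slope))
    body <- c(
      .dcm_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      .dcm_elem(0x0008, 0x0018, "UI", .dcm_uid()),
      .dcm_elem(0x0008, 0x0060, "CS", modality),
      .dcm_elem(0x0020, 0x000D, "UI", study_uid),
      .dcm_elem(0x0020, 0x000E, "UI", series_uid),
      .dcm_elem(0x0020, 0x0013, "IS", as.character(k)),
      .dcm_elem(0x0020, 0x0032, "DS",
                paste(c(vol$origin[1:2],
                        vol$origin[3] + (k - 1) * vol$spacing[3]),
                      collapse = "\\")),
      .dcm_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcm_elem(0x0028, 0x0002, "US", .w16(1)),
      .dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_elem(0x0028, 0x0010, "US", .w16(d[2])),   # Rows = y
      .dcm_elem(0x0028, 0x0011, "US", .w16(d[1])),   # Columns = x
      .dcm_elem(0x0028, 0x0030, "DS",
                paste(vol$spacing[c(2, 1)], collapse = "\\")),
      .dcm_elem(0x0028, 0x0100, "US", .w16(16)),
      .dcm_elem(0x0028, 0x0101, "US", .w16(16)),
      .dcm_elem(0x0028, 0x0102, "US", .w16(15)),
      .dcm_elem(0x0028, 0x0103, "US", .w16(1)),
      .dcm_elem(0x0028, 0x1052, "DS", format(inter, digits = 10)),
      .dcm_elem(0x0028, 0x1053, "DS", format(slope, digits = 10)),
      .dcm_elem(0x7FE0, 0x0010, "OW",
                writeBin(stored, raw(), size = 2, endian = "little"))
    )
    meta_body <- c(
      .dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      .dcm_elem(0x0002, 0x0003, "UI", .dcm_uid()),
      .dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    )
    meta <- c(.dcm_elem(0x0002, 0x0000, "UL", .w32(length(meta_body))),
              meta_body)
    con <- file(file.path(dir, sprintf("slice%03d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

#' Read RT-struct contours from a DICOM file
#'
#' Extracts every CLOSED_PLANAR contour of the ROIContourSequence as an
#' n x 3 matrix of (x, y, z) mm vertices.
#'
#' @param path an RT-struct DICOM file.
#' @return List of contour vertex matrices, ready for
#'   [rasterize_contours()].
#' @export
read_rtstruct <- function(path) {
  el <- read_dicom_file(path)
  rois <- el[["30060039"]]
  if (is.null(rois))
    stop("format error: no ROIContourSequence in ", path, call. = FALSE)
  out <- list()
  for (roi in rois) {
    for (ct in roi[["30060040"]] %||% list()) {
      typ <- .dcm_str(ct, "30060042") %||% "CLOSED_PLANAR"
      if (typ != "CLOSED_PLANAR") next
      xyz <- .dcm_nums(ct, "30060050")
      out[[length(out) + 1L]] <- matrix(xyz, ncol = 3, byrow = TRUE)
    }
  }
  out
}

#' Write a minimal RT-struct DICOM file
#'
#' Serializes contours into a ROIContourSequence; the companion of
#' [read_rtstruct()] for building synthetic end-to-end inputs.
#'
#' @param contours list of n x 3 vertex matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(contours, path) {
  item <- function(payload) c(.w16(0xFFFE), .w16(0xE000),
                              .w32(length(payload)), payload)
  cts <- lapply(contours, function(m) {
    m <- as.matrix(m)
    item(c(
      .dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
      .dcm_elem(0x3006, 0x0046, "IS", as.character(nrow(m))),
      .dcm_elem(0x3006, 0x0050, "DS",
                paste(format(t(m), trim = TRUE, digits = 10),
                      collapse = "\\"))
    ))
  })
  ctseq <- .dcm_elem(0x3006, 0x0040, "SQ", unlist(cts))
  roi_item <- item(ctseq)
  roiseq <- .dcm_elem(0x3006, 0x0039, "SQ", roi_item)
  body <- c(
    .dcm_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    .dcm_elem(0x0008, 0x0018, "UI", .dcm_uid()),
    .dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
    roiseq
  )
  meta_body <- c(
    .dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
    .dcm_elem(0x0002, 0x0003, "UI", .dcm_uid()),
    .dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(.dcm_elem(0x0002, 0x0000, "UL", .w32(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  close(con)
  invisible(path)
}
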