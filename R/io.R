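#' Load an image or mask volume from a standard format
#'
#' Dispatches on the path: NIfTI (`.nii`, `.nii.gz`), NRRD (`.nrrd`),
#' Analyze (`.hdr`/`.img`), raw with a JSON sidecar (`.raw` +
#' `<path>.json`), or a directory holding exactly one DICOM series. Voxel
#' spacing and origin are taken from the file metadata; DICOM slices are
#' ordered by spatial position, never by filename, and the DICOM rescale
#' slope/intercept is always applied.
#'
#' @param path file or DICOM directory.
#' @param format_hint optional override: `"nifti"`, `"nrrd"`, `"analyze"`,
#'   `"raw"`, `"dicom"`.
#' @param modality modality tag for formats that do not store one.
#' @return An [image_volume()].
#' @export
load_volume <- function(path, format_hint = NULL, modality = "OTHER") {
  fmt <- format_hint
  if (is.null(fmt)) {
    if (dir.exists(path)) fmt <- "dicom"
    else {
      low <- tolower(path)
      fmt <- if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
      else if (grepl("\\.nrrd$", low)) "nrrd"
      else if (grepl("\\.(hdr|img)$", low)) "analyze"
      else if (grepl("\\.raw$", low)) "raw"
      else stop("format error: cannot identify format of ", path,
                call. = FALSE)
    }
  }
  if (fmt != "dicom" && !file.exists(path) && !dir.exists(path))
    stop("file error: ", path, " does not exist", call. = FALSE)
  switch(fmt,
         nifti = read_nifti_volume(path, modality),
         nrrd = read_nrrd_volume(path, modality),
         analyze = read_analyze_volume(path, modality),
         raw = read_raw_volume(path, modality),
         dicom = read_dicom_series(path),
         stop("format error: unknown format hint ", fmt, call. = FALSE))
}

#' Write a volume to NIfTI or NRRD
#'
#' @param vol an [image_volume()] or [mask_volume()].
#' @param path destination ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  low <- tolower(path)
  arr <- vol$values * 1
  if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(4)
    diag(m)[1:3] <- vol$spacing
    m[1:3, 4] <- vol$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", low)) {
    write_nrrd_volume(vol, path)
  } else stop("format error: write supports .nii/.nii.gz/.nrrd",
              call. = FALSE)
  invisible(path)
}

read_nifti_volume <- function(path, modality) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) > 3) dim(arr) <- dim(arr)[1:3]
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  image_volume(arr, spacing = abs(sp), origin = org, modality = modality)
}

read_analyze_volume <- function(path, modality) {
  if (!requireNamespace("oro.nifti", quietly = TRUE))
    stop("reading Analyze volumes requires the oro.nifti package",
         call. = FALSE)
  stem <- sub("\\.(hdr|img)$", "", path)
  img <- oro.nifti::readANALYZE(stem)
  arr <- img@.Data
  if (length(dim(arr)) > 3) dim(arr) <- dim(arr)[1:3]
  sp <- img@pixdim[2:4]
  image_volume(arr, spacing = abs(sp), origin = c(0, 0, 0),
               modality = modality)
}

## ---- NRRD ---------------------------------------------------------------

.nrrd_types <- c("signed char" = "int8", "int8" = "int8",
                 "uchar" = "uint8", "unsigned char" = "uint8",
                 "uint8" = "uint8",
                 "short" = "int16", "int16" = "int16",
                 "ushort" = "uint16", "uint16" = "uint16",
                 "int" = "int32", "int32" = "int32",
                 "float" = "float32", "double" = "float64")

read_nrrd_volume <- function(path, modality = "OTHER") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic))
    stop("format error: not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  typ <- .nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(typ)) stop("format error: unsupported NRRD type",
                         call. = FALSE)
  dims <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  if (length(dims) != 3)
    stop("format error: only 3D NRRD volumes are supported", call. = FALSE)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    mat <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(mat^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]),
                                  ",")[[1]])
  n <- prod(dims)
  enc <- tolower(fields[["encoding"]])
  sz <- switch(typ, int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
               int32 = 4L, float32 = 4L, float64 = 8L)
  read_payload <- function(cc) {
    what <- if (typ %in% c("float32", "float64")) "double" else "integer"
    readBin(cc, what, n = n, size = sz, endian = "little",
            signed = !(typ %in% c("uint8", "uint16")))
  }
  vals <- switch(enc,
    raw = read_payload(con),
    gzip = {
      rest <- readBin(con, "raw", n = file.size(path))
      read_payload(gzcon(rawConnection(rest)))
    },
    ascii = ,
    text = as.numeric(scan(con, what = "character", quiet = TRUE)),
    stop("format error: unsupported NRRD encoding ", enc, call. = FALSE))
  image_volume(array(vals, dims), spacing = spacing, origin = origin,
               modality = modality)
}

write_nrrd_volume <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by voxrad",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(vol$values), collapse = " ")),
           sprintf("spacings: %s", paste(vol$spacing, collapse = " ")),
           sprintf("space origin: (%s)",
                   paste(vol$origin, collapse = ",")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con)
  writeBin(as.double(vol$values), con, size = 8, endian = "little")
  invisible(path)
}

## ---- raw + JSON sidecar -------------------------------------------------

read_raw_volume <- function(path, modality = "OTHER") {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: raw volumes need a '", basename(sidecar),
         "' sidecar describing shape, dtype and spacing", call. = FALSE)
  meta <- jsonlite::fromJSON(sidecar)
  dims <- as.integer(meta$shape)
  typ <- .nrrd_types[[tolower(meta$dtype)]]
  if (is.null(typ)) stop("format error: unsupported raw dtype",
                         call. = FALSE)
  sz <- switch(typ, int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
               int32 = 4L, float32 = 4L, float64 = 8L)
  endian <- if (!is.null(meta$byte_order) &&
                tolower(meta$byte_order) == "big") "big" else "little"
  what <- if (typ %in% c("float32", "float64")) "double" else "integer"
  vals <- readBin(path, what, n = prod(dims), size = sz, endian = endian,
                  signed = !(typ %in% c("uint8", "uint16")))
  image_volume(array(vals, dims),
               spacing = if (!is.null(meta$spacing))
                 as.numeric(meta$spacing) else c(1, 1, 1),
               origin = if (!is.null(meta$origin))
                 as.numeric(meta$origin) else c(0, 0, 0),
               modality = modality)
}

#' Rasterize planar closed contours onto a reference grid
#'
#' Each polygon must lie in a constant-z plane matching a slice center
#' within half the slice spacing. A voxel enters the mask when its center
#' is inside a polygon of its slice under the even-odd rule; multiple
#' polygons on one slice are unioned. Traversal orientation does not
#' matter.
#'
#' @param contours list of n x 3 matrices of (x, y, z) mm vertices, each a
#'   closed planar polygon (last vertex need not repeat the first).
#' @param reference_grid an [image_volume()] supplying the grid.
#' @return A [mask_volume()].
#' @export
rasterize_contours <- function(contours, reference_grid) {
  g <- reference_grid
  d <- dim(g$values)
  out <- array(FALSE, d)
  zc <- axis_centers(g, 3)
  xc <- axis_centers(g, 1)
  yc <- axis_centers(g, 2)
  px <- matrix(rep(xc, length(yc)), d[1], d[2])
  py <- matrix(rep(yc, each = length(xc)), d[1], d[2])
  for (poly in contours) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3)
      stop("geometry error: polygon with fewer than 3 vertices",
           call. = FALSE)
    if (diff(range(poly[, 3])) > 1e-6)
      stop("geometry error: polygon is not planar in z", call. = FALSE)
    z <- poly[1, 3]
    k <- which.min(abs(zc - z))
    if (abs(zc[k] - z) > g$spacing[3] / 2 + 1e-9)
      stop("placement error: contour z matches no slice", call. = FALSE)
    inside <- matrix(FALSE, d[1], d[2])
    nv <- nrow(poly)
    j <- nv
    for (i in seq_len(nv)) {
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[i, 1]; y2 <- poly[i, 2]
      if (y1 != y2) {
        crosses <- ((y1 > py) != (y2 > py)) &
          (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
        inside <- xor(inside, crosses)
      }
      j <- i
    }
    out[, , k] <- out[, , k] | inside
  }
  mask_volume(out, spacing = g$spacing, origin = g$origin)
}
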