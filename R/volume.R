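#' 3D scalar image volume
#'
#' Container for a 3D scalar grid with voxel spacing and origin metadata.
#' The array is indexed `[x, y, z]` with x varying fastest (R column-major
#' order) and z as the slice axis. The physical center of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`; voxel
#' extents are the half-open boxes centered on these points.
#'
#' @param values numeric 3D array of intensities (HU, Bq/ml, SUV or
#'   arbitrary units).
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   all strictly positive.
#' @param origin numeric length-3, physical coordinate (mm) of the center of
#'   the first voxel.
#' @param modality one of `"OTHER"`, `"PET"`, `"CT"`, `"MR"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = c("OTHER", "PET", "CT", "MR")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("image values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive finite numbers",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' Binary mask volume
#'
#' A 3D binary grid aligned with an [image_volume()]: same array shape,
#' spacing and origin. Nonzero entries mark the volume of interest (VOI).
#'
#' @param values logical or 0/1 numeric 3D array.
#' @inheritParams image_volume
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  v <- array(as.logical(values != 0), dim(values))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive finite numbers",
         call. = FALSE)
  structure(list(values = v, spacing = spacing, origin = origin),
            class = "mask_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 6), collapse = " x "), x$modality))
  cat(sprintf("  intensity range [%g, %g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$origin, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, spacing %s mm, %d in VOI\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 6), collapse = " x "),
              sum(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.mask_volume <- function(x) dim(x$values)

## physical coordinates (mm) of voxel centers along one axis
axis_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

## n x 3 matrix of voxel-center coordinates for a logical array selection
voxel_center_coords <- function(vol, which_arr) {
  idx <- which(which_arr, arr.ind = TRUE)
  t(t(idx - 1) * vol$spacing + vol$origin)
}

check_aligned <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("image and mask must have identical dimensions", call. = FALSE)
  if (max(abs(image$spacing - mask$spacing)) > 1e-6)
    stop("image and mask must have identical voxel spacing", call. = FALSE)
  invisible(TRUE)
}

#' Derive a binary VOI from a scalar mask volume
#'
#' A voxel enters the VOI when its value is at least `threshold_fraction`
#' times the maximum value found in the raw mask. A mask that already only
#' takes the values `{0, c}` therefore yields the same voxel set for every
#' threshold fraction.
#'
#' @param raw_mask an [image_volume()] or [mask_volume()] holding the scalar
#'   (or binary) mask data.
#' @param threshold_fraction fraction of the maximum in `(0, 1]`.
#' @return A [mask_volume()].
#' @export
derive_mask <- function(raw_mask, threshold_fraction = 0.5) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1 ||
      is.na(threshold_fraction) ||
      threshold_fraction <= 0 || threshold_fraction > 1)
    stop("'threshold_fraction' must be a single number in (0, 1]",
         call. = FALSE)
  v <- raw_mask$values
  mx <- max(v)
  if (mx <= 0)
    stop("empty VOI: the raw mask contains no positive voxel", call. = FALSE)
  mask_volume(v >= threshold_fraction * mx,
              spacing = raw_mask$spacing, origin = raw_mask$origin)
}

#' PET patient information for SUV/SUL scaling
#'
#' @param weight body weight in kg.
#' @param height body height in cm.
#' @param sex `"M"` or `"F"`.
#' @param injected_activity net injected activity in Bq, stated at injection
#'   time unless `activity_decay_corrected` is `TRUE`.
#' @param injection_time,scan_start_time `POSIXct` timestamps or numeric
#'   seconds; `scan_start_time` must not precede `injection_time`.
#' @param half_life isotope half-life in seconds (default F-18: 6586.2 s).
#' @param scaling_override optional dimensionless factor; when used with
#'   `suv_convert(..., mode = "SCALE")` every intensity is simply multiplied
#'   by it and all other fields are ignored.
#' @param activity_decay_corrected set to `TRUE` when the injected activity
#'   is already decay-corrected to scan start (DICOM sources differ); decay
#'   correction is then skipped.
#' @return An object of class `patient_info`.
#' @export
patient_info <- function(weight = NA_real_, height = NA_real_,
                         sex = c("M", "F"),
                         injected_activity = NA_real_,
                         injection_time = NA_real_,
                         scan_start_time = NA_real_,
                         half_life = 6586.2,
                         scaling_override = NULL,
                         activity_decay_corrected = FALSE) {
  sex <- match.arg(sex)
  to_s <- function(t) if (inherits(t, "POSIXct")) as.numeric(t) else
    as.numeric(t)
  inj <- to_s(injection_time); scan <- to_s(scan_start_time)
  if (!is.na(inj) && !is.na(scan) && scan < inj)
    stop("scan_start_time must not precede injection_time", call. = FALSE)
  structure(list(weight = as.numeric(weight), height = as.numeric(height),
                 sex = sex, injected_activity = as.numeric(injected_activity),
                 injection_time = inj, scan_start_time = scan,
                 half_life = as.numeric(half_life),
                 scaling_override = scaling_override,
                 activity_decay_corrected = isTRUE(activity_decay_corrected)),
            class = "patient_info")
}

## Janmahasatian lean body mass (kg); weight kg, height cm
lean_body_mass <- function(weight, height, sex) {
  bmi <- weight / (height / 100)^2
  if (sex == "M") 9270 * weight / (6680 + 216 * bmi)
  else 9270 * weight / (8780 + 244 * bmi)
}

#' Convert PET activity concentrations to SUV, SUL or a scaled image
#'
#' `SCALE` multiplies every voxel by `scaling_override` and ignores all other
#' patient fields. `SUV` computes `value * weight_g / A_decayed` where
#' `A_decayed = injected_activity * 2^(-dt / half_life)` and
#' `dt = scan_start_time - injection_time` (skipped when the activity is
#' declared pre-decayed). `SUL` replaces the body weight by the
#' Janmahasatian sex-specific lean body mass.
#'
#' @param image a PET [image_volume()] in Bq/ml.
#' @param patient a [patient_info()].
#' @param mode `"SUV"`, `"SUL"` or `"SCALE"`.
#' @return A rescaled [image_volume()].
#' @export
suv_convert <- function(image, patient, mode = c("SUV", "SUL", "SCALE")) {
  mode <- match.arg(mode)
  if (image$modality != "PET")
    stop("SUV scaling applies to PET images only", call. = FALSE)
  if (mode == "SCALE") {
    f <- patient$scaling_override
    if (is.null(f) || !is.finite(f))
      stop("SCALE mode requires a finite 'scaling_override'", call. = FALSE)
    out <- image
    out$values <- image$values * f
    return(out)
  }
  w <- if (mode == "SUV") patient$weight
       else lean_body_mass(patient$weight, patient$height, patient$sex)
  if (!is.finite(w) || w <= 0)
    stop("scaling error: nonpositive or missing body mass", call. = FALSE)
  a <- patient$injected_activity
  if (!is.finite(a) || a <= 0)
    stop("scaling error: nonpositive or missing injected activity",
         call. = FALSE)
  if (!patient$activity_decay_corrected) {
    dt <- patient$scan_start_time - patient$injection_time
    if (!is.finite(dt))
      stop("scaling error: injection and scan start times required",
           call. = FALSE)
    a <- a * 2^(-dt / patient$half_life)
  }
  if (a <= 0) stop("scaling error: nonpositive decayed activity",
                   call. = FALSE)
  out <- image
  out$values <- image$values * (w * 1000) / a
  out
}
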