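#' Region of interest: paired intensity and morphological voxel sets
#'
#' Extracts the ROI a feature computation consumes: `intensity` holds the
#' image values inside the intensity mask (`NA` elsewhere) and `morph` the
#' morphological mask. Re-segmentation shrinks only the intensity mask;
#' morphology, first-order statistics and local-intensity features keep
#' reading the full morphological voxel set.
#'
#' @param image an [image_volume()].
#' @param mask an aligned [mask_volume()].
#' @return An object of class `roi` with fields `intensity` (3D array, `NA`
#'   outside the intensity mask), `morph` (logical 3D array), `spacing`,
#'   `origin`.
#' @export
extract_roi <- function(image, mask) {
  check_aligned(image, mask)
  if (!any(mask$values)) stop("empty VOI", call. = FALSE)
  intens <- image$values
  intens[!mask$values] <- NA_real_
  structure(list(intensity = intens, morph = mask$values,
                 spacing = image$spacing, origin = image$origin),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %d intensity voxels / %d morphological voxels\n",
              sum(!is.na(x$intensity)), sum(x$morph)))
  invisible(x)
}

roi_values <- function(roi) roi$intensity[!is.na(roi$intensity)]

#' Restrict the intensity mask to an intensity range
#'
#' Keeps only intensity-mask voxels whose value lies in the closed interval
#' `[min_val, max_val]`. The morphological mask is left untouched.
#'
#' @param roi an `roi` from [extract_roi()].
#' @param min_val,max_val optional bounds; `NULL` leaves that side open.
#' @return The re-segmented `roi`.
#' @export
resegment_range <- function(roi, min_val = NULL, max_val = NULL) {
  lo <- if (is.null(min_val)) -Inf else as.numeric(min_val)
  hi <- if (is.null(max_val)) Inf else as.numeric(max_val)
  if (lo > hi) stop("min_val must not exceed max_val", call. = FALSE)
  drop <- !is.na(roi$intensity) & (roi$intensity < lo | roi$intensity > hi)
  roi$intensity[drop] <- NA_real_
  if (!any(!is.na(roi$intensity)))
    stop("empty VOI: re-segmentation removed every intensity voxel",
         call. = FALSE)
  attr(roi, "reseg_range") <- c(lo, hi)
  roi
}

#' Exclude outlier intensities from the intensity mask
#'
#' Retains values within `n_sigma` population standard deviations of the
#' mean; mean and sigma are computed once on the incoming intensity set
#' (no iteration). A constant ROI (sigma 0) is returned unchanged.
#'
#' @param roi an `roi`.
#' @param n_sigma width of the retained band in standard deviations.
#' @return The filtered `roi`.
#' @export
exclude_outliers <- function(roi, n_sigma = 3) {
  x <- roi_values(roi)
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))          # population sigma
  if (sg == 0) return(roi)
  drop <- !is.na(roi$intensity) &
    (roi$intensity < mu - n_sigma * sg | roi$intensity > mu + n_sigma * sg)
  roi$intensity[drop] <- NA_real_
  if (!any(!is.na(roi$intensity)))
    stop("empty VOI: outlier exclusion removed every voxel", call. = FALSE)
  roi
}

new_discretized_roi <- function(levels, n_levels, rule, morph, spacing,
                                origin) {
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 rule = rule, morph = morph, spacing = spacing,
                 origin = origin),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %d voxels, %d grey levels (%s)\n",
              sum(!is.na(x$levels)), x$n_levels, x$rule$method))
  invisible(x)
}

#' Discretize ROI intensities to integer grey levels
#'
#' Fixed bin number (FBN) maps `x` to
#' `min(floor(n_bins * (x - min) / (max - min)) + 1, n_bins)` so that levels
#' span `1..n_bins`; a constant ROI collapses to a single level. Fixed bin
#' size (FBS) maps `x` to `floor((x - anchor) / bin_width) + 1` with the
#' anchor at `lower_bound` when given (keeping bins comparable across
#' images re-segmented to a common range) and at the ROI minimum otherwise.
#' Bins are half-open `[lo, hi)` except the top FBN bin, which is closed.
#'
#' @param roi an `roi`.
#' @param method `"FBN"` or `"FBS"`.
#' @param n_bins number of bins (FBN).
#' @param bin_width bin width in intensity units (FBS).
#' @param lower_bound optional FBS anchor intensity.
#' @return A `discretized_roi`: integer `levels` in `1..n_levels` (`NA`
#'   outside the intensity mask), the level count and the rule used.
#' @export
discretize <- function(roi, method = c("FBN", "FBS"), n_bins = 64,
                       bin_width = NULL, lower_bound = NULL) {
  method <- match.arg(method)
  x <- roi$intensity
  inside <- !is.na(x)
  vals <- x[inside]
  if (!length(vals)) stop("empty VOI", call. = FALSE)
  if (method == "FBN") {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 1L)
      stop("parameter error: FBN needs n_bins >= 1", call. = FALSE)
    rng <- range(vals)
    if (rng[1] == rng[2]) {
      lev <- rep(1L, length(vals))
      ng <- 1L
    } else {
      lev <- pmin(floor(n_bins * (vals - rng[1]) / (rng[2] - rng[1])) + 1,
                  n_bins)
      ng <- n_bins
    }
    rule <- list(method = "FBN", n_bins = n_bins)
  } else {
    if (is.null(bin_width) || !is.finite(bin_width) || bin_width <= 0)
      stop("parameter error: FBS needs bin_width > 0", call. = FALSE)
    b0 <- if (!is.null(lower_bound)) as.numeric(lower_bound) else min(vals)
    lev <- floor((vals - b0) / bin_width) + 1
    ng <- max(lev)
    rule <- list(method = "FBS", bin_width = bin_width, anchor = b0)
  }
  out <- array(NA_integer_, dim(x))
  out[inside] <- as.integer(lev)
  new_discretized_roi(out, ng, rule, roi$morph, roi$spacing, roi$origin)
}

#' Discretize for the intensity-volume histogram
#'
#' Same mechanics as [discretize()] but configured independently, so the IVH
#' can use its own rule. When no rule is requested the continuous
#' intensities are represented through a fine 1000-bin FBN fallback, which
#' makes the volume-fraction curves effectively continuous.
#'
#' @inheritParams discretize
#' @param method `"FBN"`, `"FBS"`, or `"none"` for the fallback.
#' @export
discretize_ivh <- function(roi, method = c("none", "FBN", "FBS"),
                           n_bins = 1000, bin_width = NULL,
                           lower_bound = NULL) {
  method <- match.arg(method)
  if (method == "none")
    discretize(roi, "FBN", n_bins = 1000)
  else
    discretize(roi, method, n_bins = n_bins, bin_width = bin_width,
               lower_bound = lower_bound)
}

## ---- interpolation ------------------------------------------------------

## Output grid aligned by physical center (translation-consistent):
## n_out = ceil(n_in * s_in / s_out); centers of input and output grids
## coincide.
resample_axis_grid <- function(n_in, s_in, s_out) {
  n_out <- max(1L, as.integer(ceiling(n_in * s_in / s_out - 1e-9)))
  center_in <- (n_in - 1) * s_in / 2
  start <- center_in - (n_out - 1) * s_out / 2
  list(n = n_out, coords = start + (0:(n_out - 1)) * s_out)
}

## 1D resample of every line of `arr` along `axis` onto coords (input-index
## physical coordinates relative to the first input center).
resample_along <- function(arr, axis, s_in, coords, method) {
  n_in <- dim(arr)[axis]
  xin <- (0:(n_in - 1)) * s_in
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  xq <- pmin(pmax(coords, xin[1]), xin[n_in])   # clamp to extent
  out <- switch(method,
    nearest = {
      idx <- pmin(pmax(floor(xq / s_in + 0.5) + 1, 1), n_in)
      m[idx, , drop = FALSE]
    },
    trilinear = {
      if (n_in == 1L) m[rep(1L, length(xq)), , drop = FALSE]
      else apply(m, 2, function(col)
        stats::approx(xin, col, xout = xq, rule = 2)$y)
    },
    cubic_spline = {
      if (n_in < 4L) {
        if (n_in == 1L) m[rep(1L, length(xq)), , drop = FALSE]
        else apply(m, 2, function(col)
          stats::approx(xin, col, xout = xq, rule = 2)$y)
      } else {
        apply(m, 2, function(col)
          stats::spline(xin, col, xout = xq, method = "natural")$y)
      }
    },
    stop("unknown interpolation method", call. = FALSE))
  out <- matrix(out, nrow = length(xq))
  dim(out) <- c(length(xq), d[-1])
  aperm(out, order(perm))
}

#' Resample an image volume onto a new voxel grid
#'
#' Separable resampling by nearest-neighbour, trilinear or natural cubic
#' spline interpolation. The output grid covers the input physical extent
#' and is aligned so the physical centers of input and output grids
#' coincide ("align by center"), making results invariant under grid
#' translation. Samples falling outside the input extent are clamped to the
#' nearest edge value. In `slicewise_2d` mode only the in-plane axes are
#' resampled; slice spacing and count are unchanged.
#'
#' @param image an [image_volume()].
#' @param target_spacing length-3 target spacing in mm (the z entry is
#'   ignored in 2D mode).
#' @param method `"nearest"`, `"trilinear"` or `"cubic_spline"`.
#' @param mode `"full_3d"` or `"slicewise_2d"`.
#' @return The resampled [image_volume()].
#' @export
interpolate_image <- function(image, target_spacing,
                              method = c("trilinear", "nearest",
                                         "cubic_spline"),
                              mode = c("full_3d", "slicewise_2d")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  ts <- as.numeric(target_spacing)
  if (length(ts) == 1L) ts <- rep(ts, 3)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("parameter error: target spacing must be positive and finite",
         call. = FALSE)
  axes <- if (mode == "slicewise_2d") 1:2 else 1:3
  arr <- image$values
  spacing <- image$spacing
  origin <- image$origin
  for (ax in axes) {
    if (abs(ts[ax] - spacing[ax]) < 1e-12) next
    g <- resample_axis_grid(dim(arr)[ax], spacing[ax], ts[ax])
    arr <- resample_along(arr, ax, spacing[ax], g$coords, method)
    origin[ax] <- origin[ax] + g$coords[1]
    spacing[ax] <- ts[ax]
  }
  image_volume(arr, spacing = spacing, origin = origin,
               modality = image$modality)
}

#' Resample a mask volume onto a new voxel grid
#'
#' The mask is interpolated as a scalar 0/1 field with the same scheme as
#' [interpolate_image()] and re-binarized at the inclusive threshold 0.5.
#'
#' @inheritParams interpolate_image
#' @param mask a [mask_volume()].
#' @param threshold re-binarization threshold (inclusive).
#' @return The resampled [mask_volume()].
#' @export
interpolate_mask <- function(mask, target_spacing,
                             method = c("trilinear", "nearest",
                                        "cubic_spline"),
                             mode = c("full_3d", "slicewise_2d"),
                             threshold = 0.5) {
  img <- image_volume(mask$values * 1, spacing = mask$spacing,
                      origin = mask$origin)
  out <- interpolate_image(img, target_spacing, method, mode)
  keep <- out$values >= threshold
  if (!any(keep))
    stop("empty VOI after mask interpolation", call. = FALSE)
  mask_volume(keep, spacing = out$spacing, origin = out$origin)
}
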