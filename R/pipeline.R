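#' Run the full feature-extraction pipeline
#'
#' Applies the configured preprocessing in the fixed order interpolation ->
#' VOI threshold -> re-segmentation -> outlier exclusion -> discretization,
#' then computes the selected feature groups. Morphology, statistics and
#' local-intensity features are calculated before discretization on the
#' un-discretized ROI; the intensity-volume histogram uses its own
#' discretization when configured separately.
#'
#' @param image an [image_volume()].
#' @param mask an aligned [image_volume()] or [mask_volume()] holding the
#'   (possibly scalar) mask.
#' @param config a `run_config` ([parse_config()] / [default_config()]).
#' @param patient a [patient_info()], required for PET SUV/SUL scaling.
#' @param selection named logical vector from [parse_feature_selection()].
#' @return A data frame (`group`, `feature`, `value`) in stable row order.
#' @export
extract_features <- function(image, mask, config = default_config(),
                             patient = NULL,
                             selection = parse_feature_selection()) {
  ## PET intensity scaling
  if (image$modality == "PET" && config$petscaling != "NONE") {
    if (is.null(patient))
      stop("usage error: PET images require patient information for SUV ",
           "scaling (or PETScaling = none)", call. = FALSE)
    image <- suv_convert(image, patient, config$petscaling)
  }
  ## binary VOI before any resampling
  bin_mask <- if (inherits(mask, "mask_volume")) mask
              else derive_mask(mask, config$thresholdforvoi)
  ## interpolation
  if (config$useinterpolation == 1) {
    ts <- c(ifelse(is.na(config$targetspacingx), config$targetspacing,
                   config$targetspacingx),
            ifelse(is.na(config$targetspacingy), config$targetspacing,
                   config$targetspacingy),
            ifelse(is.na(config$targetspacingz), config$targetspacing,
                   config$targetspacingz))
    method <- switch(tolower(config$interpolationmethod),
                     trilinear = "trilinear", nearest = "nearest",
                     spline = , cubic_spline = , cubicspline =
                       "cubic_spline",
                     stop("parse error: unknown InterpolationMethod",
                          call. = FALSE))
    mode <- if (config$interpolation2d == 1) "slicewise_2d" else "full_3d"
    image <- interpolate_image(image, ts, method, mode)
    bin_mask <- interpolate_mask(bin_mask, ts, method, mode,
                                 config$maskinterpolationthreshold)
  }
  roi <- extract_roi(image, bin_mask)
  ## re-segmentation and outlier exclusion shrink the intensity mask only
  reseg_lower <- NULL
  if (config$resegmentimage == 1) {
    roi <- resegment_range(roi,
                           if (is.finite(config$minintensity))
                             config$minintensity else NULL,
                           if (is.finite(config$maxintensity))
                             config$maxintensity else NULL)
    if (is.finite(config$minintensity))
      reseg_lower <- config$minintensity
  }
  if (config$excludeoutliers == 1)
    roi <- exclude_outliers(roi, config$outliersigma)

  rows <- list()
  add <- function(group, feats) {
    if (is.null(feats)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, feature = names(feats),
      value = as.numeric(unlist(feats)), stringsAsFactors = FALSE)
  }

  if (selection[["Morphology"]] || selection[["LocalIntensity"]]) {
    mf <- morphology_features(image, bin_mask,
                              smooth_iterations = config$smoothiterations)
    local_names <- c("local intensity peak", "global intensity peak")
    if (selection[["Morphology"]])
      add("Morphology", mf[setdiff(names(mf), local_names)])
    if (selection[["LocalIntensity"]])
      add("Local intensity", mf[local_names])
  }
  if (selection[["Statistics"]])
    add("Statistics", first_order(roi))
  if (selection[["IntensityVolume"]]) {
    divh <- if (config$discretizeivhseparately == 1)
      discretize_ivh(roi, config$ivhdiscretizationmethod,
                     n_bins = config$ivhnrbins,
                     bin_width = config$ivhbinwidth,
                     lower_bound = reseg_lower)
    else discretize_ivh(roi, "none")
    add("intensity volume", ivh_features(divh))
  }
  droi <- NULL
  need_droi <- selection[["IntensityHistogram"]] ||
    any(selection[c("GLCM", "GLRLM", "GLSZM", "GLDZM", "NGTDM", "NGLDM")])
  if (need_droi)
    droi <- discretize(roi, config$discretizationmethod,
                       n_bins = config$nrbins,
                       bin_width = config$binwidth,
                       lower_bound = reseg_lower)
  if (selection[["IntensityHistogram"]])
    add("Intensity histogram", ih_features(droi))
  for (fam in c("GLCM", "GLRLM", "GLSZM", "GLDZM", "NGTDM", "NGLDM")) {
    if (!selection[[fam]]) next
    tb <- texture_feature_table(droi, fam, alpha = config$ngldmalpha)
    if (!is.null(tb)) rows[[length(rows) + 1L]] <- tb
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
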