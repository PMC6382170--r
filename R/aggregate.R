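## pad count matrices to a common column count and sum them
.merge_counts <- function(mats) {
  w <- max(vapply(mats, ncol, integer(1)))
  Reduce(`+`, lapply(mats, function(m) {
    if (ncol(m) < w) cbind(m, matrix(0, nrow(m), w - ncol(m))) else m
  }))
}

## slice indices holding at least one ROI voxel
.roi_slices <- function(levels) {
  which(apply(!is.na(levels), 3, any))
}

## mean over a list of named feature vectors, skipping NULLs (empty
## matrices are skipped rather than averaged in as zeros)
.mean_features <- function(fl) {
  fl <- Filter(Negate(is.null), fl)
  if (!length(fl)) return(NULL)
  rowMeans(do.call(cbind, fl))
}

#' Texture features of one family under one aggregation scheme
#'
#' Builds the family's texture matrices from the discretized ROI and
#' combines them per the requested scheme. For the directional families
#' (GLCM, GLRLM): `AVG_2D` computes features per (slice, direction) matrix
#' and averages; `SLICE_MERGED_2D` merges directions within each slice,
#' extracts features per slice and averages; `DIR_MERGED_2D` merges each
#' direction over slices and averages features over directions;
#' `MERGED_2D` merges all 2D matrices; `AVG_3D` averages features over the
#' 13 3D directions; `MERGED_3D` merges all 3D directional matrices.
#' Merging always sums count matrices before normalization. The
#' non-directional families (GLSZM, GLDZM, NGTDM, NGLDM) support `AVG_2D`
#' (per-slice average), `MERGED_2D` (merged slices) and `MERGED_3D`
#' (single 3D matrix). Voxel-count denominators (run/zone/dependence
#' percentages) scale with the number of directional matrices merged.
#'
#' @param droi a `discretized_roi`.
#' @param family `"GLCM"`, `"GLRLM"`, `"GLSZM"`, `"GLDZM"`, `"NGTDM"` or
#'   `"NGLDM"`.
#' @param scheme `"AVG_2D"`, `"SLICE_MERGED_2D"`, `"DIR_MERGED_2D"`,
#'   `"MERGED_2D"`, `"AVG_3D"` or `"MERGED_3D"`.
#' @param alpha NGLDM level-difference tolerance.
#' @return Named numeric vector of features, or `NULL` if every matrix in
#'   scope was empty.
#' @export
texture_features <- function(droi,
                             family = c("GLCM", "GLRLM", "GLSZM", "GLDZM",
                                        "NGTDM", "NGLDM"),
                             scheme = c("AVG_2D", "SLICE_MERGED_2D",
                                        "DIR_MERGED_2D", "MERGED_2D",
                                        "AVG_3D", "MERGED_3D"),
                             alpha = 0) {
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  lv <- droi$levels
  ng <- droi$n_levels
  directional <- family %in% c("GLCM", "GLRLM")
  if (!directional && scheme %in% c("SLICE_MERGED_2D", "DIR_MERGED_2D",
                                    "AVG_3D"))
    stop(sprintf("configuration error: scheme %s does not apply to %s",
                 scheme, family), call. = FALSE)
  nv_slice <- function(k) sum(!is.na(lv[, , k]))
  nv_total <- sum(!is.na(lv))
  slice_arr <- function(k) lv[, , k, drop = FALSE]

  if (directional) {
    build <- if (family == "GLCM") {
      function(a, off) glcm_matrix(a, ng, off)
    } else {
      function(a, off) glrlm_matrix(a, ng, off)
    }
    feat <- if (family == "GLCM") {
      function(m, nv) glcm_features(m)
    } else {
      function(m, nv) glrlm_features(m, nv)
    }
    if (scheme %in% c("AVG_3D", "MERGED_3D")) {
      offs <- direction_offsets("3D")
      mats <- lapply(seq_len(nrow(offs)),
                     function(t) build(lv, offs[t, ]))
      if (scheme == "AVG_3D")
        return(.mean_features(lapply(mats, feat, nv = nv_total)))
      return(feat(.merge_counts(mats), nv_total * nrow(offs)))
    }
    offs <- direction_offsets("2D")
    ks <- .roi_slices(lv)
    mats <- lapply(ks, function(k)
      lapply(seq_len(nrow(offs)),
             function(t) build(slice_arr(k), offs[t, ])))
    switch(scheme,
      AVG_2D = .mean_features(unlist(lapply(seq_along(ks), function(ki)
        lapply(mats[[ki]], feat, nv = nv_slice(ks[ki]))),
        recursive = FALSE)),
      SLICE_MERGED_2D = .mean_features(lapply(seq_along(ks), function(ki)
        feat(.merge_counts(mats[[ki]]),
             nv_slice(ks[ki]) * nrow(offs)))),
      DIR_MERGED_2D = .mean_features(lapply(seq_len(nrow(offs)),
        function(t) feat(.merge_counts(lapply(mats, `[[`, t)),
                         nv_total))),
      MERGED_2D = feat(.merge_counts(unlist(mats, recursive = FALSE)),
                       nv_total * nrow(offs)))
  } else if (family == "NGTDM") {
    if (scheme == "MERGED_3D")
      return(ngtdm_features(ngtdm_matrix(lv, ng, "3D")))
    ks <- .roi_slices(lv)
    mats <- lapply(ks, function(k) ngtdm_matrix(slice_arr(k), ng, "2D"))
    if (scheme == "AVG_2D")
      return(.mean_features(lapply(mats, ngtdm_features)))
    ## merged slices: sum the difference and occupancy vectors
    list_s <- Reduce(`+`, lapply(mats, `[[`, "s"))
    list_n <- Reduce(`+`, lapply(mats, `[[`, "n"))
    ngtdm_features(list(s = list_s, n = list_n, n_levels = ng))
  } else {
    build3 <- switch(family,
      GLSZM = function() glszm_matrix(lv, ng, "3D"),
      GLDZM = function() gldzm_matrix(lv, ng, droi$morph, "3D"),
      NGLDM = function() ngldm_matrix(lv, ng, "3D", alpha))
    build2 <- switch(family,
      GLSZM = function(k) glszm_matrix(slice_arr(k), ng, "2D"),
      GLDZM = function(k) gldzm_matrix(slice_arr(k), ng,
                                       droi$morph[, , k, drop = FALSE],
                                       "2D"),
      NGLDM = function(k) ngldm_matrix(slice_arr(k), ng, "2D", alpha))
    feat <- switch(family, GLSZM = glszm_features, GLDZM = gldzm_features,
                   NGLDM = ngldm_features)
    if (scheme == "MERGED_3D") return(feat(build3(), nv_total))
    ks <- .roi_slices(lv)
    mats <- lapply(ks, build2)
    if (scheme == "AVG_2D")
      return(.mean_features(lapply(seq_along(ks), function(ki)
        feat(mats[[ki]], nv_slice(ks[ki])))))
    feat(.merge_counts(mats), nv_total)
  }
}

## (family, scheme) -> CSV group label, mirroring the standard output rows
.texture_group_labels <- list(
  GLCM = c(AVG_2D = "glcmFeatures2Davg",
           SLICE_MERGED_2D = "glcmFeatures2Dmrg",
           DIR_MERGED_2D = "glcmFeatures2DDmrg",
           MERGED_2D = "glcmFeatures2Dvmrg",
           AVG_3D = "glcmFeatures3Davg",
           MERGED_3D = "glcmFeatures3DWmrg"),
  GLRLM = c(AVG_2D = "GLRLMFeatures2Davg",
            SLICE_MERGED_2D = "GLRLMFeatures2DWmrg",
            DIR_MERGED_2D = "GLRLMFeatures2DDmrg",
            MERGED_2D = "GLRLMFeatures2Dvmrg",
            AVG_3D = "GLRLMFeatures3Davg",
            MERGED_3D = "GLRLMFeatures3Dmrg"),
  GLSZM = c(AVG_2D = "GLSZMFeatures2Davg",
            MERGED_2D = "GLSZMFeatures2Dvmrg",
            MERGED_3D = "GLSZMFeatures3D"),
  GLDZM = c(AVG_2D = "gldzmFeatures2Davg",
            MERGED_2D = "gldzmFeatures2Dmrg",
            MERGED_3D = "gldzmFeatures3D"),
  NGTDM = c(AVG_2D = "ngtdmFeatures2avg",
            MERGED_2D = "ngtdmFeatures2Dmrg",
            MERGED_3D = "ngtdmFeatures3D"),
  NGLDM = c(AVG_2D = "ngldmFeatures2Davg",
            MERGED_2D = "ngldmFeatures2Dmrg",
            MERGED_3D = "ngldmFeatures3D"))

#' All texture features of one family across its aggregation schemes
#'
#' @inheritParams texture_features
#' @return A data frame with columns `group`, `feature`, `value`.
#' @export
texture_feature_table <- function(droi, family, alpha = 0) {
  labels <- .texture_group_labels[[family]]
  out <- lapply(names(labels), function(sch) {
    f <- texture_features(droi, family, sch, alpha = alpha)
    if (is.null(f)) return(NULL)
    data.frame(group = labels[[sch]], feature = names(f),
               value = as.numeric(f), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
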