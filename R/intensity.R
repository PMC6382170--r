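## population central moments
.pop_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  list(n = n, mu = mu, m2 = m2, m3 = m3, m4 = m4)
}

## shared statistical battery; percentile rule: linear interpolation between
## order statistics (stats::quantile type 7)
.stat_battery <- function(x) {
  m <- .pop_moments(x)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  p10 <- q[1]; p25 <- q[2]; med <- q[3]; p75 <- q[4]; p90 <- q[5]
  sub <- x[x >= p10 & x <= p90]
  list(
    mean = m$mu,
    variance = m$m2,
    skewness = if (m$m2 > 0) m$m3 / m$m2^1.5 else 0,
    kurtosis = if (m$m2 > 0) m$m4 / m$m2^2 - 3 else 0,  # excess
    median = med,
    minimum = min(x),
    p10 = p10, p90 = p90,
    maximum = max(x),
    interquartile_range = p75 - p25,
    range = max(x) - min(x),
    mean_abs_dev = mean(abs(x - m$mu)),
    robust_mean_abs_dev = mean(abs(sub - mean(sub))),
    median_abs_dev = mean(abs(x - med)),
    coeff_of_variation = if (m$mu != 0) sqrt(m$m2) / m$mu else 0,
    quartile_coeff = if ((p75 + p25) != 0) (p75 - p25) / (p75 + p25) else 0,
    energy = sum(x^2),
    root_mean_square = sqrt(sum(x^2) / m$n)
  )
}

#' First-order statistical features on raw ROI intensities
#'
#' Population moments (divide by N), percentile features with linear
#' interpolation between order statistics, mean/robust-mean/median absolute
#' deviations (the latter in the sense of mean absolute deviation from the
#' median), coefficient of variation, quartile coefficient of dispersion,
#' energy and root-mean-square. Kurtosis is excess kurtosis.
#'
#' @param roi an `roi` from [extract_roi()].
#' @return Named list of 18 feature values, CSV-label order.
#' @export
first_order <- function(roi) {
  x <- roi_values(roi)
  if (!length(x)) stop("empty VOI", call. = FALSE)
  b <- .stat_battery(x)
  list(
    "mean" = b$mean, "variance" = b$variance, "skewness" = b$skewness,
    "kurtosis" = b$kurtosis, "median" = b$median, "minimum" = b$minimum,
    "10th percentile" = b$p10, "90th percentile" = b$p90,
    "maximum" = b$maximum, "Interquartile range" = b$interquartile_range,
    "range" = b$range, "Mean absolute deviation" = b$mean_abs_dev,
    "Robust mean absolute deviation" = b$robust_mean_abs_dev,
    "Median absolute deviation" = b$median_abs_dev,
    "Coefficient of variation" = b$coeff_of_variation,
    "Quartile coefficient" = b$quartile_coeff,
    "Energy" = b$energy, "Root mean" = b$root_mean_square
  )
}

#' Intensity-histogram features on discretized grey levels
#'
#' The first-order battery evaluated on the integer levels, plus mode
#' (lowest level on ties), histogram entropy (bits) and uniformity, and the
#' maximum/minimum histogram gradient with the grey levels attaining them.
#' Gradients use central differences `(H(i+1) - H(i-1)) / 2`, with the
#' histogram taken as zero outside its support (so the end gradients are
#' half the one-sided differences).
#'
#' @param droi a `discretized_roi`.
#' @return Named list of 24 feature values.
#' @export
ih_features <- function(droi) {
  lv <- droi$levels[!is.na(droi$levels)]
  if (!length(lv)) stop("empty VOI", call. = FALSE)
  ng <- droi$n_levels
  h <- tabulate(lv, nbins = ng)
  p <- h / sum(h)
  b <- .stat_battery(as.numeric(lv))
  mode_lv <- which(h == max(h))[1]
  pn <- p[p > 0]
  grad <- if (ng == 1) 0 else {
    hp <- c(0, h, 0)                     # zero outside the support
    (hp[3:(ng + 2)] - hp[1:ng]) / 2
  }
  list(
    "mean" = b$mean, "variance" = b$variance, "skewness" = b$skewness,
    "kurtosis" = b$kurtosis, "median" = b$median, "minimum" = b$minimum,
    "10th percentile" = b$p10, "90th percentile" = b$p90,
    "maximum" = b$maximum, "mode" = as.numeric(mode_lv),
    "Interquartile range" = b$interquartile_range, "range" = b$range,
    "Mean absolute deviation" = b$mean_abs_dev,
    "Robust mean absolute deviation" = b$robust_mean_abs_dev,
    "Median absolute deviation" = b$median_abs_dev,
    "Coefficient of variation" = b$coeff_of_variation,
    "Quartile coefficient" = b$quartile_coeff,
    "Entropy" = -sum(pn * log2(pn)),
    "Uniformity" = sum(p^2),
    "Energy" = b$energy,
    "Maximum histogram gradient" = max(grad),
    "Maximum histogram gradient grey level" =
      as.numeric(which.max(grad)),
    "Minimum histogram gradient" = min(grad),
    "Minimum histogram gradient grey level" =
      as.numeric(which.min(grad))
  )
}

#' Intensity-volume-histogram features
#'
#' The intensity fraction of level `i` is
#' `gamma(i) = (i - i_min) / (i_max - i_min)` over the discretized range;
#' `nu(gamma)` is the fraction of ROI voxels with level strictly above the
#' threshold level at `gamma`. Reported are the volume fractions at
#' intensity fractions 0.10 and 0.90, the intensities at volume fractions
#' 0.10 and 0.90 (smallest level whose `nu` drops to or below the target,
#' mapped back to the level scale), and their differences. A constant ROI
#' has no intensity range: the curve degenerates to a step and the
#' intensity-fraction features are returned as the single level with a
#' warning.
#'
#' @param droi_ivh a `discretized_roi` produced by [discretize_ivh()].
#' @param strict use strictly-above tail counts (default); `FALSE` counts
#'   levels at-or-above the threshold.
#' @return Named list with the six IVH features.
#' @export
ivh_features <- function(droi_ivh, strict = TRUE) {
  lv <- droi_ivh$levels[!is.na(droi_ivh$levels)]
  if (!length(lv)) stop("empty VOI", call. = FALSE)
  imin <- min(lv); imax <- max(lv)
  nv <- length(lv)
  nu_at <- function(thr_level) {
    if (strict) sum(lv > thr_level) / nv else sum(lv >= thr_level) / nv
  }
  if (imax == imin) {
    warning("constant ROI: intensity-volume histogram is degenerate")
    return(list("volume at int fraction 10" = nu_at(imin),
                "volume at int fraction 90" = nu_at(imin),
                "int at vol fraction 10" = as.numeric(imin),
                "int at vol fraction 90" = as.numeric(imin),
                "difference vol at int fraction" = 0,
                "difference int at volume fraction" = 0))
  }
  gamma_level <- function(g) imin + g * (imax - imin)
  v10 <- nu_at(gamma_level(0.10))
  v90 <- nu_at(gamma_level(0.90))
  int_at_vol <- function(target) {
    for (i in imin:imax) if (nu_at(i) <= target) return(as.numeric(i))
    as.numeric(imax)
  }
  i10 <- int_at_vol(0.10)
  i90 <- int_at_vol(0.90)
  list("volume at int fraction 10" = v10,
       "volume at int fraction 90" = v90,
       "int at vol fraction 10" = i10,
       "int at vol fraction 90" = i90,
       "difference vol at int fraction" = v10 - v90,
       "difference int at volume fraction" = i10 - i90)
}
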