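## Entropy helper: -sum(p log2 p) over positive entries
.h2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

#' GLCM features from a (symmetrized) count matrix
#'
#' The 25 Haralick-style features on the joint probability matrix
#' `p(i, j)`, its marginals, and the difference `p_{|i-j|}` and sum
#' `p_{i+j}` distributions.
#'
#' @param counts square co-occurrence count (or probability) matrix.
#' @return Named numeric vector of 25 features, or `NULL` (with a warning)
#'   for an all-zero matrix.
#' @export
glcm_features <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) { warning("empty GLCM skipped"); return(NULL) }
  p <- counts / tot
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu <- sum(i * p)                       # symmetric: mu_x = mu_y
  sigma2 <- sum((i - mu)^2 * p)
  ## difference and cross-diagonal distributions
  kd <- abs(i - j)
  pd <- vapply(0:(ng - 1), function(k) sum(p[kd == k]), numeric(1))
  ks <- i + j
  ps <- vapply(2:(2 * ng), function(k) sum(p[ks == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pd)
  sa <- sum((2:(2 * ng)) * ps)
  hxy <- .h2(p)
  pxy <- px[i] * py[j]
  hxy1 <- -sum(p[p > 0 & pxy > 0] * log2(pxy[p > 0 & pxy > 0]))
  hxy2 <- .h2(as.vector(outer(px, py)))
  hx <- .h2(px)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else NA_real_
  c("joint maximum" = max(p),
    "joint average" = mu,
    "joint variance" = sigma2,
    "joint entropy" = hxy,
    "difference average" = da,
    "difference variance" = sum(((0:(ng - 1)) - da)^2 * pd),
    "difference entropy" = .h2(pd),
    "sum average" = sa,
    "sum variance" = sum(((2:(2 * ng)) - sa)^2 * ps),
    "sum entropy" = .h2(ps),
    "angular second moment" = sum(p^2),
    "contrast" = sum((i - j)^2 * p),
    "dissimilarity" = sum(abs(i - j) * p),
    "inverse difference" = sum(p / (1 + abs(i - j))),
    "inverse difference normalised" = sum(p / (1 + abs(i - j) / ng)),
    "inverse difference moment" = sum(p / (1 + (i - j)^2)),
    "inverse difference moment normalised" =
      sum(p / (1 + (i - j)^2 / ng^2)),
    "inverse variance" = sum(p[i != j] / (i - j)[i != j]^2),
    "correlation" = corr,
    "autocorrelation" = sum(i * j * p),
    "cluster tendency" = sum((i + j - 2 * mu)^2 * p),
    "cluster shade" = sum((i + j - 2 * mu)^3 * p),
    "cluster prominence" = sum((i + j - 2 * mu)^4 * p),
    "first measure of information correlation" =
      if (hx > 0) (hxy - hxy1) / hx else NA_real_,
    "second measure of information correlation" =
      if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0)
}

## shared run/zone/distance-style feature battery: matrix indexed
## (grey level i, j = run length | zone size | zone distance), nv = voxel
## count for the percentage feature
.rl_battery <- function(counts, nv, labels) {
  ns <- sum(counts)
  if (ns <= 0) { warning("empty texture matrix skipped"); return(NULL) }
  p <- counts / ns
  i <- row(counts); j <- col(counts)
  si <- rowSums(counts); sj <- colSums(counts)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(
    sum(sj / seq_along(sj)^2) / ns,
    sum(sj * seq_along(sj)^2) / ns,
    sum(si / seq_along(si)^2) / ns,
    sum(si * seq_along(si)^2) / ns,
    sum(p / (i^2 * j^2)),
    sum(p * i^2 / j^2),
    sum(p * j^2 / i^2),
    sum(p * i^2 * j^2),
    sum(si^2) / ns,
    sum(si^2) / ns^2,
    sum(sj^2) / ns,
    sum(sj^2) / ns^2,
    ns / nv,
    sum((i - mu_i)^2 * p),
    sum((j - mu_j)^2 * p),
    .h2(p)
  )
  names(out) <- labels
  out
}

#' GLRLM features
#' @param counts run-length count matrix (levels x run lengths).
#' @param n_voxels ROI voxel count of the aggregated scope, multiplied by
#'   the number of directional matrices merged into `counts`.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(counts, n_voxels) {
  .rl_battery(counts, n_voxels, c(
    "short run emphasis", "long runs emphasis",
    "Low grey level run emphasis", "High grey level run emphasis",
    "Short run low grey level emphasis",
    "Short run high grey level emphasis",
    "Long run low grey level emphasis",
    "Long run high grey level emphasis",
    "Grey level non uniformity", "Grey level non uniformity normalized",
    "Run length non uniformity", "Run length non uniformity normalized",
    "Run percentage", "Grey level variance", "Run length variance",
    "Run entropy"))
}

#' GLSZM features
#' @param counts size-zone count matrix (levels x zone sizes).
#' @param n_voxels ROI voxel count of the aggregated scope.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(counts, n_voxels) {
  .rl_battery(counts, n_voxels, c(
    "small zone emphasis", "Large zone emphasis",
    "Low grey level zone emphasis", "High grey level zone emphasis",
    "Small zone low grey level emphasis",
    "Small zone high grey level emphasis",
    "Large zone low grey level emphasis",
    "Large zone high grey level emphasis",
    "Grey level non uniformity GLSZM",
    "Grey level non uniformity normalized GLSZM",
    "Zone size non uniformity", "Zone size non uniformity normalized",
    "Zone percentage GLSZM", "Grey level variance GLSZM",
    "Zone size variance", "Zone size entropy"))
}

#' GLDZM features
#' @param counts distance-zone count matrix (levels x zone distances).
#' @param n_voxels ROI voxel count of the aggregated scope.
#' @return Named numeric vector of 16 features.
#' @export
gldzm_features <- function(counts, n_voxels) {
  .rl_battery(counts, n_voxels, c(
    "small distance emphasis GLDZM", "Large distance emphasis GLDZM",
    "Low grey level zone emphasis GLDZM",
    "High grey level zone emphasis GLDZM",
    "Small distance low grey level emphasis GLDZM",
    "Small distance high grey level emphasis GLDZM",
    "Large distance low grey level emphasis GLDZM",
    "Large distance high grey level emphasis GLDZM",
    "Grey level non uniformity GLDZM",
    "Grey level non uniformity normalized GLDZM",
    "Zone distance non uniformity GLDZM",
    "Zone distance non uniformity normalized GLDZM",
    "Zone percentage GLDZM", "Grey level variance GLDZM",
    "Zone distance variance GLDZM", "Zone distance entropy GLDZM"))
}

#' NGTDM features (Amadasun-King)
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' grey-tone difference vector; occupancy probabilities are taken over the
#' contributing voxels. Coarseness is capped at `1e6` when its denominator
#' vanishes.
#'
#' @param mat the list returned by [ngtdm_matrix()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(mat) {
  n <- mat$n; s <- mat$s
  nt <- sum(n)
  if (nt <= 0) { warning("empty NGTDM skipped"); return(NULL) }
  p <- n / nt
  occ <- which(p > 0)
  ngp <- length(occ)
  den_coarse <- sum(p * s)
  coarseness <- if (den_coarse > 0) min(1 / den_coarse, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    pij <- outer(p[occ], p[occ])
    dij <- outer(occ, occ, "-")
    sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(s) / nt
  } else 0
  busy_den <- if (ngp > 1) {
    ip <- occ * p[occ]
    sum(abs(outer(ip, ip, "-")))
  } else 0
  busyness <- if (busy_den > 0) den_coarse / busy_den else 0
  complexity <- if (ngp > 1) {
    ii <- outer(occ, occ, "-")
    ps <- p[occ] * s[occ]
    num <- abs(ii) * (outer(ps, rep(1, ngp)) + outer(rep(1, ngp), ps))
    den <- outer(p[occ], p[occ], "+")
    sum(num / den) / nt
  } else 0
  strength <- if (sum(s) > 0 && ngp > 1) {
    pp <- outer(p[occ], p[occ], "+")
    dij <- outer(occ, occ, "-")
    sum(pp * dij^2) / sum(s)
  } else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' NGLDM features
#'
#' Dependence-count analogues of the run-length battery plus dependence
#' count percentage, entropy and energy. With incomplete neighbourhoods
#' allowed every ROI voxel contributes, so the dependence count percentage
#' is identically 1.
#'
#' @param counts dependence count matrix (levels x dependence count + 1).
#' @param n_voxels ROI voxel count of the aggregated scope.
#' @return Named numeric vector of 17 features.
#' @export
ngldm_features <- function(counts, n_voxels) {
  base <- .rl_battery(counts, n_voxels, c(
    "Low dependence emphasis", "High dependence emphasis",
    "Low grey level count emphasis", "High grey level count emphasis",
    "Low dependence low grey level emphasis",
    "Low dependence high grey level emphasis",
    "High dependence low grey level emphasis",
    "High dependence high grey level emphasis",
    "Grey level non uniformity", "Grey level non uniformity normalized",
    "Dependence count non uniformity",
    "Dependence count non uniformity normalized",
    "Dependence count percentage", "Grey level variance",
    "Dependence count variance", "Dependence count entropy"))
  if (is.null(base)) return(NULL)
  p <- counts / sum(counts)
  c(base, "dependence Count Energy" = sum(p^2))
}
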