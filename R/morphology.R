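#' Shape scalars from mesh volume and area
#'
#' sphericity `(36 pi V^2)^(1/3) / A`, compactness1 `V / (sqrt(pi) A^(3/2))`,
#' compactness2 `36 pi V^2 / A^3` (= sphericity^3), spherical disproportion
#' `A / (36 pi V^2)^(1/3)` (= 1/sphericity), asphericity
#' `(A^3 / (36 pi V^2))^(1/3) - 1`, and the surface-to-volume ratio `A / V`.
#'
#' @param volume mesh volume, mm^3 (> 0).
#' @param area mesh surface area, mm^2 (> 0).
#' @return Named list of the six scalars.
#' @export
shape_scalars <- function(volume, area) {
  if (!is.finite(volume) || volume <= 0 || !is.finite(area) || area <= 0)
    stop("domain error: volume and area must be positive", call. = FALSE)
  sph <- (36 * pi * volume^2)^(1 / 3) / area
  list(sphericity = sph,
       compactness1 = volume / (sqrt(pi) * area^(3 / 2)),
       compactness2 = sph^3,
       spherical_disproportion = 1 / sph,
       asphericity = 1 / sph - 1,
       surface_to_volume = area / volume)
}

#' Maximum 3D diameter
#'
#' Largest pairwise Euclidean distance. Accepts a `triangle_mesh` (distance
#' over mesh vertices) or an n x 3 coordinate matrix (e.g. ROI voxel
#' centers). Points are pre-filtered to their convex extremes per octant
#' direction to keep the pairwise scan small.
#'
#' @param x a `triangle_mesh` or numeric matrix of points (mm).
#' @return Diameter in mm.
#' @export
max_3d_diameter <- function(x) {
  pts <- if (inherits(x, "triangle_mesh")) x$vertices else as.matrix(x)
  if (nrow(pts) < 2) stop("degenerate: fewer than 2 points", call. = FALSE)
  if (nrow(pts) > 400) {
    ## keep extreme points along many directions (superset of hull extremes
    ## relevant to the diameter at our tolerances is the full hull; use a
    ## dense direction fan)
    u <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
    u <- u[rowSums(u^2) > 0, ]
    proj <- pts %*% t(u)
    keep <- unique(as.vector(apply(proj, 2, which.max)))
    pts <- pts[keep, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Principal-axis lengths of a mask
#'
#' Eigen-decomposition of the population covariance of ROI voxel-center
#' coordinates. Axis length along eigenvalue `lambda` is `4 sqrt(lambda)`;
#' elongation `sqrt(l2/l1)` and flatness `sqrt(l3/l1)`. Vanished axes
#' (planar or collinear masks) report zero; an error is raised only when
#' the largest eigenvalue is zero.
#'
#' @param mask a [mask_volume()].
#' @return List with `major`, `minor`, `least` (mm), `elongation`,
#'   `flatness`.
#' @export
pca_axes <- function(mask) {
  pts <- voxel_center_coords(mask, mask$values)
  if (nrow(pts) < 2) stop("degenerate: fewer than 2 voxels", call. = FALSE)
  cc <- sweep(pts, 2, colMeans(pts))
  cov <- crossprod(cc) / nrow(cc)           # population covariance
  ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  if (ev[1] <= 0) stop("degenerate: zero-extent mask", call. = FALSE)
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]),
       least = 4 * sqrt(ev[3]),
       elongation = sqrt(ev[2] / ev[1]), flatness = sqrt(ev[3] / ev[1]))
}

#' Bounding-box and ellipsoid density features
#'
#' AABB quantities use the axis-aligned bounding box of the mesh vertices;
#' the approximating ellipsoid (AEE) has semi-axes equal to half the PCA
#' axis lengths.
#'
#' @param mask a [mask_volume()].
#' @param mesh the `triangle_mesh` whose volume/area are reported.
#' @return List with `vol_density_aabb`, `area_density_aabb`,
#'   `vol_density_aee`.
#' @export
density_features <- function(mask, mesh) {
  V <- mesh_volume(mesh); A <- mesh_area(mesh)
  rng <- apply(mesh$vertices, 2, range)
  ext <- rng[2, ] - rng[1, ]
  if (any(ext <= 0)) stop("degenerate: zero box extent", call. = FALSE)
  vbox <- prod(ext)
  abox <- 2 * (ext[1] * ext[2] + ext[1] * ext[3] + ext[2] * ext[3])
  ax <- pca_axes(mask)
  semi <- c(ax$major, ax$minor, ax$least) / 2
  vaee <- 4 * pi * prod(semi) / 3
  list(vol_density_aabb = V / vbox,
       area_density_aabb = A / abox,
       vol_density_aee = if (vaee > 0) V / vaee else NA_real_)
}

#' Center-of-mass shift
#'
#' Distance between the unweighted and the intensity-weighted centroid of
#' the ROI voxel centers.
#'
#' @param image an [image_volume()].
#' @param mask an aligned [mask_volume()].
#' @return Shift in mm.
#' @export
com_shift <- function(image, mask) {
  check_aligned(image, mask)
  pts <- voxel_center_coords(mask, mask$values)
  w <- image$values[mask$values]
  tw <- sum(w)
  if (tw <= 0)
    stop("degenerate: total intensity must be positive for weighting",
         call. = FALSE)
  geo <- colMeans(pts)
  wc <- colSums(pts * w) / tw
  sqrt(sum((geo - wc)^2))
}

#' Integrated intensity
#'
#' Mean ROI intensity times the (mesh) volume.
#'
#' @inheritParams com_shift
#' @param volume volume in mm^3 to integrate over (typically the mesh
#'   volume).
#' @return intensity * mm^3.
#' @export
integrated_intensity <- function(image, mask, volume) {
  mean(image$values[mask$values]) * volume
}

#' Moran's I and Geary's C over the ROI
#'
#' Spatial autocorrelation of ROI intensities with inverse-distance weights
#' `w_ij = 1 / d_ij` between voxel centers. Exact up to `max_n` voxels;
#' larger ROIs are reduced by deterministic stratified subsampling (every
#' k-th voxel in array order), which keeps the estimate reproducible
#' without randomness.
#'
#' @inheritParams com_shift
#' @param max_n largest ROI size computed exactly.
#' @return List with `morans_i` and `gearys_c`; both `NaN` (with a warning)
#'   for constant intensities.
#' @export
spatial_autocorrelation <- function(image, mask, max_n = 20000) {
  check_aligned(image, mask)
  pts <- voxel_center_coords(mask, mask$values)
  x <- image$values[mask$values]
  n <- length(x)
  if (n > max_n) {
    keep <- unique(round(seq(1, n, length.out = max_n)))
    pts <- pts[keep, , drop = FALSE]
    x <- x[keep]
    n <- length(x)
  }
  mu <- mean(x)
  ss <- sum((x - mu)^2)
  if (ss == 0) {
    warning("constant intensities: Moran's I / Geary's C undefined")
    return(list(morans_i = NaN, gearys_c = NaN))
  }
  num_i <- 0; num_c <- 0; sw <- 0
  block <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(pts^2), "+") -
      2 * pts[idx, , drop = FALSE] %*% t(pts)
    d <- sqrt(pmax(d2, 0))
    w <- 1 / d
    w[!is.finite(w)] <- 0                 # i == j
    for (r in seq_along(idx)) w[r, idx[r]] <- 0
    sw <- sw + sum(w)
    num_i <- num_i + sum(w * outer(x[idx] - mu, x - mu))
    num_c <- num_c + sum(w * (outer(x[idx], x, "-"))^2)
  }
  list(morans_i = (n / sw) * num_i / ss,
       gearys_c = ((n - 1) / (2 * sw)) * num_c / ss)
}

#' Local and global intensity peaks
#'
#' Mean intensity in a spherical neighborhood of volume 1 cm^3 (radius
#' 6.2035 mm) around voxel centers; voxels enter the neighborhood when
#' their center is within the radius. The neighborhood may extend outside
#' the mask but is clipped at the image border. The local peak is the
#' neighborhood mean at the maximum-intensity ROI voxel (ties resolved by
#' the highest mean); the global peak is the maximum neighborhood mean over
#' all ROI voxels.
#'
#' @inheritParams com_shift
#' @return List with `local_peak`, `global_peak`.
#' @export
intensity_peaks <- function(image, mask) {
  check_aligned(image, mask)
  if (!any(mask$values)) stop("empty VOI", call. = FALSE)
  r <- (3 * 1000 / (4 * pi))^(1 / 3)      # 6.2035 mm
  sp <- image$spacing
  rad <- floor(r / sp)
  offs <- as.matrix(expand.grid(dx = -rad[1]:rad[1], dy = -rad[2]:rad[2],
                                dz = -rad[3]:rad[3]))
  dmm <- sqrt(colSums((t(offs) * sp)^2))
  offs <- offs[dmm <= r, , drop = FALSE]
  d <- dim(image$values)
  sums <- array(0, d)
  cnts <- array(0, d)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    xs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    zs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    sums[xs - o[1], ys - o[2], zs - o[3]] <-
      sums[xs - o[1], ys - o[2], zs - o[3]] + image$values[xs, ys, zs]
    cnts[xs - o[1], ys - o[2], zs - o[3]] <-
      cnts[xs - o[1], ys - o[2], zs - o[3]] + 1
  }
  nbr_mean <- sums / cnts
  roi_means <- nbr_mean[mask$values]
  roi_vals <- image$values[mask$values]
  at_max <- roi_vals == max(roi_vals)
  list(local_peak = max(roi_means[at_max]),
       global_peak = max(roi_means))
}

#' All morphological and local-intensity features
#'
#' Computes the full morphology block on the un-discretized ROI: mesh and
#' voxel-count volume, surface area, the shape scalars, center-of-mass
#' shift, maximum 3D diameter (over ROI voxel centers), PCA axis features,
#' bounding-box/ellipsoid densities, integrated intensity, Moran's I and
#' Geary's C, and the local/global intensity peaks. Feature names follow
#' the standard CSV row labels.
#'
#' @inheritParams com_shift
#' @param smooth_iterations Taubin fairing passes applied to the raw
#'   iso-surface mesh before measuring it (0 = raw mesh).
#' @return Named list of feature values.
#' @export
morphology_features <- function(image, mask, smooth_iterations = 40) {
  mesh <- build_mesh(mask)
  if (smooth_iterations > 0) mesh <- smooth_mesh(mesh, smooth_iterations)
  V <- mesh_volume(mesh)
  A <- mesh_area(mesh)
  ss <- shape_scalars(V, A)
  ax <- pca_axes(mask)
  dens <- density_features(mask, mesh)
  ac <- spatial_autocorrelation(image, mask)
  pk <- intensity_peaks(image, mask)
  nvox <- sum(mask$values)
  pts <- voxel_center_coords(mask, mask$values)
  list(
    "Volume" = V,
    "approximate volume" = nvox * prod(mask$spacing),
    "Surface" = A,
    "Surface to volume ratio" = ss$surface_to_volume,
    "Compactness1" = ss$compactness1,
    "Compactness2" = ss$compactness2,
    "Spherical disproportion" = ss$spherical_disproportion,
    "sphericity" = ss$sphericity,
    "asphericity" = ss$asphericity,
    "center of mass shift" = com_shift(image, mask),
    "maximum 3D diameter" = max_3d_diameter(pts),
    "major axis length" = ax$major,
    "minor axis length" = ax$minor,
    "least axis length" = ax$least,
    "elongation" = ax$elongation,
    "flatness" = ax$flatness,
    "vol density AABB" = dens$vol_density_aabb,
    "area density AABB" = dens$area_density_aabb,
    "vol density AEE" = dens$vol_density_aee,
    "integrated intensity" = integrated_intensity(image, mask, V),
    "Morans I" = ac$morans_i,
    "Gearys C" = ac$gearys_c,
    "local intensity peak" = pk$local_peak,
    "global intensity peak" = pk$global_peak
  )
}
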