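#' Voxelized sphere phantom
#'
#' Generates an image/mask pair holding a digitized sphere, mimicking one
#' sphere of the NEMA image-quality phantom: a voxel belongs to the mask iff
#' its center lies within `diameter / 2` of the sphere center. The image is
#' filled with a foreground intensity inside the sphere and a background
#' intensity outside (default contrast 10:1, the typical NEMA fill ratio).
#'
#' @param diameter sphere diameter in mm; must exceed the largest voxel edge.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm. The default is the
#'   clinical PET reconstruction grid `3.1819 x 3.1819 x 2` mm.
#' @param center_offset sphere-center offset from a voxel center, in voxel
#'   fractions per axis (0 places the center exactly on a voxel center).
#' @param margin voxels of guaranteed background padding around the sphere.
#' @param foreground,background image intensities inside/outside the mask.
#' @return `list(image =` [image_volume()]`, mask =` [mask_volume()]`)`.
#' @export
make_sphere <- function(diameter, spacing = c(3.1819, 3.1819, 2),
                        center_offset = c(0, 0, 0), margin = 3,
                        foreground = 10, background = 1) {
  spacing <- as.numeric(spacing)
  if (diameter <= max(spacing))
    stop("sphere diameter must exceed the largest voxel edge", call. = FALSE)
  if (margin < 1) stop("margin must be at least 1 voxel", call. = FALSE)
  n <- ceiling(diameter / spacing) + 2 * margin + 2
  ci <- floor(n / 2) + center_offset        # 0-based center index (fractional)
  ax <- lapply(1:3, function(k) ((0:(n[k] - 1)) - ci[k]) * spacing[k])
  r2 <- (diameter / 2)^2
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  inside <- d2 <= r2
  # containment check: no mask voxel may touch the outer padding layer
  if (any(inside[c(1, n[1]), , ]) || any(inside[, c(1, n[2]), ]) ||
      any(inside[, , c(1, n[3])]))
    stop("geometry error: sphere not contained in grid", call. = FALSE)
  img <- array(background, n)
  img[inside] <- foreground
  list(image = image_volume(img, spacing = spacing),
       mask = mask_volume(inside, spacing = spacing))
}

## run code under a temporary RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random discretized grid
#'
#' Reproducible integer-valued grid with levels drawn uniformly from
#' `1..n_levels` and a full mask, used as input for texture-matrix oracle
#' tests. The same seed always yields the same grid.
#'
#' @param shape integer length-3 grid dimensions.
#' @param n_levels number of grey levels.
#' @param seed integer RNG seed.
#' @param spacing voxel spacing in mm.
#' @return A `discretized_roi` (see [discretize()]) with all voxels in the
#'   ROI.
#' @export
make_grid <- function(shape, n_levels, seed, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_levels >= 1L)
  lv <- with_seed(seed,
                  array(sample.int(n_levels, prod(shape), replace = TRUE),
                        shape))
  new_discretized_roi(levels = lv, n_levels = as.integer(n_levels),
                      rule = list(method = "FBN", n_bins = n_levels),
                      morph = array(TRUE, shape),
                      spacing = as.numeric(spacing), origin = c(0, 0, 0))
}

#' Small digital phantom with hand-checkable feature values
#'
#' A fixed 5 x 4 x 4 grid with small integer intensities (1..6) and an
#' irregular mask, built in code so it regenerates byte-identically. It is
#' deliberately tiny enough that every feature can be recomputed by hand or
#' by an exhaustive oracle, and is used as the regression fixture for the
#' feature families.
#'
#' @param spacing voxel spacing in mm.
#' @return `list(image, mask)` as for [make_sphere()].
#' @export
make_digital_phantom <- function(spacing = c(2, 2, 2)) {
  v <- array(1, c(5, 4, 4))
  # slice-wise patterns (x fastest), small dynamic range with one hot spot
  v[, , 1] <- matrix(c(1, 4, 4, 1, 1,
                       1, 4, 6, 1, 1,
                       4, 1, 6, 4, 1,
                       4, 4, 6, 4, 1), 5, 4)
  v[, , 2] <- matrix(c(1, 4, 4, 1, 1,
                       1, 1, 6, 1, 1,
                       1, 1, 3, 1, 1,
                       4, 4, 6, 1, 1), 5, 4)
  v[, , 3] <- matrix(c(1, 4, 4, 1, 1,
                       1, 1, 1, 1, 1,
                       1, 1, 1, 1, 1,
                       1, 1, 6, 1, 1), 5, 4)
  v[, , 4] <- matrix(c(1, 4, 4, 1, 1,
                       1, 1, 1, 1, 1,
                       1, 1, 1, 1, 1,
                       1, 1, 6, 1, 1), 5, 4)
  m <- array(TRUE, c(5, 4, 4))
  m[1, 4, 1] <- FALSE
  m[5, 1, 3] <- FALSE
  m[2, 3, 3] <- FALSE
  m[2, 4, 3] <- FALSE
  m[1, 4, 4] <- FALSE
  m[5, 1, 4] <- FALSE
  list(image = image_volume(v, spacing = spacing),
       mask = mask_volume(m, spacing = spacing))
}
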