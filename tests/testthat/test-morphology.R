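test_that("iso-surface meshes of canonical masks are closed and exact", {
  # isolated voxel: octahedron through the face centers, V = 1/6, A = sqrt(3)
  m1 <- build_mesh(mask_volume(array(TRUE, c(1, 1, 1))))
  expect_true(mesh_is_closed(m1))
  expect_equal(mesh_volume(m1), 1 / 6)
  expect_equal(mesh_area(m1), sqrt(3))
  # 2x2x2 cube of voxels: volume strictly between 1 and 8, equals the
  # signed-tetrahedron oracle evaluated about a different reference point
  m2 <- build_mesh(mask_volume(array(TRUE, c(2, 2, 2))))
  expect_true(mesh_is_closed(m2))
  v2 <- mesh_volume(m2)
  expect_gt(v2, 1); expect_lt(v2, 8)
  expect_equal(v2, oracle_mesh_volume(m2))
  # torus: Euler characteristic 0
  x <- array(FALSE, c(7, 7, 3))
  for (i in 1:7) for (j in 1:7) {
    r <- sqrt((i - 4)^2 + (j - 4)^2)
    if (r >= 1 && r <= 2.6) x[i, j, 2] <- TRUE
  }
  mt <- build_mesh(mask_volume(x))
  expect_true(mesh_is_closed(mt))
  nv <- nrow(mt$vertices); nf <- nrow(mt$triangles)
  expect_equal(nv - 3 * nf / 2 + nf, 0)
  expect_error(build_mesh(mask_volume(array(FALSE, c(2, 2, 2)))),
               "empty VOI")
})

test_that("mesh volume equals the divergence oracle on random blobs", {
  for (seed in 1:3) {
    set.seed(seed)
    arr <- array(runif(6 * 6 * 6) > 0.55, c(6, 6, 6))
    arr[1, 1, 1] <- TRUE
    me <- build_mesh(mask_volume(arr, spacing = c(1.3, 0.8, 2.1)))
    expect_true(mesh_is_closed(me))
    expect_equal(mesh_volume(me), oracle_mesh_volume(me), tolerance = 1e-9)
  }
})

test_that("shape scalars satisfy their closed forms and identities", {
  # perfect sphere, analytic V and A for r = 18.5 mm -> sphericity 1
  r <- 18.5
  s <- shape_scalars(4 / 3 * pi * r^3, 4 * pi * r^2)
  expect_equal(s$sphericity, 1)
  # cube: sphericity (pi/6)^(1/3)
  a <- 3.7
  sc <- shape_scalars(a^3, 6 * a^2)
  expect_equal(sc$sphericity, (pi / 6)^(1 / 3))
  # identities on arbitrary positive V, A
  for (va in list(c(100, 120), c(5, 40), c(2.3e4, 4.1e3))) {
    z <- shape_scalars(va[1], va[2])
    expect_equal(z$compactness2, z$sphericity^3)
    expect_equal(z$spherical_disproportion, 1 / z$sphericity)
    expect_equal(z$asphericity, 1 / z$sphericity - 1)
    expect_equal(z$surface_to_volume, va[2] / va[1])
  }
  expect_error(shape_scalars(-1, 5), "domain error")
})

test_that("max 3D diameter matches the exhaustive pairwise oracle", {
  # unit cube mesh vertices: space diagonal sqrt(3)
  cube <- expand.grid(0:1, 0:1, 0:1)
  expect_equal(max_3d_diameter(as.matrix(cube)), sqrt(3))
  # meshes up to a few hundred vertices: equals O(n^2) brute force
  for (seed in 1:2) {
    set.seed(seed)
    arr <- array(runif(5 * 5 * 5) > 0.5, c(5, 5, 5))
    arr[3, 3, 3] <- TRUE
    me <- build_mesh(mask_volume(arr))
    brute <- max(dist(me$vertices))
    expect_equal(max_3d_diameter(me), brute)
  }
  # the point prefilter keeps the diameter on larger clouds
  set.seed(9)
  pts <- matrix(rnorm(3000), ncol = 3)
  expect_equal(max_3d_diameter(pts), max(dist(pts)), tolerance = 1e-9)
  expect_error(max_3d_diameter(matrix(0, 1, 3)), "degenerate")
})

test_that("PCA axes: sphere isotropy, collinear masks, grid symmetry", {
  sph <- make_sphere(21, spacing = c(1, 1, 1))
  ax <- pca_axes(sph$mask)
  expect_equal(ax$elongation, 1, tolerance = 0.05)
  expect_equal(ax$flatness, 1, tolerance = 0.05)
  # collinear 3-voxel mask along x: population eigenvalues (2/3, 0, 0)
  lin <- mask_volume(array(TRUE, c(3, 1, 1)))
  axl <- pca_axes(lin)
  expect_equal(axl$major, 4 * sqrt(2 / 3))
  expect_equal(axl$minor, 0)
  expect_equal(axl$flatness, 0)
  # permutation of an isotropic grid leaves the axis lengths unchanged
  set.seed(3)
  arr <- array(runif(4^3) > 0.5, c(4, 4, 4)); arr[1] <- TRUE
  ax1 <- pca_axes(mask_volume(arr))
  ax2 <- pca_axes(mask_volume(aperm(arr, c(2, 3, 1))))
  expect_equal(ax1$major, ax2$major)
  expect_equal(ax1$least, ax2$least)
})

test_that("density features: box-filling cube and sphere-in-box ratio", {
  cube <- mask_volume(array(TRUE, c(4, 4, 4)))
  mc <- build_mesh(cube)
  dens <- density_features(cube, mc)
  # the mesh IS the box apart from the chamfered corners: density near 1
  expect_lt(dens$vol_density_aabb, 1 + 1e-9)
  expect_gt(dens$vol_density_aabb, 0.8)
  sph <- make_sphere(21, spacing = c(1, 1, 1))
  ms <- smooth_mesh(build_mesh(sph$mask))
  ds <- density_features(sph$mask, ms)
  expect_equal(ds$vol_density_aabb, pi / 6, tolerance = 0.1)
  expect_lt(ds$vol_density_aabb, 1 + 1e-9)
})

test_that("center-of-mass shift: constant, hand example, scale invariance", {
  img <- image_volume(array(5, c(3, 3, 3)))
  msk <- mask_volume(array(TRUE, c(3, 3, 3)))
  expect_equal(com_shift(img, msk), 0)
  # two voxels at x = 0, 1 with intensities 1, 3: weighted x = 0.75
  im2 <- image_volume(array(c(1, 3), c(2, 1, 1)))
  mk2 <- mask_volume(array(TRUE, c(2, 1, 1)))
  expect_equal(com_shift(im2, mk2), 0.25)
  im2b <- im2; im2b$values <- im2$values * 2
  expect_equal(com_shift(im2b, mk2), 0.25)
})

test_that("Moran's I / Geary's C equal the O(N^2) oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    arr <- array(runif(6 * 5 * 4) > 0.4, c(6, 5, 4)); arr[2, 2, 2] <- TRUE
    msk <- mask_volume(arr, spacing = c(1.1, 0.9, 2))
    img <- image_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                        spacing = c(1.1, 0.9, 2))
    got <- spatial_autocorrelation(img, msk)
    pts <- voxrad:::voxel_center_coords(msk, msk$values)
    ref <- oracle_moran_geary(pts, img$values[msk$values])
    expect_equal(got$morans_i, ref$morans_i, tolerance = 1e-10)
    expect_equal(got$gearys_c, ref$gearys_c, tolerance = 1e-10)
    # affine invariance
    img2 <- img; img2$values <- 3.2 * img$values - 7
    got2 <- spatial_autocorrelation(img2, msk)
    expect_equal(got2$morans_i, got$morans_i)
    expect_equal(got2$gearys_c, got$gearys_c)
  }
  # two voxels, values {0, 1}: I = -1; C from the same closed form
  im <- image_volume(array(c(0, 1), c(2, 1, 1)))
  mk <- mask_volume(array(TRUE, c(2, 1, 1)))
  got <- spatial_autocorrelation(im, mk)
  expect_equal(got$morans_i, -1)
  ref <- oracle_moran_geary(matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE),
                            c(0, 1))
  expect_equal(got$gearys_c, ref$gearys_c)
  # constant: NaN with warning
  imc <- image_volume(array(1, c(2, 1, 1)))
  expect_warning(r <- spatial_autocorrelation(imc, mk), "constant")
  expect_true(is.nan(r$morans_i))
})

test_that("intensity peaks: constant image, hot voxel, dominance", {
  img <- image_volume(array(4.2, c(8, 8, 8)), spacing = c(2, 2, 2))
  msk <- mask_volume(array(TRUE, c(8, 8, 8)), spacing = c(2, 2, 2))
  pk <- intensity_peaks(img, msk)
  expect_equal(pk$local_peak, 4.2)
  expect_equal(pk$global_peak, 4.2)
  # single hot voxel in a zero background, 2 mm isotropic: the local peak
  # averages over the enumerated 1 cm^3 neighbourhood
  arr <- array(0, c(11, 11, 11)); arr[6, 6, 6] <- 100
  img2 <- image_volume(arr, spacing = c(2, 2, 2))
  msk2 <- mask_volume(array(TRUE, c(11, 11, 11)), spacing = c(2, 2, 2))
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  cnt <- 0
  for (dx in -3:3) for (dy in -3:3) for (dz in -3:3)
    if (sqrt(sum((c(dx, dy, dz) * 2)^2)) <= r) cnt <- cnt + 1
  pk2 <- intensity_peaks(img2, msk2)
  expect_equal(pk2$local_peak, 100 / cnt)
  expect_gte(pk2$global_peak, pk2$local_peak)
  # global >= local on random images
  set.seed(4)
  img3 <- image_volume(array(rnorm(1000), c(10, 10, 10)),
                       spacing = c(2, 2, 2))
  msk3 <- mask_volume(array(runif(1000) > 0.3, c(10, 10, 10)),
                      spacing = c(2, 2, 2))
  pk3 <- intensity_peaks(img3, msk3)
  expect_gte(pk3$global_peak, pk3$local_peak)
})

test_that("sphere mesh volume converges to the analytic value", {
  d <- 17
  errs <- vapply(list(c(2.4, 2.4, 2.4), c(1.6, 1.6, 1.6), c(1, 1, 1)),
                 function(sp) {
                   me <- smooth_mesh(build_mesh(make_sphere(d, sp)$mask))
                   abs(mesh_volume(me) - 4 / 3 * pi * (d / 2)^3)
                 }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("raw mesh volume lies below the voxel-count volume on spheres", {
  for (d in c(37, 28, 21, 17)) {
    ph <- make_sphere(d)
    raw <- build_mesh(ph$mask)
    vcount <- sum(ph$mask$values) * prod(ph$mask$spacing)
    expect_lt(mesh_volume(raw), vcount)
  }
})

test_that("morphology features are invariant under grid translation", {
  ph <- make_sphere(13, spacing = c(1.5, 1.5, 1.5))
  shifted_img <- ph$image; shifted_img$origin <- c(100, -50, 25)
  shifted_msk <- ph$mask; shifted_msk$origin <- c(100, -50, 25)
  a <- suppressWarnings(morphology_features(ph$image, ph$mask,
                                            smooth_iterations = 5))
  b <- suppressWarnings(morphology_features(shifted_img, shifted_msk,
                                            smooth_iterations = 5))
  for (nm in setdiff(names(a), c("Morans I", "Gearys C")))
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-8, label = nm)
})
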