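# Seeded grids used across the family-vs-oracle checks (<= 6x6x4, Ng <= 4),
# one full mask and one irregular mask per size.
texture_cases <- list(
  make_grid(c(6, 6, 4), 4, seed = 101),
  make_grid(c(5, 4, 3), 3, seed = 202),
  random_roi_grid(c(6, 6, 4), 4, seed = 303),
  random_roi_grid(c(4, 4, 4), 2, seed = 404)
)

test_that("GLCM matrices equal exhaustive pair enumeration, all offsets", {
  for (g in texture_cases) {
    for (t in seq_len(13)) {
      off <- direction_offsets("3D")[t, ]
      expect_equal(unname(glcm_matrix(g$levels, g$n_levels, off)) * 1,
                   oracle_glcm(g$levels, g$n_levels, off),
                   label = sprintf("offset %s", paste(off, collapse = ",")))
    }
  }
  # 1x1x2 ROI with levels (1, 2), x-offset within slice finds no pair;
  # the z-offset pairs them symmetrically
  lv <- array(c(1L, 2L), c(1, 1, 2))
  mz <- glcm_matrix(lv, 2, c(0, 0, 1))
  expect_equal(unname(mz) * 1, matrix(c(0, 1, 1, 0), 2, 2))
  # constant ROI: all mass on the diagonal
  mc <- glcm_matrix(array(1L, c(3, 3, 1)), 2, c(1, 0, 0))
  expect_true(all(mc[2, ] == 0) && all(mc[, 2] == 0) && mc[1, 1] > 0)
})

test_that("GLRLM matrices equal the run-walking oracle, all offsets", {
  for (g in texture_cases) {
    for (t in seq_len(13)) {
      off <- direction_offsets("3D")[t, ]
      got <- glrlm_matrix(g$levels, g$n_levels, off)
      ref <- oracle_glrlm(g$levels, g$n_levels, off)
      expect_equal(unname(got)[, seq_len(ncol(ref)), drop = FALSE] * 1,
                   ref)
      # run-length conservation per direction
      expect_equal(sum(got %*% seq_len(ncol(got))),
                   sum(!is.na(g$levels)))
    }
  }
  # constant N-voxel line: single run; SRE = 1/N^2, LRE = N^2
  n <- 6
  lv <- array(1L, c(n, 1, 1))
  m <- glrlm_matrix(lv, 1, c(1, 0, 0))
  f <- glrlm_features(m, n)
  expect_equal(f[["short run emphasis"]], 1 / n^2)
  expect_equal(f[["long runs emphasis"]], n^2)
  expect_equal(f[["Run percentage"]], 1 / n)
})

test_that("GLSZM matrices equal the label-propagation oracle", {
  for (g in texture_cases) {
    got <- glszm_matrix(g$levels, g$n_levels, "3D")
    ref <- oracle_glszm(g$levels, g$n_levels, TRUE)
    expect_equal(unname(got)[, seq_len(ncol(ref)), drop = FALSE] * 1, ref)
    expect_equal(sum(got %*% seq_len(ncol(got))), sum(!is.na(g$levels)))
    # per-slice 2D zones
    for (k in seq_len(dim(g$levels)[3])) {
      sl <- g$levels[, , k, drop = FALSE]
      if (all(is.na(sl))) next
      expect_equal(unname(glszm_matrix(sl, g$n_levels, "2D")) * 1,
                   oracle_glszm(sl, g$n_levels, FALSE))
    }
  }
  # constant ROI: one zone of size Nv, zone percentage 1/Nv
  lv <- array(1L, c(4, 3, 2))
  f <- glszm_features(glszm_matrix(lv, 1, "3D"), 24)
  expect_equal(f[["Zone percentage GLSZM"]], 1 / 24)
})

test_that("GLDZM distances equal the BFS oracle; marginals match GLSZM", {
  for (g in texture_cases) {
    got <- gldzm_matrix(g$levels, g$n_levels, g$morph, "3D")
    ref <- oracle_gldzm(g$levels, g$n_levels, g$morph, TRUE)
    expect_equal(unname(got)[, seq_len(ncol(ref)), drop = FALSE] * 1, ref)
    # GLDZM and GLSZM share grey-level marginals (same zones)
    gz <- glszm_matrix(g$levels, g$n_levels, "3D")
    expect_equal(rowSums(got), rowSums(gz))
  }
  # single-voxel ROI touches outside immediately: distance 1
  lv1 <- array(NA_integer_, c(3, 3, 1)); lv1[2, 2, 1] <- 1L
  m1 <- gldzm_matrix(lv1, 1, array(TRUE, c(3, 3, 1)) & !is.na(lv1), "2D")
  expect_equal(unname(m1) * 1, matrix(1, 1, 1))
  # 5x5x1 full single-level ROI: distance map peaks at 3, zone distance 1
  lv5 <- array(1L, c(5, 5, 1))
  dmap <- voxrad:::.distance_map(array(TRUE, c(5, 5, 1)), "2D")
  expect_equal(dmap[3, 3, 1], 3)
  expect_equal(dmap, oracle_distance_map(array(TRUE, c(5, 5, 1)), FALSE))
  m5 <- gldzm_matrix(lv5, 1, array(TRUE, c(5, 5, 1)), "2D")
  expect_equal(which(m5[1, ] > 0), 1L)
})

test_that("NGTDM difference vectors equal the neighbourhood-mean oracle", {
  for (g in texture_cases) {
    got <- ngtdm_matrix(g$levels, g$n_levels, "3D")
    ref <- oracle_ngtdm(g$levels, g$n_levels, TRUE)
    expect_equal(got$s, ref$s)
    expect_equal(got$n, ref$n)
  }
  # 3x3 slice, center level 2 in a ring of 1s
  lv <- array(1L, c(3, 3, 1)); lv[2, 2, 1] <- 2L
  m <- ngtdm_matrix(lv, 2, "2D")
  expect_equal(m$s[2], 1)              # |2 - mean(eight 1s)| = 1
  ring <- oracle_ngtdm(lv, 2, FALSE)
  expect_equal(m$s[1], ring$s[1])
  # constant ROI: zero differences, coarseness capped, contrast 0
  lvc <- array(1L, c(3, 3, 3))
  f <- ngtdm_features(ngtdm_matrix(lvc, 1, "3D"))
  expect_equal(unname(f["coarseness"]), 1e6)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["complexity"]), 0)
})

test_that("NGLDM matrices equal the neighbour-count oracle; DCP is 1", {
  for (g in texture_cases) {
    for (alpha in c(0, 1)) {
      got <- ngldm_matrix(g$levels, g$n_levels, "3D", alpha)
      ref <- oracle_ngldm(g$levels, g$n_levels, TRUE, alpha)
      expect_equal(unname(got)[, seq_len(ncol(ref)), drop = FALSE] * 1,
                   ref)
    }
    f <- ngldm_features(ngldm_matrix(g$levels, g$n_levels, "3D", 0),
                        sum(!is.na(g$levels)))
    expect_equal(unname(f["Dependence count percentage"]), 1)
  }
  # constant 3x3x3 full ROI: the center voxel has dependence count 26
  m <- ngldm_matrix(array(1L, c(3, 3, 3)), 1, "3D", 0)
  expect_equal(m[1, 27], 1L)
})

test_that("normalized texture matrices sum to one in every scheme", {
  g <- texture_cases[[3]]
  for (t in seq_len(13)) {
    off <- direction_offsets("3D")[t, ]
    for (m in list(glcm_matrix(g$levels, g$n_levels, off),
                   glrlm_matrix(g$levels, g$n_levels, off)))
      if (sum(m) > 0) expect_equal(sum(m / sum(m)), 1)
  }
  for (m in list(glszm_matrix(g$levels, g$n_levels, "3D"),
                 gldzm_matrix(g$levels, g$n_levels, g$morph, "3D"),
                 ngldm_matrix(g$levels, g$n_levels, "3D", 0)))
    expect_equal(sum(m / sum(m)), 1)
})

test_that("GLCM features: point mass, checkerboard, identities", {
  # constant ROI
  f <- glcm_features(glcm_matrix(array(1L, c(4, 4, 1)), 1, c(1, 0, 0)))
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["joint maximum"]], 1)
  expect_equal(f[["angular second moment"]], 1)
  expect_equal(f[["joint entropy"]], 0)
  # 2-level checkerboard, in-plane offset: only (1,2)/(2,1) pairs
  chk <- array(0L, c(6, 6, 1))
  for (i in 1:6) for (j in 1:6) chk[i, j, 1] <- 1L + (i + j) %% 2L
  fc <- glcm_features(glcm_matrix(chk, 2, c(1, 0, 0)))
  expect_equal(fc[["contrast"]], 1)
  expect_equal(fc[["correlation"]], -1)
  # cluster tendency equals sum variance on any matrix
  for (g in texture_cases[1:2]) {
    fm <- glcm_features(glcm_matrix(g$levels, g$n_levels, c(1, 1, 0)))
    expect_equal(fm[["cluster tendency"]], fm[["sum variance"]])
  }
  # empty matrix: warning and NULL
  expect_warning(fn <- glcm_features(matrix(0, 3, 3)), "empty")
  expect_null(fn)
})

test_that("aggregation schemes merge counts before normalization", {
  g <- texture_cases[[1]]
  lv <- g$levels; ng <- g$n_levels
  offs <- direction_offsets("2D")
  # MERGED_2D count matrix equals the elementwise sum of all per-slice
  # per-direction matrices (additivity oracle via features on the sum)
  mats <- list()
  for (k in seq_len(dim(lv)[3])) for (t in seq_len(nrow(offs)))
    mats[[length(mats) + 1]] <-
      oracle_glcm(lv[, , k, drop = FALSE], ng, offs[t, ])
  merged_ref <- Reduce(`+`, mats)
  got <- texture_features(g, "GLCM", "MERGED_2D")
  expect_equal(got, glcm_features(merged_ref))
  # MERGED_3D likewise over the 13 3D offsets
  mats3 <- lapply(seq_len(13), function(t)
    oracle_glcm(lv, ng, direction_offsets("3D")[t, ]))
  expect_equal(texture_features(g, "GLCM", "MERGED_3D"),
               glcm_features(Reduce(`+`, mats3)))
  # AVG_2D equals the arithmetic mean of per-matrix features
  per <- lapply(mats, glcm_features)
  expect_equal(texture_features(g, "GLCM", "AVG_2D"),
               rowMeans(do.call(cbind, per)))
  # GLRLM DIR_MERGED_2D: per-direction slice sums, averaged over directions
  nvt <- sum(!is.na(lv))
  per_dir <- lapply(seq_len(nrow(offs)), function(t) {
    md <- Reduce(function(a, b) {
      w <- max(ncol(a), ncol(b))
      pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
      pad(a) + pad(b)
    }, lapply(seq_len(dim(lv)[3]), function(k)
      oracle_glrlm(lv[, , k, drop = FALSE], ng, offs[t, ])))
    glrlm_features(md, nvt)
  })
  expect_equal(texture_features(g, "GLRLM", "DIR_MERGED_2D"),
               rowMeans(do.call(cbind, per_dir)))
})

test_that("degenerate single-slice single-direction merges coincide", {
  lv <- array(c(1L, 2L, 1L, 2L, 2L, 1L), c(3, 2, 1))
  g <- voxrad:::new_discretized_roi(lv, 2, list(method = "FBN"),
                                    array(TRUE, dim(lv)), c(1, 1, 1),
                                    c(0, 0, 0))
  # one slice: AVG_2D and SLICE_MERGED_2D differ only via direction
  # merging; with all four direction matrices equal they coincide with
  # MERGED_2D features up to the count scaling, which normalization removes
  f_slice <- texture_features(g, "GLCM", "SLICE_MERGED_2D")
  f_vol <- texture_features(g, "GLCM", "MERGED_2D")
  expect_equal(f_slice, f_vol)
  f_gl <- texture_features(g, "GLRLM", "SLICE_MERGED_2D")
  f_gv <- texture_features(g, "GLRLM", "MERGED_2D")
  expect_equal(f_gl, f_gv)
})

test_that("constant images give scheme-independent degenerate features", {
  lv <- array(1L, c(4, 4, 3))
  g <- voxrad:::new_discretized_roi(lv, 1, list(method = "FBN"),
                                    array(TRUE, dim(lv)), c(1, 1, 1),
                                    c(0, 0, 0))
  for (sch in c("AVG_2D", "SLICE_MERGED_2D", "DIR_MERGED_2D", "MERGED_2D",
                "AVG_3D", "MERGED_3D")) {
    f <- texture_features(g, "GLCM", sch)
    expect_equal(f[["contrast"]], 0, label = sch)
    expect_equal(f[["joint entropy"]], 0, label = sch)
  }
})

test_that("GLCM features are invariant under 180-degree rotation", {
  for (g in texture_cases[c(1, 3)]) {
    rot <- g
    rot$levels <- g$levels[dim(g$levels)[1]:1, dim(g$levels)[2]:1, ,
                           drop = FALSE]
    rot$morph <- g$morph[dim(g$morph)[1]:1, dim(g$morph)[2]:1, ,
                         drop = FALSE]
    expect_equal(texture_features(g, "GLCM", "MERGED_2D"),
                 texture_features(rot, "GLCM", "MERGED_2D"))
  }
})

test_that("scheme/family mismatches raise configuration errors", {
  g <- texture_cases[[2]]
  expect_error(texture_features(g, "GLSZM", "AVG_3D"), "configuration")
  expect_error(texture_features(g, "NGTDM", "DIR_MERGED_2D"),
               "configuration")
})

test_that("slices with empty matrices are skipped, not averaged as zeros", {
  lv <- array(NA_integer_, c(2, 2, 3))
  lv[, , 1] <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  lv[1, 1, 2] <- 1L                    # lone voxel: no pairs in-slice
  g <- voxrad:::new_discretized_roi(lv, 2, list(method = "FBN"),
                                    !is.na(lv), c(1, 1, 1), c(0, 0, 0))
  f <- suppressWarnings(texture_features(g, "GLCM", "AVG_2D"))
  only1 <- suppressWarnings(texture_features(
    voxrad:::new_discretized_roi(lv[, , 1, drop = FALSE], 2,
                                 list(method = "FBN"),
                                 !is.na(lv[, , 1, drop = FALSE]),
                                 c(1, 1, 1), c(0, 0, 0)),
    "GLCM", "AVG_2D"))
  expect_equal(f, only1)
})
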