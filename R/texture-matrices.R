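#' Texture direction sets
#'
#' Unit-Chebyshev-distance displacement vectors, one per direction up to
#' negation: 4 in-plane directions for 2D, 13 for 3D.
#'
#' @param dimensionality `"2D"` or `"3D"`.
#' @return Integer matrix with one offset `(dx, dy, dz)` per row.
#' @export
direction_offsets <- function(dimensionality = c("3D", "2D")) {
  dimensionality <- match.arg(dimensionality)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g <- g[keep, , drop = FALSE]
  if (dimensionality == "2D") g <- g[g[, 3] == 0, , drop = FALSE]
  unname(g)
}

## all neighbourhood offsets (Chebyshev ball minus center): 26 in 3D, 8 in 2D
neighbourhood_offsets <- function(dimensionality = c("3D", "2D")) {
  dimensionality <- match.arg(dimensionality)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  if (dimensionality == "2D") g <- g[g[, 3] == 0, , drop = FALSE]
  unname(g)
}

## index ranges of the overlap of an array with its copy shifted by `off`
.shift_ranges <- function(d, off) {
  lapply(1:3, function(ax) {
    lo <- max(1, 1 - off[ax]); hi <- min(d[ax], d[ax] - off[ax])
    if (lo > hi) integer(0) else lo:hi
  })
}

## paired level vectors (a at v, b at v + off), both inside the ROI
.level_pairs <- function(lv, off) {
  d <- dim(lv)
  r <- .shift_ranges(d, off)
  if (any(lengths(r) == 0)) return(list(a = integer(0), b = integer(0)))
  a <- lv[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b <- lv[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts level pairs `(g(v), g(v + offset))` for voxel pairs inside the
#' ROI, symmetrized by adding the transpose. Normalization to probabilities
#' happens at feature time.
#'
#' @param levels integer 3D array of grey levels (`NA` outside the ROI),
#'   e.g. the `levels` field of a `discretized_roi` (possibly a single
#'   slice).
#' @param n_levels number of grey levels (matrix side).
#' @param offset integer displacement `(dx, dy, dz)`.
#' @return `n_levels` x `n_levels` count matrix.
#' @export
glcm_matrix <- function(levels, n_levels, offset) {
  p <- .level_pairs(levels, offset)
  m <- matrix(tabulate((p$a - 1L) * n_levels + p$b,
                       nbins = n_levels * n_levels),
              n_levels, n_levels, byrow = TRUE)
  m + t(m)
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal runs of equal grey level along the offset direction.
#'
#' @inheritParams glcm_matrix
#' @return Count matrix indexed (grey level, run length).
#' @export
glrlm_matrix <- function(levels, n_levels, offset) {
  d <- dim(levels)
  ## run starts: ROI voxels whose predecessor along -offset is absent/different
  prev <- array(NA_integer_, d)
  r <- .shift_ranges(d, -offset)
  if (!any(lengths(r) == 0))
    prev[r[[1]], r[[2]], r[[3]]] <-
      levels[r[[1]] - offset[1], r[[2]] - offset[2], r[[3]] - offset[3]]
  is_start <- !is.na(levels) & (is.na(prev) | prev != levels)
  starts <- which(is_start, arr.ind = TRUE)
  if (nrow(starts) == 0) return(matrix(0, n_levels, 1))
  lev <- levels[is_start]
  len <- rep(1L, nrow(starts))
  pos <- starts
  active <- rep(TRUE, nrow(starts))
  while (any(active)) {
    pos[active, ] <- pos[active, , drop = FALSE] +
      rep(offset, each = sum(active))
    ia <- which(active)
    inb <- pos[ia, 1] >= 1 & pos[ia, 1] <= d[1] &
      pos[ia, 2] >= 1 & pos[ia, 2] <= d[2] &
      pos[ia, 3] >= 1 & pos[ia, 3] <= d[3]
    same <- rep(FALSE, length(ia))
    if (any(inb)) {
      nxt <- levels[pos[ia[inb], , drop = FALSE]]
      same[inb] <- !is.na(nxt) & nxt == lev[ia[inb]]
    }
    len[ia[same]] <- len[ia[same]] + 1L
    active[ia[!same]] <- FALSE
  }
  maxlen <- max(len)
  matrix(tabulate((lev - 1L) * maxlen + len, nbins = n_levels * maxlen),
         n_levels, maxlen, byrow = TRUE)
}

## linear-index flood fill over equal-level ROI voxels; returns a list of
## zones, each holding the level and the member linear indices
.zones <- function(levels, conn_offsets) {
  d <- dim(levels)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  off_l <- conn_offsets[, 1] + conn_offsets[, 2] * nx +
    conn_offsets[, 3] * nx * ny
  seen <- array(FALSE, d)
  out <- list()
  roi <- which(!is.na(levels))
  for (v0 in roi) {
    if (seen[v0]) next
    g <- levels[v0]
    stack <- v0
    seen[v0] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      i <- (v - 1L) %% nx + 1L
      j <- ((v - 1L) %/% nx) %% ny + 1L
      k <- (v - 1L) %/% (nx * ny) + 1L
      for (t in seq_len(nrow(conn_offsets))) {
        ii <- i + conn_offsets[t, 1]; jj <- j + conn_offsets[t, 2]
        kk <- k + conn_offsets[t, 3]
        if (ii < 1 || ii > nx || jj < 1 || jj > ny || kk < 1 || kk > nz)
          next
        w <- v + off_l[t]
        if (!seen[w] && !is.na(levels[w]) && levels[w] == g) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    out[[length(out) + 1L]] <- list(level = g, cells = members)
  }
  out
}

#' Grey-level size-zone matrix
#'
#' Zones are connected components of equal grey level; connectivity is
#' 26-neighbour in 3D and 8-neighbour within a slice in 2D.
#'
#' @inheritParams glcm_matrix
#' @param dimensionality `"3D"` or `"2D"` (pass single slices for 2D).
#' @return Count matrix indexed (grey level, zone size).
#' @export
glszm_matrix <- function(levels, n_levels, dimensionality = "3D") {
  zs <- .zones(levels, neighbourhood_offsets(dimensionality))
  if (!length(zs)) return(matrix(0, n_levels, 1))
  sizes <- vapply(zs, function(z) length(z$cells), integer(1))
  levs <- vapply(zs, function(z) z$level, integer(1))
  maxsz <- max(sizes)
  matrix(tabulate((levs - 1L) * maxsz + sizes, nbins = n_levels * maxsz),
         n_levels, maxsz, byrow = TRUE)
}

## city-block distance map on the morphological mask: 1 at voxels touching
## outside (or the image border), growing inward; 6-connected in 3D,
## 4-connected in-plane in 2D
.distance_map <- function(morph, dimensionality = "3D") {
  d <- dim(morph)
  offs <- neighbourhood_offsets(dimensionality)
  offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  dist <- array(NA_real_, d)
  frontier <- morph & FALSE
  ## distance 1: any neighbour outside mask or outside image
  for (t in seq_len(nrow(offs))) {
    o <- offs[t, ]
    nb <- array(FALSE, d)          # neighbour-inside indicator
    r <- .shift_ranges(d, o)
    if (!any(lengths(r) == 0))
      nb[r[[1]], r[[2]], r[[3]]] <-
        morph[r[[1]] + o[1], r[[2]] + o[2], r[[3]] + o[3]]
    frontier <- frontier | (morph & !nb)
  }
  dist[frontier] <- 1
  cur <- frontier
  lvl <- 1
  while (any(cur)) {
    nxt <- array(FALSE, d)
    for (t in seq_len(nrow(offs))) {
      o <- offs[t, ]
      r <- .shift_ranges(d, o)
      if (any(lengths(r) == 0)) next
      shifted <- array(FALSE, d)
      shifted[r[[1]], r[[2]], r[[3]]] <-
        cur[r[[1]] + o[1], r[[2]] + o[2], r[[3]] + o[3]]
      nxt <- nxt | shifted
    }
    nxt <- nxt & morph & is.na(dist)
    lvl <- lvl + 1
    dist[nxt] <- lvl
    cur <- nxt
  }
  dist
}

#' Grey-level distance-zone matrix
#'
#' Zones as in [glszm_matrix()]; the distance of a zone is the minimum over
#' its voxels of the city-block distance to outside the morphological mask
#' (boundary voxels have distance 1).
#'
#' @inheritParams glszm_matrix
#' @param morph logical array: the morphological mask the distances are
#'   measured against (same shape as `levels`).
#' @return Count matrix indexed (grey level, zone distance).
#' @export
gldzm_matrix <- function(levels, n_levels, morph, dimensionality = "3D") {
  zs <- .zones(levels, neighbourhood_offsets(dimensionality))
  if (!length(zs)) return(matrix(0, n_levels, 1))
  dmap <- .distance_map(morph, dimensionality)
  dists <- vapply(zs, function(z) min(dmap[z$cells]), numeric(1))
  levs <- vapply(zs, function(z) z$level, integer(1))
  maxd <- max(dists)
  matrix(tabulate((levs - 1L) * maxd + dists, nbins = n_levels * maxd),
         n_levels, maxd, byrow = TRUE)
}

## neighbour sums/counts over the Chebyshev-1 neighbourhood, ROI-restricted
.neighbour_stats <- function(levels, dimensionality) {
  d <- dim(levels)
  offs <- neighbourhood_offsets(dimensionality)
  sums <- array(0, d)
  cnts <- array(0L, d)
  for (t in seq_len(nrow(offs))) {
    o <- offs[t, ]
    r <- .shift_ranges(d, o)
    if (any(lengths(r) == 0)) next
    nb <- array(NA_integer_, d)
    nb[r[[1]], r[[2]], r[[3]]] <-
      levels[r[[1]] + o[1], r[[2]] + o[2], r[[3]] + o[3]]
    ok <- !is.na(nb)
    sums[ok] <- sums[ok] + nb[ok]
    cnts[ok] <- cnts[ok] + 1L
  }
  list(sums = sums, cnts = cnts)
}

#' Neighbourhood grey-tone difference matrix
#'
#' For every ROI voxel with at least one valid (ROI) neighbour in its
#' Chebyshev-1 neighbourhood, accumulates `|level - mean neighbour level|`
#' per grey level. Partial neighbourhoods at ROI or image borders are
#' valid.
#'
#' @inheritParams glszm_matrix
#' @return List with `s` (summed absolute differences per level), `n`
#'   (contributing-voxel count per level) and `n_levels`.
#' @export
ngtdm_matrix <- function(levels, n_levels, dimensionality = "3D") {
  ns <- .neighbour_stats(levels, dimensionality)
  ok <- !is.na(levels) & ns$cnts > 0L
  lv <- levels[ok]
  diffs <- abs(lv - ns$sums[ok] / ns$cnts[ok])
  s <- numeric(n_levels)
  acc <- tapply(diffs, factor(lv, levels = seq_len(n_levels)), sum)
  s[!is.na(acc)] <- acc[!is.na(acc)]
  list(s = s, n = tabulate(lv, nbins = n_levels), n_levels = n_levels)
}

#' Neighbouring grey-level dependence matrix
#'
#' The dependence count of a voxel is the number of Chebyshev-1 neighbours
#' whose level differs by at most `alpha`; incomplete neighbourhoods at the
#' borders are allowed, so every ROI voxel has a defined count.
#'
#' @inheritParams glszm_matrix
#' @param alpha level-difference tolerance (default 0: exact equality).
#' @return Count matrix indexed (grey level, dependence count + 1).
#' @export
ngldm_matrix <- function(levels, n_levels, dimensionality = "3D",
                         alpha = 0) {
  d <- dim(levels)
  offs <- neighbourhood_offsets(dimensionality)
  dep <- array(0L, d)
  for (t in seq_len(nrow(offs))) {
    o <- offs[t, ]
    r <- .shift_ranges(d, o)
    if (any(lengths(r) == 0)) next
    nb <- array(NA_integer_, d)
    nb[r[[1]], r[[2]], r[[3]]] <-
      levels[r[[1]] + o[1], r[[2]] + o[2], r[[3]] + o[3]]
    hit <- !is.na(levels) & !is.na(nb) & abs(levels - nb) <= alpha
    dep[hit] <- dep[hit] + 1L
  }
  ok <- !is.na(levels)
  lv <- levels[ok]
  k1 <- dep[ok] + 1L                      # dependence count k stored at k+1
  maxk <- max(k1)
  matrix(tabulate((lv - 1L) * maxk + k1, nbins = n_levels * maxk),
         n_levels, maxk, byrow = TRUE)
}
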