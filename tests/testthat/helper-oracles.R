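# Brute-force reference implementations, written independently of the
# package internals: plain loops, no shared helpers. `lv` is always an
# integer 3D array with NA outside the ROI.

oracle_glcm <- function(lv, ng, off) {
  d <- dim(lv)
  m <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
      next
    b <- lv[ii, jj, kk]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

oracle_glrlm <- function(lv, ng, off) {
  d <- dim(lv)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    pi_ <- i - off[1]; pj <- j - off[2]; pk <- k - off[3]
    prev_same <- pi_ >= 1 && pi_ <= d[1] && pj >= 1 && pj <= d[2] &&
      pk >= 1 && pk <= d[3] && !is.na(lv[pi_, pj, pk]) &&
      lv[pi_, pj, pk] == a
    if (prev_same) next                       # not a run start
    len <- 1
    ci <- i + off[1]; cj <- j + off[2]; ck <- k + off[3]
    while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] &&
           ck >= 1 && ck <= d[3] && !is.na(lv[ci, cj, ck]) &&
           lv[ci, cj, ck] == a) {
      len <- len + 1
      ci <- ci + off[1]; cj <- cj + off[2]; ck <- ck + off[3]
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  if (!length(runs)) return(matrix(0, ng, 1))
  rr <- do.call(rbind, runs)
  m <- matrix(0, ng, max(rr[, 2]))
  for (t in seq_len(nrow(rr))) m[rr[t, 1], rr[t, 2]] <-
      m[rr[t, 1], rr[t, 2]] + 1
  m
}

# connectivity offsets for the zone oracles
.oracle_conn <- function(three_d) {
  g <- expand.grid(-1:1, -1:1, if (three_d) -1:1 else 0)
  g <- as.matrix(g[rowSums(abs(g)) > 0, ])
  unname(g)
}

# recursive label propagation (repeat-until-stable), very different from
# the package's stack flood fill
oracle_zone_labels <- function(lv, three_d) {
  d <- dim(lv)
  lab <- array(0L, d)
  lab[!is.na(lv)] <- seq_len(sum(!is.na(lv)))
  conn <- .oracle_conn(three_d)
  repeat {
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        if (is.na(lv[i, j, k])) next
        for (t in seq_len(nrow(conn))) {
          ii <- i + conn[t, 1]; jj <- j + conn[t, 2]; kk <- k + conn[t, 3]
          if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
              kk < 1 || kk > d[3]) next
          if (is.na(lv[ii, jj, kk])) next
          if (lv[ii, jj, kk] == lv[i, j, k] &&
              lab[ii, jj, kk] < lab[i, j, k]) {
            lab[i, j, k] <- lab[ii, jj, kk]
            changed <- TRUE
          }
        }
      }
    if (!changed) break
  }
  lab
}

oracle_glszm <- function(lv, ng, three_d) {
  lab <- oracle_zone_labels(lv, three_d)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(matrix(0, ng, 1))
  sizes <- vapply(ids, function(z) sum(lab == z), integer(1))
  levs <- vapply(ids, function(z) lv[which(lab == z)[1]], integer(1))
  m <- matrix(0, ng, max(sizes))
  for (t in seq_along(ids)) m[levs[t], sizes[t]] <- m[levs[t], sizes[t]] + 1
  m
}

# breadth-first-search city-block distance to outside the morph mask
oracle_distance_map <- function(morph, three_d) {
  d <- dim(morph)
  conn <- .oracle_conn(three_d)
  conn <- conn[rowSums(abs(conn)) == 1, , drop = FALSE]
  dist <- array(Inf, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!morph[i, j, k]) next
    for (t in seq_len(nrow(conn))) {
      ii <- i + conn[t, 1]; jj <- j + conn[t, 2]; kk <- k + conn[t, 3]
      outside <- ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
        kk < 1 || kk > d[3] || !morph[ii, jj, kk]
      if (outside) dist[i, j, k] <- 1
    }
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        if (!morph[i, j, k]) next
        for (t in seq_len(nrow(conn))) {
          ii <- i + conn[t, 1]; jj <- j + conn[t, 2]; kk <- k + conn[t, 3]
          if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
              kk < 1 || kk > d[3]) next
          if (!morph[ii, jj, kk]) next
          if (dist[ii, jj, kk] + 1 < dist[i, j, k]) {
            dist[i, j, k] <- dist[ii, jj, kk] + 1
            changed <- TRUE
          }
        }
      }
    if (!changed) break
  }
  dist
}

oracle_gldzm <- function(lv, ng, morph, three_d) {
  lab <- oracle_zone_labels(lv, three_d)
  dmap <- oracle_distance_map(morph, three_d)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids)) return(matrix(0, ng, 1))
  dd <- vapply(ids, function(z) min(dmap[lab == z]), numeric(1))
  levs <- vapply(ids, function(z) lv[which(lab == z)[1]], integer(1))
  m <- matrix(0, ng, max(dd))
  for (t in seq_along(ids)) m[levs[t], dd[t]] <- m[levs[t], dd[t]] + 1
  m
}

oracle_ngtdm <- function(lv, ng, three_d) {
  d <- dim(lv)
  conn <- .oracle_conn(three_d)
  s <- numeric(ng); n <- integer(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    nb <- c()
    for (t in seq_len(nrow(conn))) {
      ii <- i + conn[t, 1]; jj <- j + conn[t, 2]; kk <- k + conn[t, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (!is.na(lv[ii, jj, kk])) nb <- c(nb, lv[ii, jj, kk])
    }
    if (!length(nb)) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1L
  }
  list(s = s, n = n)
}

oracle_ngldm <- function(lv, ng, three_d, alpha = 0) {
  d <- dim(lv)
  conn <- .oracle_conn(three_d)
  recs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    dep <- 0
    for (t in seq_len(nrow(conn))) {
      ii <- i + conn[t, 1]; jj <- j + conn[t, 2]; kk <- k + conn[t, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3]) next
      if (!is.na(lv[ii, jj, kk]) && abs(lv[ii, jj, kk] - a) <= alpha)
        dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(a, dep + 1)
  }
  rr <- do.call(rbind, recs)
  m <- matrix(0, ng, max(rr[, 2]))
  for (t in seq_len(nrow(rr))) m[rr[t, 1], rr[t, 2]] <-
      m[rr[t, 1], rr[t, 2]] + 1
  m
}

oracle_moran_geary <- function(pts, x) {
  n <- length(x)
  mu <- mean(x)
  num_i <- 0; num_c <- 0; sw <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    w <- 1 / sqrt(sum((pts[i, ] - pts[j, ])^2))
    sw <- sw + w
    num_i <- num_i + w * (x[i] - mu) * (x[j] - mu)
    num_c <- num_c + w * (x[i] - x[j])^2
  }
  ss <- sum((x - mu)^2)
  list(morans_i = n / sw * num_i / ss,
       gearys_c = (n - 1) / (2 * sw) * num_c / ss)
}

# signed divergence-theorem volume about an arbitrary reference point
oracle_mesh_volume <- function(mesh, ref = c(13.7, -4.2, 8.9)) {
  v <- sweep(mesh$vertices, 2, ref)
  tot <- 0
  for (t in seq_len(nrow(mesh$triangles))) {
    a <- v[mesh$triangles[t, 1], ]
    b <- v[mesh$triangles[t, 2], ]
    cc <- v[mesh$triangles[t, 3], ]
    tot <- tot + sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                           b[3] * cc[1] - b[1] * cc[3],
                           b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  abs(tot)
}

oracle_point_in_polygon <- function(px, py, poly) {
  # angle-summation (winding via atan2), different from the crossing rule
  n <- nrow(poly)
  ang <- 0
  for (t in seq_len(n)) {
    p1 <- poly[t, 1:2]; p2 <- poly[if (t == n) 1 else t + 1, 1:2]
    a1 <- atan2(p1[2] - py, p1[1] - px)
    a2 <- atan2(p2[2] - py, p2[1] - px)
    dd <- a2 - a1
    if (dd > pi) dd <- dd - 2 * pi
    if (dd < -pi) dd <- dd + 2 * pi
    ang <- ang + dd
  }
  abs(ang) > pi
}

# seeded ROI with an irregular (non-full) mask for property tests
random_roi_grid <- function(shape, ng, seed, frac = 0.8) {
  g <- make_grid(shape, ng, seed)
  lv <- g$levels
  set.seed(seed + 1000)
  drop <- sample(length(lv), round((1 - frac) * length(lv)))
  lv[drop] <- NA_integer_
  if (all(is.na(lv))) lv[1] <- 1L
  g$levels <- lv
  g
}
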