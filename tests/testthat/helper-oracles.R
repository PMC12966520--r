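# Pure-R voxel oracles, independent of the package's compiled kernels.
# All operate on logical 3D arrays and are written via zero-padded array
# shifts, not neighbour loops, so they share no code path with src/.

ora_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  as.matrix(g[keep, ])
}

ora_shift <- function(a, o) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
  sy <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
  sz <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
  out[sx, sy, sz] <- a[sx - o[1], sy - o[2], sz - o[3]]
  out
}

ora_dilate <- function(m, connectivity = 6) {
  out <- m
  offs <- ora_offsets(connectivity)
  for (i in seq_len(nrow(offs))) out <- out | ora_shift(m, offs[i, ])
  out
}

# flood-fill connected components
ora_components <- function(m, connectivity = 6) {
  lab <- array(0L, dim(m))
  remaining <- m
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    cur <- array(FALSE, dim(m))
    cur[which(remaining)[1]] <- TRUE
    repeat {
      nxt <- ora_dilate(cur, connectivity) & m
      if (identical(nxt, cur)) break
      cur <- nxt
    }
    lab[cur] <- k
    remaining <- remaining & !cur
  }
  lab
}

# breadth-first-search geodesic step count from a seed set within a domain
ora_geodesic <- function(domain, seeds, connectivity = 6) {
  dist <- array(Inf, dim(domain))
  frontier <- seeds & domain
  dist[frontier] <- 0
  k <- 0L
  repeat {
    nxt <- ora_dilate(frontier, connectivity) & domain & !is.finite(dist)
    if (!any(nxt)) break
    k <- k + 1L
    dist[nxt] <- k
    frontier <- nxt
  }
  dist
}

# axis-aligned tube mask builder (thin construction helper for fixtures)
tube_mask <- function(d, from, to, half = 0L) {
  m <- array(FALSE, d)
  n <- max(abs(to - from)) + 1L
  xs <- round(seq(from[1], to[1], length.out = n))
  ys <- round(seq(from[2], to[2], length.out = n))
  zs <- round(seq(from[3], to[3], length.out = n))
  for (i in seq_len(n)) {
    rx <- max(1, xs[i] - half):min(d[1], xs[i] + half)
    ry <- max(1, ys[i] - half):min(d[2], ys[i] + half)
    rz <- max(1, zs[i] - half):min(d[3], zs[i] + half)
    m[rx, ry, rz] <- TRUE
  }
  m
}

# small synthetic tree for fast shortening tests: aorta slab + branches
small_tree <- function(d = c(48, 48, 48)) {
  g <- array(0L, d)
  g[20:28, 20:28, 4:44] <- 1L                       # aorta block
  g[29:46, 23:25, 10:12] <- 2L                      # iliac +x
  g[29:46, 23:25, 30:32] <- 4L                      # renal +x
  g[23:25, 29:46, 24:26] <- 3L                      # mesenteric +y
  artery_label_map(g)
}

random_mask <- function(d, p, seed) {
  set.seed(seed)
  array(stats::runif(prod(d)) < p, d)
}

noiseless_config <- function(...) {
  phantom_config(lumen_hu_sd = 0, calc_hu_sd = 0, background_hu_sd = 0, ...)
}
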