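# Independent brute-force oracles used to cross-check the package's
# geometry and clustering implementations. These deliberately take the
# slow, direct route (exhaustive enumeration, rasterization) and share no
# code with the implementation paths they verify.

# exhaustive all-pairs nearest-neighbour distances
oracle_nnd <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    dd <- sqrt((x - x[i])^2 + (y - y[i])^2)
    min(dd[-i])
  }, numeric(1))
}

# convex hull area by shoelace on grDevices::chull
oracle_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# brute-force alpha-complex area: enumerate all triangles, keep those that
# are Delaunay (no other point strictly inside the circumcircle, checked
# point by point) with circumradius <= alpha, and measure the union of the
# kept triangles on a 1-nm raster
oracle_alpha_area <- function(pts, alpha, res = 1) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  tris <- utils::combn(n, 3)
  kept <- list()
  for (c in seq_len(ncol(tris))) {
    i <- tris[1, c]; j <- tris[2, c]; k <- tris[3, c]
    a <- pts[i, ]; b <- pts[j, ]; d <- pts[k, ]
    den <- 2 * (a[1] * (b[2] - d[2]) + b[1] * (d[2] - a[2]) +
                d[1] * (a[2] - b[2]))
    if (abs(den) < 1e-12) next
    a2 <- sum(a^2); b2 <- sum(b^2); d2 <- sum(d^2)
    ux <- (a2 * (b[2] - d[2]) + b2 * (d[2] - a[2]) + d2 * (a[2] - b[2])) / den
    uy <- (a2 * (d[1] - b[1]) + b2 * (a[1] - d[1]) + d2 * (b[1] - a[1])) / den
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    if (r2 > alpha^2 * (1 + 1e-12)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    dd <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (any(dd < r2 * (1 - 1e-9))) next
    kept[[length(kept) + 1L]] <- rbind(a, b, d)
  }
  if (length(kept) == 0L) return(0)
  rng_x <- range(pts[, 1]); rng_y <- range(pts[, 2])
  gx <- seq(rng_x[1] - res, rng_x[2] + res, by = res)
  gy <- seq(rng_y[1] - res, rng_y[2] + res, by = res)
  grid <- as.matrix(expand.grid(x = gx + res / 2, y = gy + res / 2))
  inside <- rep(FALSE, nrow(grid))
  in_tri <- function(p, tri) {
    s <- function(p1, p2, p3)
      (p1[, 1] - p3[1]) * (p2[2] - p3[2]) - (p2[1] - p3[1]) * (p1[, 2] - p3[2])
    d1 <- s(p, tri[1, ], tri[2, ])
    d2 <- s(p, tri[2, ], tri[3, ])
    d3 <- s(p, tri[3, ], tri[1, ])
    !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
  }
  for (tri in kept) inside <- inside | in_tri(grid, tri)
  sum(inside) * res^2
}

# brute-force single-linkage components over all pixel pairs
oracle_components <- function(i, j, pixel_size, linkage) {
  n <- length(i)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      d <- pixel_size * sqrt((i[a] - i[b])^2 + (j[a] - j[b])^2)
      if (d <= linkage + 1e-9 && comp[a] != comp[b]) {
        comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random non-overlapping axis-aligned-ish square layouts for NND tests
random_sparse_array <- function(n, seed, spacing = 80) {
  set.seed(seed)
  pos <- expand.grid(gx = 1:ceiling(sqrt(n)), gy = 1:ceiling(sqrt(n)))
  pos <- pos[sample.int(nrow(pos), n), ]
  data.frame(id = seq_len(n),
             x = pos$gx * spacing + runif(n, 0, spacing / 4),
             y = pos$gy * spacing + runif(n, 0, spacing / 4),
             theta = runif(n, 0, 90))
}
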