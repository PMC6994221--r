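#' Alpha-shape parameters
#'
#' @param alpha_radius disk radius of the alpha complex in nm (default 50,
#'   the same length scale as the cluster linkage rule).
#' @return list of class \code{"shape_params"}.
#' @export
shape_params <- function(alpha_radius = 50) {
  stopifnot(is.numeric(alpha_radius), alpha_radius > 0)
  structure(list(alpha_radius = alpha_radius), class = "shape_params")
}

#' Alpha-shape area of a planar point set
#'
#' The alpha shape generalises the convex hull to concave boundaries: the
#' Delaunay triangulation of the points is computed and only triangles whose
#' circumscribed-circle radius is at most \code{alpha_radius} are kept (the
#' alpha complex). The reported area is the summed area of the kept
#' triangles; as \code{alpha_radius} grows the shape converges to the convex
#' hull.
#'
#' @param points two-column matrix or data.frame of x, y coordinates (nm).
#' @param params a \code{\link{shape_params}} object (or a number, taken as
#'   the alpha radius in nm).
#' @return list of class \code{"alpha_shape"}: \code{area} (nm^2),
#'   \code{triangles} (m x 3 index matrix into the deduplicated points),
#'   \code{points}, \code{boundary_edges} (e x 2 index matrix of edges used
#'   by exactly one kept triangle), \code{alpha_radius}.
#' @examples
#' sq <- expand.grid(x = c(0, 100), y = c(0, 100))
#' alpha_shape_area(sq, shape_params(100))$area  # 10000
#' @export
alpha_shape_area <- function(points, params = shape_params()) {
  if (is.numeric(params) && length(params) == 1L) params <- shape_params(params)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("non-finite point coordinates")
  pts <- unique(pts)
  if (nrow(pts) < 3L)
    stop("alpha shape needs at least 3 distinct points")
  if (all_collinear(pts))
    stop("alpha shape is degenerate: all points are collinear")
  tri <- delaunay(pts, alpha = params$alpha_radius)
  keep <- tri$r2 <= params$alpha_radius^2 * (1 + 1e-12)
  tris <- tri$idx[keep, , drop = FALSE]
  area <- sum(vapply(seq_len(nrow(tris)), function(i)
    triangle_area(pts[tris[i, 1], ], pts[tris[i, 2], ], pts[tris[i, 3], ]),
    numeric(1)))
  edges <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  key <- paste(edges[, 1], edges[, 2])
  boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  structure(list(area = area, triangles = tris, points = pts,
                 boundary_edges = boundary,
                 alpha_radius = params$alpha_radius),
            class = "alpha_shape")
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("Alpha shape (radius %g nm): %d points, %d triangles, area %.1f nm^2\n",
              x$alpha_radius, nrow(x$points), nrow(x$triangles), x$area))
  invisible(x)
}

#' Tetramer coverage fraction of an array's alpha shape
#'
#' Ratio of the summed tetramer footprint area (\code{n * side^2}) to the
#' alpha-shape area drawn around all four corners of every tetramer. This is
#' the per-tomogram "coverage" used to convert dSTORM cluster areas into
#' tetramer counts. A single tetramer's shape is its own footprint, so its
#' coverage is exactly 1.
#'
#' @param array a \code{\link{tetramer_array}}.
#' @param params a \code{\link{shape_params}}.
#' @return coverage fraction (dimensionless, near (0, 1]).
#' @export
coverage_fraction <- function(array, params = shape_params()) {
  side <- attr(array, "side")
  n <- nrow(array)
  if (n == 0L) stop("empty tetramer array")
  if (n == 1L) return(1.0)
  corners <- array_corners(array)
  shp <- alpha_shape_area(corners, params)
  n * side^2 / shp$area
}

all_collinear <- function(pts) {
  p0 <- pts[1, ]
  v <- sweep(pts[-1, , drop = FALSE], 2, p0)
  crossp <- outer(v[, 1], v[, 2]) - outer(v[, 2], v[, 1])
  max(abs(crossp)) < 1e-9 * max(1, max(abs(v)))^2
}

triangle_area <- function(a, b, c) {
  abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

# Bowyer-Watson incremental Delaunay triangulation.
#
# The point-in-circumcircle test uses the standard 3x3 incircle determinant
# on coordinates relative to the query point, with counter-clockwise
# triangles and a strict > 0 comparison. On pixel-grid input (coordinates
# that are exact doubles) cocircular quads give an exactly zero determinant,
# so a point on a circle is never "inside" and either diagonal of such a
# quad may be produced; all four candidate triangles share one circumcircle,
# so the alpha inclusion test and the summed area are unaffected.
#
# Returns list(idx = m x 3 vertex indices, r2 = squared circumradii).
delaunay <- function(pts, alpha = Inf) {
  n <- nrow(pts)
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  mid <- (rng[1, ] + rng[2, ]) / 2
  # normalize into a centred O(1) box so the incircle determinant is
  # uniformly well-conditioned against the super-triangle; scaling by a
  # power of two keeps grid coordinates (and their cocircularity) exact
  scale <- 2^ceiling(log2(span))
  work <- sweep(pts, 2, mid) / scale
  # super-triangle placed beyond any circumcircle of radius <= alpha, so
  # every Delaunay triangle the alpha filter can keep is guaranteed to
  # survive super-vertex removal (hull slivers with larger circumradii may
  # attach to the super-triangle, but those are outside the alpha complex)
  big <- min(2 + 2 * alpha / scale, 1e7)
  sv <- rbind(c(-big, -big), c(big, -big), c(0, big))
  allp <- rbind(work, sv)
  cap <- 4L * n + 16L
  tri <- matrix(NA_integer_, cap, 3)
  alive <- logical(cap)
  ntri <- 0L
  env <- environment()
  add_tri <- function(i, j, k) {
    # enforce counter-clockwise orientation
    o <- (allp[j, 1] - allp[i, 1]) * (allp[k, 2] - allp[i, 2]) -
         (allp[k, 1] - allp[i, 1]) * (allp[j, 2] - allp[i, 2])
    if (o < 0) { tmp <- j; j <- k; k <- tmp }
    nt <- env$ntri + 1L
    if (nt > nrow(env$tri)) {
      env$tri <- rbind(env$tri, matrix(NA_integer_, nrow(env$tri), 3))
      env$alive <- c(env$alive, logical(length(env$alive)))
    }
    env$tri[nt, ] <- c(i, j, k)
    env$alive[nt] <- TRUE
    env$ntri <- nt
  }
  add_tri(n + 1L, n + 2L, n + 3L)
  ord <- order(pts[, 1], pts[, 2])
  for (p in ord) {
    px <- allp[p, 1]; py <- allp[p, 2]
    live <- which(alive[seq_len(ntri)])
    t1 <- tri[live, 1]; t2 <- tri[live, 2]; t3 <- tri[live, 3]
    adx <- allp[t1, 1] - px; ady <- allp[t1, 2] - py
    bdx <- allp[t2, 1] - px; bdy <- allp[t2, 2] - py
    cdx <- allp[t3, 1] - px; cdy <- allp[t3, 2] - py
    A <- adx * adx + ady * ady
    B <- bdx * bdx + bdy * bdy
    C <- cdx * cdx + cdy * cdy
    det <- adx * (bdy * C - B * cdy) -
           ady * (bdx * C - B * cdx) +
           A   * (bdx * cdy - bdy * cdx)
    bad <- live[det > 0]
    if (length(bad) == 0L) next  # duplicate-like degenerate point
    edges <- rbind(tri[bad, c(1, 2), drop = FALSE],
                   tri[bad, c(2, 3), drop = FALSE],
                   tri[bad, c(3, 1), drop = FALSE])
    se <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    key <- se[, 1] * (n + 4) + se[, 2]
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    alive[bad] <- FALSE
    for (e in which(once)) add_tri(edges[e, 1], edges[e, 2], p)
  }
  keep <- which(alive[seq_len(ntri)])
  idx <- tri[keep, , drop = FALSE]
  idx <- idx[rowSums(idx <= n) == 3L, , drop = FALSE]
  r2 <- vapply(seq_len(nrow(idx)), function(i)
    circumcircle(pts[idx[i, 1], ], pts[idx[i, 2], ], pts[idx[i, 3], ])[3],
    numeric(1))
  list(idx = idx, r2 = r2)
}

# circumcentre (x, y) and squared radius of triangle abc
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}
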