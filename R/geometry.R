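#' Geometric relation between two square tetramers
#'
#' Computes the quantities the arrangement classifier operates on: the
#' centre-to-centre distance, the minimal angular difference modulo 90
#' degrees, whether the two squares count as parallel, and — for parallel
#' pairs — the edge gap and edge overlap of the facing sides.
#'
#' Both squares are rotated into the frame of their mean orientation (the
#' bisector of the two orientations along the shorter modulo-90 arc), where
#' gap and overlap are measured on the facing-edge pair that minimises the
#' gap. For pairs within the default 10-degree parallel tolerance the
#' residual tilt of each square in that frame is below 5 degrees and is
#' ignored in the edge arithmetic; this defines the measurement.
#'
#' @param a,b tetramers: named lists, one-row data.frames or rows of a
#'   \code{\link{tetramer_array}} with fields \code{x}, \code{y},
#'   \code{theta} (degrees).
#' @param side common edge length in nm.
#' @param angle_tol parallelism tolerance in degrees, in \code{[0, 45]}.
#' @return list of class \code{"pair_relation"} with fields
#'   \code{centre_distance}, \code{delta_theta}, \code{parallel},
#'   \code{gap}, \code{overlap} (the last two are \code{NA} when the pair
#'   is not parallel).
#' @examples
#' a <- list(x = 0, y = 0, theta = 0)
#' b <- list(x = 28, y = 20, theta = 0)
#' pair_relation(a, b)  # gap 1 nm, overlap 7 nm: a checkerboard neighbour
#' @export
pair_relation <- function(a, b, side = 27, angle_tol = 10) {
  xa <- as.numeric(a$x); ya <- as.numeric(a$y); ta <- as.numeric(a$theta)
  xb <- as.numeric(b$x); yb <- as.numeric(b$y); tb <- as.numeric(b$theta)
  if (!all(is.finite(c(xa, ya, ta, xb, yb, tb))))
    stop("non-finite tetramer coordinates")
  stopifnot(angle_tol >= 0, angle_tol <= 45, side > 0)
  rel <- pair_relation_core(xa, ya, ta, xb, yb, tb, side, angle_tol)
  structure(rel, class = "pair_relation")
}

# Vector-friendly core; returns a plain list.
pair_relation_core <- function(xa, ya, ta, xb, yb, tb, side, angle_tol) {
  m <- abs(ta - tb) %% 90
  dtheta <- min(m, 90 - m)
  cd <- sqrt((xb - xa)^2 + (yb - ya)^2)
  if (dtheta > angle_tol)
    return(list(centre_distance = cd, delta_theta = dtheta,
                parallel = FALSE, gap = NA_real_, overlap = NA_real_))
  # mean orientation along the shorter modulo-90 arc
  sd <- ((tb - ta + 45) %% 90) - 45
  tm <- (ta + sd / 2) %% 90
  aa <- -tm * pi / 180
  dx <- (xb - xa) * cos(aa) - (yb - ya) * sin(aa)
  dy <- (xb - xa) * sin(aa) + (yb - ya) * cos(aa)
  u <- abs(dx); v <- abs(dy)
  gap_x <- u - side; ov_x <- side - v   # facing across x
  gap_y <- v - side; ov_y <- side - u   # facing across y
  if (ov_x > 0 && (ov_y <= 0 || gap_x <= gap_y)) {
    gap <- gap_x; ov <- min(ov_x, side)
  } else if (ov_y > 0) {
    gap <- gap_y; ov <- min(ov_y, side)
  } else {
    # corner-to-corner region: no facing-edge projection intersects
    if (u >= v) { gap <- gap_x } else { gap <- gap_y }
    ov <- 0
  }
  list(centre_distance = cd, delta_theta = dtheta, parallel = TRUE,
       gap = gap, overlap = ov)
}

#' @export
print.pair_relation <- function(x, ...) {
  cat(sprintf("Pair relation: centre distance %.2f nm, delta theta %.2f deg, %s\n",
              x$centre_distance, x$delta_theta,
              if (x$parallel) sprintf("parallel (gap %.2f nm, overlap %.2f nm)",
                                      x$gap, x$overlap) else "not parallel"))
  invisible(x)
}

#' Edge-arithmetic reference for \code{pair_relation}
#'
#' Independent route to the same quantities used for cross-checking: builds
#' the explicit square polygons in the mean-orientation frame, enumerates
#' facing edge pairs, and measures the support-line distance and the
#' projected-interval intersection with segment arithmetic. Agrees exactly
#' with \code{\link{pair_relation}}; kept as a verification path, not used
#' by the classifier.
#'
#' @inheritParams pair_relation
#' @return same structure as \code{\link{pair_relation}}.
#' @export
pair_relation_edges <- function(a, b, side = 27, angle_tol = 10) {
  xa <- as.numeric(a$x); ya <- as.numeric(a$y); ta <- as.numeric(a$theta)
  xb <- as.numeric(b$x); yb <- as.numeric(b$y); tb <- as.numeric(b$theta)
  m <- abs(ta - tb) %% 90
  dtheta <- min(m, 90 - m)
  cd <- sqrt((xb - xa)^2 + (yb - ya)^2)
  if (dtheta > angle_tol)
    return(structure(list(centre_distance = cd, delta_theta = dtheta,
                          parallel = FALSE, gap = NA_real_,
                          overlap = NA_real_), class = "pair_relation"))
  sd <- ((tb - ta + 45) %% 90) - 45
  tm <- (ta + sd / 2) %% 90
  rot <- function(p, ang) {
    a <- ang * pi / 180
    cbind(p[, 1] * cos(a) - p[, 2] * sin(a),
          p[, 1] * sin(a) + p[, 2] * cos(a))
  }
  # idealised axis-aligned squares in the mean frame (residual tilt ignored,
  # as in the primary definition)
  ca <- rot(matrix(c(xa, ya), 1, 2), -tm)
  cb <- rot(matrix(c(xb, yb), 1, 2), -tm)
  sq <- function(cen) {
    h <- side / 2
    rbind(cen + c(-h, -h), cen + c(h, -h), cen + c(h, h), cen + c(-h, h))
  }
  pa <- sq(as.numeric(ca)); pb <- sq(as.numeric(cb))
  edges <- function(p) lapply(1:4, function(i) rbind(p[i, ], p[(i %% 4) + 1, ]))
  ea <- edges(pa); eb <- edges(pb)
  best <- NULL
  for (e1 in ea) for (e2 in eb) {
    d1 <- e1[2, ] - e1[1, ]; d2 <- e2[2, ] - e2[1, ]
    # facing edges are anti-parallel
    crossp <- d1[1] * d2[2] - d1[2] * d2[1]
    dotp <- sum(d1 * d2)
    if (abs(crossp) > 1e-9 || dotp >= 0) next
    # signed support-line distance along the outward normal of square a's
    # edge (corners are counter-clockwise, so outward is (dy, -dx))
    out <- c(d1[2], -d1[1]); out <- out / sqrt(sum(out^2))
    gap <- sum((e2[1, ] - e1[1, ]) * out)
    # the far-side anti-parallel pairing sits at gap <= -side; skip it
    if (gap <= -side + 1e-9) next
    # projected intervals on the edge direction
    tdir <- d1 / sqrt(sum(d1^2))
    i1 <- sort(c(sum(e1[1, ] * tdir), sum(e1[2, ] * tdir)))
    i2 <- sort(c(sum(e2[1, ] * tdir), sum(e2[2, ] * tdir)))
    ov <- min(i1[2], i2[2]) - max(i1[1], i2[1])
    if (ov > 0 && (is.null(best) || gap < best$gap))
      best <- list(gap = gap, overlap = min(ov, side))
  }
  if (is.null(best)) {
    # corner-to-corner: fall back to the dominant-axis gap with zero overlap
    dx <- abs(cb[1] - ca[1]); dy <- abs(cb[2] - ca[2])
    best <- list(gap = max(dx, dy) - side, overlap = 0)
  }
  structure(list(centre_distance = cd, delta_theta = dtheta, parallel = TRUE,
                 gap = best$gap, overlap = best$overlap),
            class = "pair_relation")
}

#' Centre-to-centre nearest-neighbour distances
#'
#' For every tetramer in an array, the minimum Euclidean centre-to-centre
#' distance to any other tetramer in the same array (the NND of the
#' tomographic analysis; histogram modes near 28 nm and 34 nm correspond to
#' side-by-side and checkerboard packing of 27-nm squares).
#'
#' @param array a \code{\link{tetramer_array}} with at least 2 tetramers.
#' @return data.frame with columns \code{id}, \code{nnd} (nm), one row per
#'   tetramer, in array order.
#' @export
nearest_neighbour_distances <- function(array) {
  n <- nrow(array)
  if (n < 2L)
    stop("nearest-neighbour distances need at least 2 tetramers")
  if (n <= 3000L) {
    d <- as.matrix(stats::dist(cbind(array$x, array$y)))
    diag(d) <- Inf
    nnd <- apply(d, 1L, min)
  } else {
    nnd <- vapply(seq_len(n), function(i) {
      dd <- (array$x - array$x[i])^2 + (array$y - array$y[i])^2
      dd[i] <- Inf
      sqrt(min(dd))
    }, numeric(1))
  }
  data.frame(id = array$id, nnd = unname(nnd))
}
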