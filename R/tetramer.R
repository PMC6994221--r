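#' Construct a tetramer array
#'
#' A tetramer array holds the mapped positions and in-plane orientations of
#' every RyR2 tetramer fitted in one tomogram (one dyad). Each tetramer is
#' modelled as a square of edge length \code{side} (27 nm for RyR2) centred at
#' \code{(x, y)} with orientation \code{theta}. Because a square has 4-fold
#' rotational symmetry, orientations are reduced modulo 90 degrees to
#' \code{[0, 90)}.
#'
#' @param tetramers data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{theta} (degrees). Coordinates in nm.
#' @param side edge length of the square footprint in nm (default 27; the
#'   footprint area \code{side^2} is then 729 nm^2).
#' @param tomogram identifier of the tomogram the array came from.
#' @param group treatment label.
#' @param overlap_tol maximum tolerated footprint-overlap area between any
#'   two tetramers, in nm^2. Fitted squares may abut but must not overlap by
#'   more than this.
#' @param check validate invariants (non-empty, finite coordinates, unique
#'   ids, pairwise footprint overlap below \code{overlap_tol}).
#' @return object of class \code{"tetramer_array"}: a data.frame with columns
#'   \code{id, x, y, theta} and attributes \code{side}, \code{tomogram},
#'   \code{group}.
#' @export
tetramer_array <- function(tetramers, side = 27, tomogram = "tomo1",
                           group = "Control", overlap_tol = 1,
                           check = TRUE) {
  stopifnot(is.data.frame(tetramers),
            all(c("x", "y") %in% names(tetramers)))
  df <- as.data.frame(tetramers)
  if (check && nrow(df) == 0L)
    stop("tetramer_array must contain at least one tetramer")
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  if (is.null(df$theta)) df$theta <- rep(0, nrow(df))
  df <- df[, c("id", "x", "y", "theta")]
  df$theta <- df$theta %% 90
  if (check) {
    if (nrow(df) == 0L)
      stop("tetramer_array must contain at least one tetramer")
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)) ||
        !all(is.finite(df$theta)))
      stop("non-finite tetramer coordinates or angles")
    if (side <= 0) stop("side must be positive")
    if (anyDuplicated(df$id)) stop("duplicate tetramer ids")
  }
  structure(df,
            side = side, tomogram = tomogram, group = group,
            class = c("tetramer_array", "data.frame")) -> arr
  if (check) {
    bad <- footprint_overlaps(arr, tol = overlap_tol)
    if (nrow(bad) > 0L)
      stop(sprintf(
        "tetramer footprints overlap by more than %g nm^2 (e.g. ids %s and %s: %.2f nm^2)",
        overlap_tol, bad$id_a[1], bad$id_b[1], bad$area[1]))
  }
  arr
}

#' @export
print.tetramer_array <- function(x, ...) {
  cat(sprintf("Tetramer array: %d tetramers (side %g nm), tomogram %s, group %s\n",
              nrow(x), attr(x, "side"), attr(x, "tomogram"), attr(x, "group")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Corners of square i in an array (or of an x/y/theta/side quadruple),
# counter-clockwise, as a 4x2 matrix.
square_corners <- function(x, y, theta, side) {
  h <- side / 2
  a <- theta * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  base <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  sweep(base %*% t(R), 2, c(x, y), "+")
}

#' Corner coordinates of every tetramer in an array
#'
#' @param array a \code{tetramer_array}.
#' @return matrix with \code{4 * n} rows and columns \code{x, y}.
#' @export
array_corners <- function(array) {
  side <- attr(array, "side")
  out <- do.call(rbind, lapply(seq_len(nrow(array)), function(i)
    square_corners(array$x[i], array$y[i], array$theta[i], side)))
  colnames(out) <- c("x", "y")
  out
}

# Pairs of tetramers whose square footprints intersect with area > tol.
# Only pairs closer than side*sqrt(2) can overlap, so prefilter on distance.
footprint_overlaps <- function(array, tol = 1) {
  n <- nrow(array)
  out <- data.frame(id_a = character(0), id_b = character(0),
                    area = numeric(0))
  if (n < 2L) return(out)
  side <- attr(array, "side")
  cd <- close_pairs(array$x, array$y, side * sqrt(2))
  if (nrow(cd) == 0L) return(out)
  for (r in seq_len(nrow(cd))) {
    i <- cd$i[r]; j <- cd$j[r]
    a <- convex_intersection_area(
      square_corners(array$x[i], array$y[i], array$theta[i], side),
      square_corners(array$x[j], array$y[j], array$theta[j], side))
    if (a > tol)
      out <- rbind(out, data.frame(id_a = as.character(array$id[i]),
                                   id_b = as.character(array$id[j]),
                                   area = a))
  }
  out
}

# All index pairs (i < j) with centre distance < r, without forming the full
# distance matrix for large n (simple grid-bucket sweep).
close_pairs <- function(x, y, r) {
  n <- length(x)
  if (n <= 1500L) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    idx <- which(upper.tri(d) & d < r, arr.ind = TRUE)
    return(data.frame(i = idx[, 1], j = idx[, 2]))
  }
  cx <- floor(x / r); cy <- floor(y / r)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  res_i <- integer(0); res_j <- integer(0)
  coords <- unique(data.frame(cx = cx, cy = cy))
  bucket_of <- function(a, b) buckets[[paste(a, b)]]
  for (b in seq_len(nrow(coords))) {
    a0 <- coords$cx[b]; b0 <- coords$cy[b]
    here <- bucket_of(a0, b0)
    neigh <- here
    for (da in -1:1) for (db in -1:1) {
      if (da == 0 && db == 0) next
      nb <- bucket_of(a0 + da, b0 + db)
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (i in here) {
      cand <- neigh[neigh > i]
      if (!length(cand)) next
      dd <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
      keep <- cand[dd < r^2]
      res_i <- c(res_i, rep.int(i, length(keep)))
      res_j <- c(res_j, keep)
    }
  }
  data.frame(i = res_i, j = res_j)
}

# Area of intersection of two convex polygons (counter-clockwise vertex
# matrices) via Sutherland-Hodgman clipping + shoelace.
convex_intersection_area <- function(p, q) {
  subj <- p
  nq <- nrow(q)
  for (k in seq_len(nq)) {
    if (nrow(subj) == 0L) return(0)
    a <- q[k, ]; b <- q[(k %% nq) + 1L, ]
    # keep points on the left of edge a->b
    cross <- (b[1] - a[1]) * (subj[, 2] - a[2]) -
             (b[2] - a[2]) * (subj[, 1] - a[1])
    inside <- cross >= -1e-12
    out <- matrix(numeric(0), 0, 2)
    ns <- nrow(subj)
    for (i in seq_len(ns)) {
      j <- (i %% ns) + 1L
      if (inside[i]) {
        out <- rbind(out, subj[i, ])
        if (!inside[j]) out <- rbind(out, seg_line_cross(subj[i, ], subj[j, ], a, b))
      } else if (inside[j]) {
        out <- rbind(out, seg_line_cross(subj[i, ], subj[j, ], a, b))
      }
    }
    subj <- out
  }
  if (nrow(subj) < 3L) return(0)
  shoelace_area(subj)
}

seg_line_cross <- function(p1, p2, a, b) {
  d1 <- (b[1] - a[1]) * (p1[2] - a[2]) - (b[2] - a[2]) * (p1[1] - a[1])
  d2 <- (b[1] - a[1]) * (p2[2] - a[2]) - (b[2] - a[2]) * (p2[1] - a[1])
  t <- d1 / (d1 - d2)
  p1 + t * (p2 - p1)
}

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}
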