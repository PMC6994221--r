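#' Arrangement classification parameters
#'
#' Thresholds of the checkerboard / side-by-side classifier. Two tetramers
#' are adjacent when their sides are parallel (within \code{angle_tol}),
#' the facing edges are separated by a gap below \code{gap_max} and their
#' projected overlap is positive. Adjacent pairs with overlap below
#' \code{overlap_cb_max} are checkerboard; pairs at or above it are
#' side-by-side.
#'
#' Boundary conventions: the gap test is strict (\code{gap < gap_max}), the
#' checkerboard test is strict (\code{overlap < overlap_cb_max}), so an
#' overlap exactly at the boundary (18 nm = 2/3 of a 27-nm side) classifies
#' as side-by-side; a corner-to-corner contact (zero projected overlap) does
#' not create adjacency.
#'
#' @param gap_max maximum facing-edge gap in nm (default 3).
#' @param overlap_cb_max checkerboard/side-by-side overlap boundary in nm
#'   (default 18, i.e. 2/3 of the 27-nm side).
#' @param angle_tol parallelism tolerance in degrees (default 10).
#' @param overlap_min exclusive lower bound on overlap for adjacency
#'   (default 0).
#' @return list of class \code{"arrangement_params"}.
#' @export
arrangement_params <- function(gap_max = 3, overlap_cb_max = 18,
                               angle_tol = 10, overlap_min = 0) {
  stopifnot(gap_max > 0, overlap_cb_max > 0, angle_tol >= 0,
            angle_tol <= 45, overlap_min >= 0)
  structure(list(gap_max = gap_max, overlap_cb_max = overlap_cb_max,
                 angle_tol = angle_tol, overlap_min = overlap_min),
            class = "arrangement_params")
}

#' Classify one tetramer pair
#'
#' @param rel a \code{\link{pair_relation}} (computed with the same
#'   \code{angle_tol} as in \code{params}).
#' @param params an \code{\link{arrangement_params}}.
#' @return one of \code{"checkerboard"}, \code{"side_by_side"},
#'   \code{"none"}.
#' @export
classify_pair <- function(rel, params = arrangement_params()) {
  if (!isTRUE(rel$parallel)) return("none")
  if (!(rel$gap < params$gap_max)) return("none")
  if (!(rel$overlap > params$overlap_min)) return("none")
  if (rel$overlap < params$overlap_cb_max) "checkerboard" else "side_by_side"
}

#' Classify every tetramer in an array
#'
#' Each tetramer is labelled by the configurations of its adjacent
#' neighbours: \code{checkerboard} if all adjacency relations are
#' checkerboard, \code{side_by_side} if all are side-by-side, \code{both}
#' if mixed, and \code{isolated} if it has no adjacent neighbour.
#'
#' @param array a \code{\link{tetramer_array}}.
#' @param params an \code{\link{arrangement_params}}.
#' @return data.frame with columns \code{id}, \code{label} (factor with the
#'   four levels), \code{n_cb_neighbours}, \code{n_ss_neighbours}.
#' @export
classify_tetramers <- function(array, params = arrangement_params()) {
  n <- nrow(array)
  side <- attr(array, "side")
  n_cb <- integer(n); n_ss <- integer(n)
  if (n >= 2L) {
    # only pairs closer than sqrt((side+gap_max)^2 + side^2) can qualify
    rmax <- sqrt((side + params$gap_max)^2 + side^2) + 1e-6
    cp <- close_pairs(array$x, array$y, rmax)
    for (r in seq_len(nrow(cp))) {
      i <- cp$i[r]; j <- cp$j[r]
      rel <- pair_relation_core(array$x[i], array$y[i], array$theta[i],
                                array$x[j], array$y[j], array$theta[j],
                                side, params$angle_tol)
      lab <- classify_pair(rel, params)
      if (lab == "checkerboard") {
        n_cb[i] <- n_cb[i] + 1L; n_cb[j] <- n_cb[j] + 1L
      } else if (lab == "side_by_side") {
        n_ss[i] <- n_ss[i] + 1L; n_ss[j] <- n_ss[j] + 1L
      }
    }
  }
  label <- ifelse(n_cb > 0L & n_ss > 0L, "both",
           ifelse(n_cb > 0L, "checkerboard",
           ifelse(n_ss > 0L, "side_by_side", "isolated")))
  data.frame(id = array$id,
             label = factor(label, levels = arrangement_levels()),
             n_cb_neighbours = n_cb, n_ss_neighbours = n_ss)
}

#' Classify a single tetramer within its array
#'
#' @param id id of the tetramer to classify.
#' @inheritParams classify_tetramers
#' @return a single label string.
#' @export
classify_tetramer <- function(id, array, params = arrangement_params()) {
  labs <- classify_tetramers(array, params)
  row <- match(id, labs$id)
  if (is.na(row)) stop("tetramer id not found in array")
  as.character(labs$label[row])
}

arrangement_levels <- function()
  c("checkerboard", "side_by_side", "both", "isolated")

#' Per-group arrangement summary
#'
#' Pools tetramers across arrays within each treatment group and tabulates
#' the fraction of tetramers that are checkerboard-only, side-by-side-only,
#' mixed ("both") and isolated, mirroring the tomographic arrangement
#' tables.
#'
#' @param arrays list of \code{\link{tetramer_array}} objects.
#' @param params an \code{\link{arrangement_params}}.
#' @return data.frame of class \code{"arrangement_summary"}: one row per
#'   group with counts, fractions, \code{n_tetramers}, \code{n_arrays}.
#' @export
summarize_arrangements <- function(arrays, params = arrangement_params()) {
  if (inherits(arrays, "tetramer_array")) arrays <- list(arrays)
  if (length(arrays) == 0L) stop("no arrays supplied")
  per <- lapply(arrays, function(a) {
    cl <- classify_tetramers(a, params)
    data.frame(group = attr(a, "group"), label = cl$label)
  })
  pooled <- do.call(rbind, per)
  groups <- unique(pooled$group)
  rows <- lapply(groups, function(g) {
    labs <- pooled$label[pooled$group == g]
    counts <- table(labs)
    n <- length(labs)
    na <- sum(vapply(arrays, function(a) attr(a, "group") == g, logical(1)))
    out <- data.frame(group = g, n_tetramers = n, n_arrays = na)
    for (lv in arrangement_levels()) {
      out[[paste0("n_", lv)]] <- as.integer(counts[[lv]])
      out[[paste0("frac_", lv)]] <- counts[[lv]] / n
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("arrangement_summary", "data.frame")
  res
}

#' @export
print.arrangement_summary <- function(x, digits = 3, ...) {
  cat("Tetramer arrangement summary (fractions per group):\n")
  show <- data.frame(group = x$group,
                     checkerboard = round(x$frac_checkerboard, digits),
                     side_by_side = round(x$frac_side_by_side, digits),
                     both = round(x$frac_both, digits),
                     isolated = round(x$frac_isolated, digits),
                     tetramers = x$n_tetramers, arrays = x$n_arrays)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
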