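#' Blink quality-control thresholds
#'
#' @param max_sigma_xy maximum XY localization error in nm (default 10).
#' @param max_sigma_z maximum Z localization error in nm (default 40).
#' @param min_gof minimum goodness of fit (default 0.9).
#' @param max_nn maximum distance to the nearest surviving neighbour in nm
#'   (default 30); blinks farther than this from every other surviving
#'   blink are discarded.
#' @param z_min,z_max z slice in nm retaining the surface layer (default a
#'   150-nm slab from 0 to 150). Use \code{-Inf}/\code{Inf} to disable.
#' @return list of class \code{"qc_thresholds"}.
#' @export
qc_thresholds <- function(max_sigma_xy = 10, max_sigma_z = 40,
                          min_gof = 0.9, max_nn = 30,
                          z_min = 0, z_max = 150) {
  stopifnot(max_sigma_xy > 0, max_sigma_z > 0, min_gof >= 0, min_gof <= 1,
            max_nn > 0, z_min < z_max)
  structure(list(max_sigma_xy = max_sigma_xy, max_sigma_z = max_sigma_z,
                 min_gof = min_gof, max_nn = max_nn,
                 z_min = z_min, z_max = z_max),
            class = "qc_thresholds")
}

#' Cluster-analysis parameters
#'
#' @param linkage maximum pixel-centre separation joining two lit pixels
#'   into one cluster, in nm (default 50).
#' @param min_area smallest retained cluster area in nm^2 (default 1600;
#'   clusters with area strictly below this are treated as noise).
#' @param tetramer_area footprint area of one tetramer in nm^2 (default
#'   729 = 27^2).
#' @param coverage fraction of a cluster's alpha-shape area occupied by
#'   tetramer footprints, measured per treatment group from tomograms;
#'   must be set before estimating tetramer counts.
#' @param pixel_size rasterization pixel edge in nm (default 10).
#' @return list of class \code{"cluster_params"}.
#' @export
cluster_params <- function(linkage = 50, min_area = 1600,
                           tetramer_area = 729, coverage = NA_real_,
                           pixel_size = 10) {
  stopifnot(linkage > 0, min_area >= 0, tetramer_area > 0, pixel_size > 0)
  if (!is.na(coverage)) stopifnot(coverage > 0, coverage <= 1)
  structure(list(linkage = linkage, min_area = min_area,
                 tetramer_area = tetramer_area, coverage = coverage,
                 pixel_size = pixel_size),
            class = "cluster_params")
}

#' Quality-filter dSTORM localizations
#'
#' Two fixed stages: (1) keep blinks inside the z slice with XY error at
#' most \code{max_sigma_xy}, Z error at most \code{max_sigma_z} and
#' goodness of fit at least \code{min_gof}; (2) among the survivors,
#' discard any blink whose nearest surviving neighbour (3D distance) is
#' farther than \code{max_nn}. The neighbour test runs once, after the
#' quality stage, so that neighbour support only comes from believable
#' localizations.
#'
#' @param locs data.frame of localizations with columns \code{x, y, z}
#'   (nm), \code{sigma_xy}, \code{sigma_z} (nm), \code{gof}.
#' @param thr a \code{\link{qc_thresholds}}.
#' @return the filtered data.frame (possibly empty).
#' @export
qc_filter <- function(locs, thr = qc_thresholds()) {
  locs <- as.data.frame(locs)
  if (nrow(locs) == 0L) return(locs)
  keep <- locs$sigma_xy <= thr$max_sigma_xy &
          locs$sigma_z <= thr$max_sigma_z &
          locs$gof >= thr$min_gof &
          locs$z >= thr$z_min & locs$z <= thr$z_max
  out <- locs[keep, , drop = FALSE]
  n <- nrow(out)
  if (n == 0L) return(out)
  nn <- if (n == 1L) Inf else nn_dist3(out$x, out$y, out$z)
  out[nn <= thr$max_nn, , drop = FALSE]
}

# nearest-neighbour 3D distance for each point, grid-bucketed for large n
nn_dist3 <- function(x, y, z, cell = 60) {
  n <- length(x)
  if (n <= 2000L) {
    d <- as.matrix(stats::dist(cbind(x, y, z)))
    diag(d) <- Inf
    return(apply(d, 1, min))
  }
  cx <- floor(x / cell); cy <- floor(y / cell); cz <- floor(z / cell)
  key <- paste(cx, cy, cz)
  buckets <- split(seq_len(n), key)
  nn <- rep(Inf, n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (da in -1:1) for (db in -1:1) for (dc in -1:1) {
      b <- buckets[[paste(cx[i] + da, cy[i] + db, cz[i] + dc)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (length(cand))
      nn[i] <- sqrt(min((x[cand] - x[i])^2 + (y[cand] - y[i])^2 +
                        (z[cand] - z[i])^2))
  }
  # points with no neighbour within the 3x3x3 cell block are farther than
  # `cell` away from everything, which exceeds any max_nn <= cell
  nn
}

#' Rasterize localizations onto a pixel grid
#'
#' Maps the (already quality-filtered) blinks onto a square grid of
#' \code{pixel_size}-nm pixels anchored at the minimum x and y of the
#' input, pixels half-open on the right. A pixel is lit when at least one
#' blink falls in it; afterwards, any pixel holding exactly one blink with
#' no lit pixel among its 8 neighbours is switched off (the lone-blink
#' denoising rule).
#'
#' @param locs data.frame with columns \code{x, y} (nm), QC-filtered.
#' @param pixel_size pixel edge in nm (default 10).
#' @return object of class \code{"pixel_grid"}: list with \code{origin},
#'   \code{pixel_size} and a data.frame \code{pixels} of lit-pixel integer
#'   indices \code{i, j} (0-based) with \code{count} blinks each.
#' @export
rasterize_localizations <- function(locs, pixel_size = 10) {
  locs <- as.data.frame(locs)
  if (nrow(locs) == 0L)
    return(structure(list(origin = c(0, 0), pixel_size = pixel_size,
                          pixels = data.frame(i = integer(0), j = integer(0),
                                              count = integer(0))),
                     class = "pixel_grid"))
  x0 <- min(locs$x); y0 <- min(locs$y)
  i <- floor((locs$x - x0) / pixel_size)
  j <- floor((locs$y - y0) / pixel_size)
  key <- paste(i, j)
  tab <- table(key)
  first <- !duplicated(key)
  px <- data.frame(i = as.integer(i[first]), j = as.integer(j[first]))
  px$count <- as.integer(tab[key[first]])
  # lone single-blink pixels with no lit 8-neighbour are noise
  lit <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(px))) assign(paste(px$i[r], px$j[r]), TRUE, lit)
  has_neighbour <- vapply(seq_len(nrow(px)), function(r) {
    for (da in -1:1) for (db in -1:1) {
      if (da == 0L && db == 0L) next
      if (exists(paste(px$i[r] + da, px$j[r] + db), lit, inherits = FALSE))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  px <- px[px$count > 1L | has_neighbour, , drop = FALSE]
  rownames(px) <- NULL
  structure(list(origin = c(x0, y0), pixel_size = pixel_size, pixels = px),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("Pixel grid: %d lit %g-nm pixels, origin (%.1f, %.1f) nm\n",
              nrow(x$pixels), x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Single-linkage clustering of lit pixels
#'
#' Connected components of the lit pixels where two pixels are joined when
#' their centres are at most \code{linkage} nm apart (50 nm by default, the
#' scale beyond which tetramer nearest-neighbour distances rarely reach).
#'
#' @param grid a \code{\link{rasterize_localizations}} result.
#' @param params a \code{\link{cluster_params}}.
#' @return data.frame of the grid's lit pixels with an added integer
#'   \code{cluster} column (1-based component ids, largest first).
#' @export
link_clusters <- function(grid, params = cluster_params()) {
  px <- grid$pixels
  n <- nrow(px)
  if (n == 0L) { px$cluster <- integer(0); return(px) }
  ps <- grid$pixel_size
  rmax_pix <- floor(params$linkage / ps)
  # neighbour offsets with centre distance <= linkage
  offs <- expand.grid(da = -rmax_pix:rmax_pix, db = -rmax_pix:rmax_pix)
  offs <- offs[(offs$da^2 + offs$db^2) * ps^2 <= params$linkage^2 + 1e-9, ]
  offs <- offs[offs$da > 0 | (offs$da == 0 & offs$db > 0), ]
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(n)) assign(paste(px$i[r], px$j[r]), r, idx)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (r in seq_len(n)) {
    for (o in seq_len(nrow(offs))) {
      key <- paste(px$i[r] + offs$da[o], px$j[r] + offs$db[o])
      s <- get0(key, idx, inherits = FALSE)
      if (!is.null(s)) {
        ra <- find(r); rb <- find(s)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sizes <- table(root)
  ord <- names(sort(sizes, decreasing = TRUE))
  px$cluster <- match(as.character(root), ord)
  px
}

#' Alpha-shape areas of clusters, with the small-cluster filter
#'
#' Computes each cluster's alpha-shape boundary and area from its lit-pixel
#' centres and drops clusters whose area is below \code{min_area} (1600 nm^2
#' by default, which also removes isolated single tetramers) or that are
#' degenerate (fewer than 3 non-collinear pixel centres).
#'
#' @param pixels output of \code{\link{link_clusters}} (lit pixels with a
#'   \code{cluster} column); pixel centres are computed from \code{grid}.
#' @param grid the \code{\link{rasterize_localizations}} result the pixels
#'   came from.
#' @param shape a \code{\link{shape_params}}.
#' @param params a \code{\link{cluster_params}}.
#' @return data.frame of class \code{"cluster_table"}: one row per retained
#'   cluster with \code{cluster_id}, \code{area_nm2}, \code{n_pixels},
#'   \code{n_blinks}; the alpha shapes are attached as attribute
#'   \code{"shapes"} (a list keyed by cluster id).
#' @export
cluster_areas <- function(pixels, grid, shape = shape_params(),
                          params = cluster_params()) {
  ps <- grid$pixel_size
  ids <- sort(unique(pixels$cluster))
  rows <- list(); shapes <- list()
  for (cid in ids) {
    sub <- pixels[pixels$cluster == cid, , drop = FALSE]
    cx <- grid$origin[1] + (sub$i + 0.5) * ps
    cy <- grid$origin[2] + (sub$j + 0.5) * ps
    pts <- cbind(cx, cy)
    if (nrow(pts) < 3L || all_collinear(pts)) next
    shp <- alpha_shape_area(pts, shape)
    if (shp$area < params$min_area) next
    rows[[length(rows) + 1L]] <-
      data.frame(cluster_id = cid, area_nm2 = shp$area,
                 n_pixels = nrow(sub), n_blinks = sum(sub$count))
    shapes[[as.character(cid)]] <- shp
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), area_nm2 = numeric(0),
               n_pixels = integer(0), n_blinks = integer(0))
  rownames(out) <- NULL
  attr(out, "shapes") <- shapes
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Estimate tetramers per cluster
#'
#' Multiplies the cluster area by the group's tomogram-derived coverage
#' fraction (the share of an array's alpha shape occupied by tetramer
#' footprints) and divides by the single-tetramer footprint (729 nm^2),
#' rounding half away from zero to an integer count.
#'
#' @param area cluster area(s) in nm^2 (vectorised).
#' @param params a \code{\link{cluster_params}} with \code{coverage} set.
#' @return integer tetramer count(s).
#' @examples
#' estimate_tetramers(12200, cluster_params(coverage = 0.495))  # 8
#' @export
estimate_tetramers <- function(area, params) {
  if (is.na(params$coverage))
    stop("cluster_params$coverage must be set (group value from tomograms)")
  stopifnot(all(area > 0))
  x <- area * params$coverage / params$tetramer_area
  as.integer(floor(x + 0.5))  # round half away from zero (counts are >= 0)
}

#' Run the full dSTORM cluster pipeline
#'
#' Convenience wrapper: QC filter, rasterization, linkage clustering,
#' alpha-shape areas with the small-cluster filter, and (when coverage is
#' set) tetramer-count estimation.
#'
#' @param locs localization data.frame (see \code{\link{qc_filter}}).
#' @param thr \code{\link{qc_thresholds}}.
#' @param shape \code{\link{shape_params}}.
#' @param params \code{\link{cluster_params}}.
#' @return a \code{cluster_table} (with \code{n_tetramers} column when
#'   coverage is available), carrying the grid as attribute \code{"grid"}.
#' @export
dstorm_pipeline <- function(locs, thr = qc_thresholds(),
                            shape = shape_params(),
                            params = cluster_params()) {
  filtered <- qc_filter(locs, thr)
  grid <- rasterize_localizations(filtered, params$pixel_size)
  px <- link_clusters(grid, params)
  tab <- cluster_areas(px, grid, shape, params)
  if (!is.na(params$coverage) && nrow(tab) > 0L)
    tab$n_tetramers <- estimate_tetramers(tab$area_nm2, params)
  attr(tab, "grid") <- grid
  tab
}
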