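#' Synthetic tetramer-array generator configuration
#'
#' The generator emulates the packing motifs seen in dyadic tetramer maps:
#' side-by-side runs (centre-to-centre ~28 nm, near-full edge overlap),
#' checkerboard runs (~34 nm, partial overlap of ~7 nm), tetramers with one
#' neighbour of each kind ("both"), and isolated tetramers far from
#' everything.
#'
#' The checkerboard motif places a neighbour at lateral offset
#' \code{side - cb_overlap} along the shared edge and axial offset
#' \code{sqrt(cb_centre_distance^2 - lateral^2)}, which for the defaults
#' (34-nm spacing, 7-nm overlap, 27-nm side) gives a facing-edge gap of
#' about 0.5 nm — inside the 3-nm adjacency rule.
#'
#' @param n_tetramers total number of tetramers to place.
#' @param target_fractions named or positional fractions over
#'   (checkerboard, side_by_side, both, isolated); must sum to 1.
#' @param side square edge in nm (27).
#' @param cb_centre_distance checkerboard centre spacing in nm (34).
#' @param ss_centre_distance side-by-side centre spacing in nm (28).
#' @param cb_overlap projected facing-edge overlap of the checkerboard
#'   motif in nm (7).
#' @param positional_jitter_sd per-tetramer positional jitter sd in nm.
#' @param angular_jitter_sd per-tetramer orientation jitter sd in degrees.
#' @param seed RNG seed.
#' @return list of class \code{"array_gen_config"}.
#' @export
array_gen_config <- function(n_tetramers = 100,
                             target_fractions = c(checkerboard = 0.5,
                                                  side_by_side = 0.3,
                                                  both = 0.05,
                                                  isolated = 0.15),
                             side = 27, cb_centre_distance = 34,
                             ss_centre_distance = 28, cb_overlap = 7,
                             positional_jitter_sd = 1,
                             angular_jitter_sd = 2, seed = 1L) {
  f <- as.numeric(target_fractions)
  stopifnot(length(f) == 4L, abs(sum(f) - 1) < 1e-9, all(f >= 0),
            n_tetramers >= 1, side > 0,
            cb_centre_distance >= side - 1, ss_centre_distance >= side - 1,
            cb_overlap > 0, cb_overlap < side,
            positional_jitter_sd >= 0, angular_jitter_sd >= 0)
  structure(list(n_tetramers = n_tetramers,
                 target_fractions = stats::setNames(f, arrangement_levels()),
                 side = side, cb_centre_distance = cb_centre_distance,
                 ss_centre_distance = ss_centre_distance,
                 cb_overlap = cb_overlap,
                 positional_jitter_sd = positional_jitter_sd,
                 angular_jitter_sd = angular_jitter_sd,
                 seed = as.integer(seed)),
            class = "array_gen_config")
}

#' Generate a synthetic tetramer array with known arrangement labels
#'
#' Places motifs (checkerboard runs, side-by-side runs, mixed triples,
#' isolated singletons) on a coarse grid with >= 100 nm between motifs so
#' no unintended adjacency arises, rotates each motif by a random angle,
#' applies per-tetramer positional and angular jitter (redrawing jitter
#' whenever it would break the intended adjacency class or overlap
#' footprints), and returns the array together with the intended labels.
#'
#' @param cfg an \code{\link{array_gen_config}}.
#' @param tomogram,group metadata for the returned array.
#' @return list with \code{array} (a \code{\link{tetramer_array}}) and
#'   \code{labels} (data.frame \code{id}, \code{label} of intended
#'   classes).
#' @export
gen_tetramer_array <- function(cfg = array_gen_config(),
                               tomogram = "synthetic", group = "Control") {
  set.seed(cfg$seed)
  n <- cfg$n_tetramers
  f <- cfg$target_fractions
  side <- cfg$side
  # motif bookkeeping: a "both" triple contributes 1 both + 1 cb + 1 ss
  n_both <- round(f[["both"]] * n)
  n_cb <- max(round(f[["checkerboard"]] * n) - n_both, 0)
  n_ss <- max(round(f[["side_by_side"]] * n) - n_both, 0)
  # a paired class needs at least 2 members; a stranded single becomes
  # isolated
  if (n_cb == 1L) n_cb <- 0L
  if (n_ss == 1L) n_ss <- 0L
  n_iso <- n - n_both * 3 - n_cb - n_ss
  if (n_iso < 0) stop("infeasible fractions for this n")
  # split cb and ss tetramers into runs of 2-5
  runs <- function(total) {
    out <- integer(0)
    while (total > 0) {
      r <- min(sample(2:5, 1), total)
      if (total - r == 1) r <- r + 1   # avoid leaving a singleton
      out <- c(out, r)
      total <- total - r
    }
    out
  }
  motifs <- c(lapply(runs(n_cb), function(r) list(kind = "cb", size = r)),
              lapply(runs(n_ss), function(r) list(kind = "ss", size = r)),
              replicate(n_both, list(kind = "both", size = 3L),
                        simplify = FALSE),
              replicate(n_iso, list(kind = "iso", size = 1L),
                        simplify = FALSE))
  if (length(motifs) == 0L) stop("nothing to place")
  motifs <- motifs[sample.int(length(motifs))]
  # coarse placement grid: the longest motif (run of 6) spans < 145 nm from
  # its local origin, and origins sit 150-350 nm into a 600-nm cell, so
  # tetramers of different motifs stay >= 100 nm apart at any rotation
  pitch <- 600
  ncell <- ceiling(sqrt(length(motifs)))
  cells <- expand.grid(gx = seq_len(ncell), gy = seq_len(ncell))
  cells <- cells[sample.int(nrow(cells), length(motifs)), , drop = FALSE]
  lat <- side - cfg$cb_overlap
  axial <- sqrt(cfg$cb_centre_distance^2 - lat^2)
  params <- arrangement_params()
  # fitted boxes carry ~3 nm placement error, so jittered neighbours may
  # interpenetrate slightly; allow up to ~2% of a footprint
  otol <- max(1, 15 * (cfg$positional_jitter_sd > 0))
  rows <- list(); labels <- character(0)
  idc <- 0L
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    # motif-local centres at theta = 0
    if (m$kind == "cb") {
      xs <- cumsum(c(0, rep(axial, m$size - 1L)))
      ys <- c(0, rep_len(c(lat, 0), m$size - 1L))
      labs <- rep("checkerboard", m$size)
    } else if (m$kind == "ss") {
      xs <- cumsum(c(0, rep(cfg$ss_centre_distance, m$size - 1L)))
      ys <- rep(0, m$size)
      labs <- rep("side_by_side", m$size)
    } else if (m$kind == "both") {
      xs <- c(-cfg$ss_centre_distance, 0, axial)
      ys <- c(0, 0, lat)
      labs <- c("side_by_side", "both", "checkerboard")
    } else {
      xs <- 0; ys <- 0
      labs <- "isolated"
    }
    phi <- stats::runif(1, 0, 360)
    a <- phi * pi / 180
    gx <- (cells$gx[mi] - 1) * pitch + stats::runif(1, 150, 350)
    gy <- (cells$gy[mi] - 1) * pitch + stats::runif(1, 150, 350)
    x <- gx + xs * cos(a) - ys * sin(a)
    y <- gy + xs * sin(a) + ys * cos(a)
    theta <- rep(phi %% 90, length(xs))
    mot <- data.frame(x = x, y = y, theta = theta)
    # per-motif jitter with redraws that preserve the intended classes and
    # keep footprint interpenetration below otol
    if (cfg$positional_jitter_sd > 0 || cfg$angular_jitter_sd > 0) {
      for (attempt in 1:300) {
        cand <- mot
        nm <- nrow(mot)
        cand$x <- mot$x + stats::rnorm(nm, 0, cfg$positional_jitter_sd)
        cand$y <- mot$y + stats::rnorm(nm, 0, cfg$positional_jitter_sd)
        cand$theta <- (mot$theta +
                       stats::rnorm(nm, 0, cfg$angular_jitter_sd)) %% 90
        arr_try <- tetramer_array(cbind(id = seq_len(nm), cand),
                                  side = side, check = FALSE)
        if (nm > 1L && nrow(footprint_overlaps(arr_try, tol = otol)) > 0L)
          next
        got <- classify_tetramers(arr_try, params)
        if (all(as.character(got$label) == labs)) { mot <- cand; break }
        if (attempt == 300L)
          stop("could not jitter a motif without breaking its labels")
      }
    }
    for (t in seq_len(nrow(mot))) {
      idc <- idc + 1L
      rows[[idc]] <- data.frame(id = idc, x = mot$x[t], y = mot$y[t],
                                theta = mot$theta[t])
    }
    labels <- c(labels, labs)
  }
  df <- do.call(rbind, rows)
  arr <- tetramer_array(df, side = side, tomogram = tomogram, group = group,
                        overlap_tol = otol)
  list(array = arr,
       labels = data.frame(id = df$id,
                           label = factor(labels,
                                          levels = arrangement_levels())))
}

#' Synthetic blink-cloud generator configuration
#'
#' @param blinks_per_tetramer_mean Poisson mean blink count per tetramer.
#' @param sigma_xy_mean,sigma_xy_sd lognormal-ish XY error distribution
#'   parameters (nm); draws are truncated into (0.5, Inf).
#' @param sigma_z_mean,sigma_z_sd Z error distribution (nm).
#' @param gof_shape1,gof_shape2 Beta parameters of the goodness of fit for
#'   passing blinks (mass above 0.9).
#' @param background_density coverslip background blinks per um^2.
#' @param fail_fraction share of blinks drawn beyond the QC thresholds
#'   (assigned a failing sigma_xy, sigma_z or gof at random).
#' @param z_surface,z_sd surface depth and roughness (nm).
#' @param seed RNG seed.
#' @return list of class \code{"blink_gen_config"}.
#' @export
blink_gen_config <- function(blinks_per_tetramer_mean = 250,
                             sigma_xy_mean = 5, sigma_xy_sd = 2,
                             sigma_z_mean = 20, sigma_z_sd = 8,
                             gof_shape1 = 20, gof_shape2 = 1,
                             background_density = 1,
                             fail_fraction = 0.1,
                             z_surface = 75, z_sd = 10, seed = 1L) {
  stopifnot(blinks_per_tetramer_mean >= 0, background_density >= 0,
            fail_fraction >= 0, fail_fraction <= 1)
  structure(list(blinks_per_tetramer_mean = blinks_per_tetramer_mean,
                 sigma_xy_mean = sigma_xy_mean, sigma_xy_sd = sigma_xy_sd,
                 sigma_z_mean = sigma_z_mean, sigma_z_sd = sigma_z_sd,
                 gof_shape1 = gof_shape1, gof_shape2 = gof_shape2,
                 background_density = background_density,
                 fail_fraction = fail_fraction,
                 z_surface = z_surface, z_sd = z_sd,
                 seed = as.integer(seed)),
            class = "blink_gen_config")
}

#' Generate synthetic dSTORM localizations for a tetramer layout
#'
#' Per tetramer, a Poisson number of blinks is scattered uniformly over the
#' 27-nm square footprint and displaced by a Gaussian of the blink's drawn
#' XY error; background blinks are spread uniformly over the bounding field
#' (plus a margin). A \code{fail_fraction} of all blinks is assigned a
#' failing QC property (large sigma_xy, large sigma_z, or low goodness of
#' fit). Ground-truth membership (tetramer id, or \code{NA} for background)
#' is returned with each blink.
#'
#' @param layout a \code{\link{tetramer_array}}.
#' @param cfg a \code{\link{blink_gen_config}}.
#' @param field optional c(xmin, xmax, ymin, ymax) nm for the background
#'   field; defaults to the layout bounding box plus 200 nm.
#' @return data.frame with the canonical localization columns \code{x, y,
#'   z, sigma_xy, sigma_z, gof, frame} plus \code{source} (tetramer id or
#'   \code{NA}).
#' @export
gen_localizations <- function(layout, cfg = blink_gen_config(),
                              field = NULL) {
  set.seed(cfg$seed)
  side <- attr(layout, "side")
  if (is.null(field))
    field <- c(min(layout$x) - 200, max(layout$x) + 200,
               min(layout$y) - 200, max(layout$y) + 200)
  draw_sigma <- function(n, mu, sd)
    pmax(stats::rnorm(n, mu, sd), 0.5)
  mk <- function(n, x, y, src) {
    if (n == 0L)
      return(NULL)
    data.frame(x = x, y = y,
               z = stats::rnorm(n, cfg$z_surface, cfg$z_sd),
               sigma_xy = draw_sigma(n, cfg$sigma_xy_mean, cfg$sigma_xy_sd),
               sigma_z = draw_sigma(n, cfg$sigma_z_mean, cfg$sigma_z_sd),
               gof = 0.9 + 0.1 * stats::rbeta(n, cfg$gof_shape1,
                                              cfg$gof_shape2),
               frame = seq_len(n), source = src)
  }
  parts <- list()
  for (t in seq_len(nrow(layout))) {
    nb <- stats::rpois(1, cfg$blinks_per_tetramer_mean)
    if (nb == 0L) next
    # uniform over the rotated square footprint + localization error
    u <- stats::runif(nb, -side / 2, side / 2)
    v <- stats::runif(nb, -side / 2, side / 2)
    a <- layout$theta[t] * pi / 180
    sig <- draw_sigma(nb, cfg$sigma_xy_mean, cfg$sigma_xy_sd)
    x <- layout$x[t] + u * cos(a) - v * sin(a) + stats::rnorm(nb, 0, sig)
    y <- layout$y[t] + u * sin(a) + v * cos(a) + stats::rnorm(nb, 0, sig)
    p <- mk(nb, x, y, layout$id[t])
    p$sigma_xy <- sig
    parts[[length(parts) + 1L]] <- p
  }
  area_um2 <- (field[2] - field[1]) * (field[4] - field[3]) / 1e6
  nbg <- stats::rpois(1, cfg$background_density * area_um2)
  if (nbg > 0L)
    parts[[length(parts) + 1L]] <-
      mk(nbg, stats::runif(nbg, field[1], field[2]),
         stats::runif(nbg, field[3], field[4]), NA)
  locs <- do.call(rbind, parts)
  if (is.null(locs))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      sigma_xy = numeric(0), sigma_z = numeric(0),
                      gof = numeric(0), frame = integer(0),
                      source = integer(0)))
  rownames(locs) <- NULL
  # assign failing QC properties to a fail_fraction of blinks
  nfail <- round(cfg$fail_fraction * nrow(locs))
  if (nfail > 0L) {
    idx <- sample.int(nrow(locs), nfail)
    mode <- sample(1:3, nfail, replace = TRUE)
    locs$sigma_xy[idx[mode == 1]] <- stats::runif(sum(mode == 1), 10.5, 25)
    locs$sigma_z[idx[mode == 2]] <- stats::runif(sum(mode == 2), 40.5, 90)
    locs$gof[idx[mode == 3]] <- stats::runif(sum(mode == 3), 0.5, 0.89)
  }
  locs$frame <- seq_len(nrow(locs))
  locs
}

#' Synthetic spark-table generator configuration
#'
#' Spark parameters are log-normal with additive rat- and cell-level random
#' effects on the log scale; spark frequency is Gaussian per cell with an
#' SR-content covariate. Defaults emulate field-typical permeabilized-rat
#' spark data: geometric means 0.45 dF/F0 (amplitude), 25 ms (FDHM),
#' 1.9 um (FWHM).
#'
#' @param groups character vector of treatment labels.
#' @param log_mean named per-parameter log-scale means, recycled across
#'   groups; pass a list keyed by group for group effects.
#' @param log_sd named per-parameter spark-level log sds.
#' @param rat_sd,cell_sd random-effect sds on the log scale.
#' @param n_rats,cells_per_rat,sparks_per_cell design counts.
#' @param freq_mean,freq_sd cell spark-rate distribution
#'   (sparks s^-1 (100 um)^-1).
#' @param sr_mean,sr_sd SR-content (caffeine-transient dF/F0) distribution.
#' @param seed RNG seed.
#' @return list of class \code{"spark_gen_config"}.
#' @export
spark_gen_config <- function(groups = "Control",
                             log_mean = c(amplitude = log(0.45),
                                          fdhm = log(25),
                                          fwhm = log(1.9)),
                             log_sd = c(amplitude = 0.35, fdhm = 0.30,
                                        fwhm = 0.25),
                             rat_sd = 0.08, cell_sd = 0.15,
                             n_rats = 4, cells_per_rat = 5,
                             sparks_per_cell = 30,
                             freq_mean = 5, freq_sd = 1.5,
                             sr_mean = 3, sr_sd = 0.5, seed = 1L) {
  stopifnot(rat_sd >= 0, cell_sd >= 0, n_rats >= 1, cells_per_rat >= 1,
            sparks_per_cell >= 1, all(log_sd >= 0))
  if (!is.list(log_mean))
    log_mean <- stats::setNames(rep(list(log_mean), length(groups)), groups)
  structure(list(groups = groups, log_mean = log_mean, log_sd = log_sd,
                 rat_sd = rat_sd, cell_sd = cell_sd, n_rats = n_rats,
                 cells_per_rat = cells_per_rat,
                 sparks_per_cell = sparks_per_cell,
                 freq_mean = freq_mean, freq_sd = freq_sd,
                 sr_mean = sr_mean, sr_sd = sr_sd,
                 seed = as.integer(seed)),
            class = "spark_gen_config")
}

#' Generate a synthetic nested spark table
#'
#' @param cfg a \code{\link{spark_gen_config}}.
#' @return list with \code{sparks} (data.frame \code{rat, cell, group,
#'   amplitude, fdhm_ms, fwhm_um}) and \code{frequency} (data.frame
#'   \code{rat, cell, group, rate, sr_content}); rats are distinct across
#'   groups (different animals per treatment).
#' @export
gen_spark_table <- function(cfg = spark_gen_config()) {
  set.seed(cfg$seed)
  pars <- names(cfg$log_sd)
  sparks <- list(); freq <- list()
  for (g in cfg$groups) {
    mu <- cfg$log_mean[[g]]
    for (r in seq_len(cfg$n_rats)) {
      rat_id <- paste0(g, "_rat", r)
      rat_eff <- stats::rnorm(length(pars), 0, cfg$rat_sd)
      rat_feff <- stats::rnorm(1, 0, cfg$rat_sd * cfg$freq_mean)
      for (cl in seq_len(cfg$cells_per_rat)) {
        cell_id <- paste0(rat_id, "_cell", cl)
        cell_eff <- stats::rnorm(length(pars), 0, cfg$cell_sd)
        n <- cfg$sparks_per_cell
        vals <- vapply(seq_along(pars), function(pi)
          exp(mu[[pars[pi]]] + rat_eff[pi] + cell_eff[pi] +
              stats::rnorm(n, 0, cfg$log_sd[[pars[pi]]])),
          numeric(n))
        df <- data.frame(rat = rep(rat_id, n), cell = rep(cell_id, n),
                         group = rep(g, n))
        df$amplitude <- vals[, 1]
        df$fdhm_ms <- vals[, 2]
        df$fwhm_um <- vals[, 3]
        sparks[[length(sparks) + 1L]] <- df
        rate <- max(stats::rnorm(1, cfg$freq_mean + rat_feff, cfg$freq_sd), 0)
        sr <- max(stats::rnorm(1, cfg$sr_mean, cfg$sr_sd), 0.2)
        freq[[length(freq) + 1L]] <-
          data.frame(rat = rat_id, cell = cell_id, group = g,
                     rate = rate, sr_content = sr)
      }
    }
  }
  list(sparks = do.call(rbind, sparks), frequency = do.call(rbind, freq))
}

#' Generate a contiguous checkerboard lattice array
#'
#' Tetramers on the lattice spanned by u = (axial, lateral) and
#' v = (axial, -lateral), where \code{lateral = side - cb_overlap} and
#' \code{axial} completes the requested centre distance. Every interior
#' tetramer then has four checkerboard neighbours; the next-nearest
#' offsets (2*axial, 0) and (0, 2*lateral) are outside the adjacency rule.
#' Useful as a planted, spatially contiguous cluster.
#'
#' @param ni,nj lattice extent along u and v.
#' @param cfg an \code{\link{array_gen_config}} (spacing/side/jitter/seed
#'   fields are used).
#' @param origin c(x, y) offset in nm.
#' @param tomogram,group metadata.
#' @return a \code{\link{tetramer_array}}.
#' @export
gen_checkerboard_lattice <- function(ni = 4, nj = 4,
                                     cfg = array_gen_config(),
                                     origin = c(0, 0),
                                     tomogram = "lattice",
                                     group = "Control") {
  set.seed(cfg$seed)
  lat <- cfg$side - cfg$cb_overlap
  axial <- sqrt(cfg$cb_centre_distance^2 - lat^2)
  gridij <- expand.grid(i = seq_len(ni) - 1L, j = seq_len(nj) - 1L)
  x <- origin[1] + (gridij$i + gridij$j) * axial
  y <- origin[2] + (gridij$i - gridij$j) * lat
  df <- data.frame(id = seq_len(nrow(gridij)), x = x, y = y, theta = 0)
  df$interior <- gridij$i > 0 & gridij$i < ni - 1L &
                 gridij$j > 0 & gridij$j < nj - 1L
  if (cfg$positional_jitter_sd > 0)
    for (attempt in 1:100) {
      cand <- df
      cand$x <- df$x + stats::rnorm(nrow(df), 0, cfg$positional_jitter_sd)
      cand$y <- df$y + stats::rnorm(nrow(df), 0, cfg$positional_jitter_sd)
      ok <- try(tetramer_array(cand, side = cfg$side, tomogram = tomogram,
                               group = group, overlap_tol = 15),
                silent = TRUE)
      if (!inherits(ok, "try-error")) { df <- cand; break }
    }
  arr <- tetramer_array(df[, c("id", "x", "y", "theta")], side = cfg$side,
                        tomogram = tomogram, group = group,
                        overlap_tol = 15)
  attr(arr, "interior") <- df$interior
  arr
}
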