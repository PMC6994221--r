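mk_loc <- function(x, y, z = 75, sigma_xy = 5, sigma_z = 20, gof = 0.95) {
  n <- max(lengths(list(x, y, z, sigma_xy, sigma_z, gof)))
  data.frame(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
             sigma_xy = rep_len(sigma_xy, n), sigma_z = rep_len(sigma_z, n),
             gof = rep_len(gof, n), frame = seq_len(n))
}

test_that("qc_filter applies quality rules then the neighbour rule, in that order", {
  thr <- qc_thresholds()
  # close high-quality pair survives
  good <- mk_loc(c(0, 20), c(0, 0))
  expect_equal(nrow(qc_filter(good, thr)), 2L)
  # three failures: bad sigma_xy, bad gof, and a good-but-lonely blink
  bad <- rbind(mk_loc(0, 0, sigma_xy = 12),
               mk_loc(5, 0, gof = 0.85),
               mk_loc(1000, 1000))
  expect_equal(nrow(qc_filter(bad, thr)), 0L)
  # staged semantics: a good blink whose only close neighbour fails the gof
  # rule becomes lonely and is removed too
  staged <- rbind(mk_loc(0, 0), mk_loc(10, 0, gof = 0.85),
                  mk_loc(500, 0), mk_loc(510, 0))
  kept <- qc_filter(staged, thr)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$x >= 500))
  # z slicing
  deep <- rbind(mk_loc(0, 0, z = 300), mk_loc(10, 0, z = 300))
  expect_equal(nrow(qc_filter(deep, thr)), 0L)
  # empty input is fine
  expect_equal(nrow(qc_filter(good[0, ], thr)), 0L)
})

test_that("qc_filter never adds rows and is the identity at infinite thresholds", {
  set.seed(31)
  locs <- mk_loc(runif(50, 0, 2000), runif(50, 0, 2000),
                 sigma_xy = runif(50, 1, 15), gof = runif(50, 0.8, 1))
  thr <- qc_thresholds()
  expect_lte(nrow(qc_filter(locs, thr)), nrow(locs))
  open <- qc_thresholds(max_sigma_xy = Inf, max_sigma_z = Inf, min_gof = 0,
                        max_nn = Inf, z_min = -Inf, z_max = Inf)
  expect_equal(qc_filter(locs, open), locs)
})

test_that("rasterization applies the lone single-blink rule on the 10-nm grid", {
  # one isolated blink: empty grid
  g <- rasterize_localizations(mk_loc(0, 0))
  expect_equal(nrow(g$pixels), 0L)
  # two blinks in the same isolated pixel: stays lit
  g <- rasterize_localizations(mk_loc(c(0, 2), c(0, 2)))
  expect_equal(nrow(g$pixels), 1L)
  expect_equal(g$pixels$count, 2L)
  # two single-blink pixels diagonally adjacent: both lit (8-neighbourhood)
  g <- rasterize_localizations(mk_loc(c(0, 12), c(0, 12)))
  expect_equal(nrow(g$pixels), 2L)
  # pixels are half-open: a blink at exactly 10 nm goes to the next pixel
  g <- rasterize_localizations(mk_loc(c(0, 10), c(0, 0)))
  expect_equal(sort(g$pixels$i), c(0L, 1L))
})

test_that("linkage clustering joins pixels within 50 nm and matches the brute-force oracle", {
  block <- function(ox, oy) expand.grid(i = ox + 0:2, j = oy + 0:2)
  # two 3x3 blocks, nearest centres 40 nm apart -> one cluster
  px <- rbind(block(0, 0), block(7, 0))   # gap of 4 pixels = 40 nm
  grid <- structure(list(origin = c(0, 0), pixel_size = 10,
                         pixels = data.frame(i = px$i, j = px$j, count = 2L)),
                    class = "pixel_grid")
  out <- link_clusters(grid, cluster_params())
  expect_equal(length(unique(out$cluster)), 1L)
  # 60 nm apart -> two clusters
  px <- rbind(block(0, 0), block(9, 0))
  grid$pixels <- data.frame(i = px$i, j = px$j, count = 2L)
  out <- link_clusters(grid, cluster_params())
  expect_equal(length(unique(out$cluster)), 2L)
  # random sparse grids vs the O(n^2) oracle
  set.seed(17)
  for (rep in 1:5) {
    pi <- sample(0:40, 60, replace = TRUE)
    pj <- sample(0:40, 60, replace = TRUE)
    keep <- !duplicated(paste(pi, pj))
    pi <- pi[keep]; pj <- pj[keep]
    grid$pixels <- data.frame(i = pi, j = pj, count = 2L)
    got <- link_clusters(grid, cluster_params())$cluster
    want <- oracle_components(pi, pj, 10, 50)
    # same partition (component ids may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster area filter drops small and degenerate clusters at the 1600-nm2 boundary", {
  grid_of <- function(px) structure(list(origin = c(0, 0), pixel_size = 10,
                                         pixels = px), class = "pixel_grid")
  # 5x5 block: centres span 40x40 nm, area exactly 1600 -> retained
  px <- expand.grid(i = 0:4, j = 0:4); px$count <- 2L; px$cluster <- 1L
  tab <- cluster_areas(px, grid_of(px), shape_params(), cluster_params())
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$area_nm2, 1600)
  # 4x4 block: 900 nm2 -> dropped
  px <- expand.grid(i = 0:3, j = 0:3); px$count <- 2L; px$cluster <- 1L
  tab <- cluster_areas(px, grid_of(px), shape_params(), cluster_params())
  expect_equal(nrow(tab), 0L)
  # 2-pixel cluster: degenerate -> dropped
  px <- data.frame(i = 0:1, j = 0L, count = 2L, cluster = 1L)
  tab <- cluster_areas(px, grid_of(px), shape_params(), cluster_params())
  expect_equal(nrow(tab), 0L)
})

test_that("estimate_tetramers reproduces the printed worked examples and is monotone", {
  expect_equal(estimate_tetramers(12200, cluster_params(coverage = 0.495)), 8L)
  expect_equal(estimate_tetramers(729, cluster_params(coverage = 1.0)), 1L)
  expect_equal(estimate_tetramers(16000, cluster_params(coverage = 0.449)), 10L)
  expect_error(estimate_tetramers(1000, cluster_params()), "coverage")
  # monotone in area and coverage
  areas <- seq(1600, 40000, by = 700)
  n1 <- estimate_tetramers(areas, cluster_params(coverage = 0.5))
  expect_true(all(diff(n1) >= 0))
  covs <- seq(0.3, 0.7, by = 0.05)
  n2 <- vapply(covs, function(cv)
    estimate_tetramers(12200, cluster_params(coverage = cv)), integer(1))
  expect_true(all(diff(n2) >= 0))
  # round half away from zero
  expect_equal(estimate_tetramers(729 * 1.5, cluster_params(coverage = 1)), 2L)
})

test_that("median estimated count equals the transformed median area up to rounding", {
  set.seed(23)
  areas <- exp(rnorm(201, log(12000), 0.5))
  p <- cluster_params(coverage = 0.495)
  counts <- estimate_tetramers(areas, p)
  med <- estimate_tetramers(stats::median(areas), p)
  expect_lte(abs(stats::median(counts) - med), 0.5)
})
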