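test_that("generators are bit-reproducible for a fixed seed", {
  cfg <- array_gen_config(n_tetramers = 60, seed = 5)
  g1 <- gen_tetramer_array(cfg)
  g2 <- gen_tetramer_array(cfg)
  expect_identical(g1$array$x, g2$array$x)
  expect_identical(g1$labels$label, g2$labels$label)
  l1 <- gen_localizations(g1$array, blink_gen_config(seed = 7))
  l2 <- gen_localizations(g2$array, blink_gen_config(seed = 7))
  expect_identical(l1, l2)
  s1 <- gen_spark_table(spark_gen_config(seed = 9))
  s2 <- gen_spark_table(spark_gen_config(seed = 9))
  expect_identical(s1, s2)
})

test_that("pure side-by-side arrays without jitter have all NNDs at 28 nm", {
  g <- gen_tetramer_array(array_gen_config(
    n_tetramers = 30, target_fractions = c(0, 1, 0, 0),
    positional_jitter_sd = 0, angular_jitter_sd = 0, seed = 3))
  nnd <- nearest_neighbour_distances(g$array)$nnd
  expect_equal(nnd, rep(28, 30), tolerance = 1e-9)
})

test_that("a pure checkerboard generated array classifies 100% checkerboard", {
  g <- gen_tetramer_array(array_gen_config(
    n_tetramers = 40, target_fractions = c(1, 0, 0, 0), seed = 13))
  labs <- classify_tetramers(g$array)
  expect_true(all(labs$label == "checkerboard"))
})

test_that("generated arrays respect the footprint-overlap invariant", {
  for (seed in c(1, 2)) {
    g <- gen_tetramer_array(array_gen_config(n_tetramers = 100, seed = seed))
    ov <- ryrspat:::footprint_overlaps(g$array, tol = 15)
    expect_equal(nrow(ov), 0L)
  }
})

test_that("mixed arrays produce a bimodal NND histogram with modes at 28 and 34 nm", {
  g <- gen_tetramer_array(array_gen_config(n_tetramers = 600, seed = 17))
  nnd <- nearest_neighbour_distances(g$array)$nnd
  h <- hist(nnd[nnd < 50], breaks = seq(20, 50, by = 1), plot = FALSE)
  ss_zone <- h$mids > 24 & h$mids < 31
  cb_zone <- h$mids >= 31 & h$mids < 38
  mode_ss <- h$mids[ss_zone][which.max(h$counts[ss_zone])]
  mode_cb <- h$mids[cb_zone][which.max(h$counts[cb_zone])]
  expect_lte(abs(mode_ss - 28), 1)
  expect_lte(abs(mode_cb - 34), 1)
})

test_that("fully failing blinks leave nothing after QC", {
  g <- gen_tetramer_array(array_gen_config(n_tetramers = 6, seed = 2))
  locs <- gen_localizations(g$array, blink_gen_config(fail_fraction = 1,
                                                      seed = 4))
  expect_equal(nrow(qc_filter(locs, qc_thresholds())), 0L)
})

test_that("planted blink clouds are recovered as the right number of clusters", {
  # a single small array, no background: one cluster
  arr <- gen_checkerboard_lattice(2, 2, array_gen_config(seed = 6))
  locs <- gen_localizations(arr, blink_gen_config(background_density = 0,
                                                  seed = 8))
  tab <- dstorm_pipeline(locs, params = cluster_params(coverage = 0.5))
  expect_equal(nrow(tab), 1L)
  # two footprints 300 nm apart: two clusters
  a1 <- gen_checkerboard_lattice(2, 2, array_gen_config(seed = 6))
  a2 <- gen_checkerboard_lattice(2, 2, array_gen_config(seed = 7),
                                 origin = c(400, 0))
  both <- tetramer_array(
    data.frame(id = 1:8,
               x = c(a1$x, a2$x), y = c(a1$y, a2$y),
               theta = c(a1$theta, a2$theta)), overlap_tol = 15)
  locs <- gen_localizations(both, blink_gen_config(background_density = 0,
                                                   seed = 9))
  tab <- dstorm_pipeline(locs, params = cluster_params(coverage = 0.5))
  expect_equal(nrow(tab), 2L)
})

test_that("spark generator collapses to the geometric mean without noise", {
  cfg <- spark_gen_config(log_sd = c(amplitude = 0, fdhm = 0, fwhm = 0),
                          rat_sd = 0, cell_sd = 0, seed = 4)
  g <- gen_spark_table(cfg)
  expect_true(all(abs(g$sparks$amplitude - 0.45) < 1e-12))
  expect_true(all(abs(g$sparks$fdhm_ms - 25) < 1e-12))
  expect_true(all(abs(g$sparks$fwhm_um - 1.9) < 1e-12))
})

test_that("spark sample geometric means concentrate around the configured log-mean", {
  cfg <- spark_gen_config(n_rats = 10, cells_per_rat = 10,
                          sparks_per_cell = 100, seed = 12)
  g <- gen_spark_table(cfg)
  n <- nrow(g$sparks)
  expect_equal(n, 10 * 10 * 100)
  gm <- mean(log(g$sparks$amplitude))
  # total sd of a single log-value
  tot_sd <- sqrt(0.35^2 + 0.08^2 + 0.15^2)
  expect_lt(abs(gm - log(0.45)), 3 * tot_sd / sqrt(n) + 3 * 0.08 / sqrt(10))
})

test_that("generated spark tables carry a frequency table with SR content", {
  g <- gen_spark_table(spark_gen_config(seed = 2))
  expect_true(all(c("rate", "sr_content") %in% names(g$frequency)))
  expect_true(all(g$frequency$sr_content > 0))
  expect_true(all(g$frequency$rate >= 0))
  norm <- normalize_frequency(g$frequency$rate, g$frequency$sr_content)
  expect_equal(length(norm), nrow(g$frequency))
})
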