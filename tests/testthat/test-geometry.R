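test_that("pair_relation reproduces the canonical square configurations", {
  a <- list(x = 0, y = 0, theta = 0)
  # abutting side-by-side: gap 1, full overlap
  r <- pair_relation(a, list(x = 28, y = 0, theta = 0))
  expect_true(r$parallel)
  expect_equal(r$gap, 1)
  expect_equal(r$overlap, 27)
  expect_equal(r$centre_distance, 28)
  # checkerboard offset (28, 20): gap 1, overlap 7
  r <- pair_relation(a, list(x = 28, y = 20, theta = 0))
  expect_equal(r$gap, 1)
  expect_equal(r$overlap, 7)
  expect_equal(r$centre_distance, sqrt(28^2 + 20^2))
  # pure translation along one axis: gap 33, overlap 27
  r <- pair_relation(a, list(x = 0, y = 60, theta = 0))
  expect_equal(r$gap, 33)
  expect_equal(r$overlap, 27)
  # rotated out of tolerance: not parallel
  r <- pair_relation(a, list(x = 28, y = 0, theta = 30))
  expect_false(r$parallel)
  expect_true(is.na(r$gap))
  # 4-fold symmetry: theta 89 vs 1 differs by 2 degrees, parallel
  r <- pair_relation(list(x = 0, y = 0, theta = 89),
                     list(x = 40, y = 0, theta = 1))
  expect_true(r$parallel)
  expect_equal(r$delta_theta, 2)
})

test_that("pair_relation rejects non-finite input", {
  expect_error(pair_relation(list(x = NA, y = 0, theta = 0),
                             list(x = 1, y = 1, theta = 0)),
               "non-finite")
})

test_that("pair_relation is symmetric in its arguments", {
  set.seed(101)
  for (i in 1:200) {
    a <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
              theta = runif(1, 0, 90))
    b <- list(x = runif(1, 0, 100), y = runif(1, 0, 100),
              theta = runif(1, 0, 90))
    r1 <- pair_relation(a, b)
    r2 <- pair_relation(b, a)
    expect_equal(r1$centre_distance, r2$centre_distance)
    expect_equal(r1$delta_theta, r2$delta_theta)
    expect_equal(r1$parallel, r2$parallel)
    if (isTRUE(r1$parallel)) {
      expect_equal(r1$gap, r2$gap, tolerance = 1e-9)
      expect_equal(r1$overlap, r2$overlap, tolerance = 1e-9)
    }
  }
})

test_that("gap + side equals the facing-axis centre separation for axis-aligned squares", {
  set.seed(11)
  for (i in 1:1000) {
    dx <- runif(1, 28, 200)   # facing across x: |dx| > |dy| overlap region
    dy <- runif(1, 0, 26)
    r <- pair_relation(list(x = 0, y = 0, theta = 0),
                       list(x = dx, y = dy, theta = 0))
    expect_equal(r$gap + 27, dx, tolerance = 1e-12)
    expect_equal(r$overlap, max(27 - dy, 0), tolerance = 1e-12)
  }
})

test_that("pair_relation agrees with the explicit polygon-edge reference", {
  set.seed(77)
  for (i in 1:500) {
    a <- list(x = 0, y = 0, theta = runif(1, 0, 90))
    b <- list(x = runif(1, -60, 60), y = runif(1, -60, 60),
              theta = runif(1, 0, 90))
    r1 <- pair_relation(a, b)
    r2 <- pair_relation_edges(a, b)
    expect_equal(r1$parallel, r2$parallel)
    if (isTRUE(r1$parallel) && r1$overlap > 0 && r2$overlap > 0) {
      expect_equal(r1$gap, r2$gap, tolerance = 1e-9)
      expect_equal(r1$overlap, r2$overlap, tolerance = 1e-9)
    }
  }
})

test_that("nearest_neighbour_distances matches simple arithmetic and the brute-force oracle", {
  arr <- tetramer_array(data.frame(x = c(0, 28), y = c(0, 0), theta = 0))
  expect_equal(nearest_neighbour_distances(arr)$nnd, c(28, 28))
  arr <- tetramer_array(data.frame(x = c(0, 28, 62), y = 0, theta = 0))
  expect_equal(nearest_neighbour_distances(arr)$nnd, c(28, 28, 34))
  for (n in c(10, 50, 200)) {
    df <- random_sparse_array(n, seed = n)
    arr <- tetramer_array(df)
    expect_equal(nearest_neighbour_distances(arr)$nnd,
                 oracle_nnd(df$x, df$y))
  }
  one <- tetramer_array(data.frame(x = 0, y = 0, theta = 0))
  expect_error(nearest_neighbour_distances(one), "at least 2")
})

test_that("tetramer_array validates invariants", {
  expect_error(tetramer_array(data.frame(x = numeric(0), y = numeric(0))),
               "at least one")
  expect_error(tetramer_array(data.frame(x = c(0, NA), y = c(0, 1))),
               "non-finite")
  # heavy footprint overlap rejected, light abutment accepted
  expect_error(tetramer_array(data.frame(x = c(0, 10), y = c(0, 0),
                                         theta = 0)),
               "overlap")
  expect_s3_class(tetramer_array(data.frame(x = c(0, 27.5), y = c(0, 0),
                                            theta = 0)),
                  "tetramer_array")
  # orientations reduced modulo 90
  arr <- tetramer_array(data.frame(x = 0, y = 0, theta = 95))
  expect_equal(arr$theta, 5)
})
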