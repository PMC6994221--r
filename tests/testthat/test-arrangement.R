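mk_rel <- function(gap, overlap, parallel = TRUE)
  structure(list(centre_distance = NA_real_, delta_theta = 0,
                 parallel = parallel, gap = gap, overlap = overlap),
            class = "pair_relation")

test_that("classify_pair applies the adjacency and overlap thresholds", {
  p <- arrangement_params()
  expect_equal(classify_pair(mk_rel(1, 27), p), "side_by_side")
  expect_equal(classify_pair(mk_rel(1, 7), p), "checkerboard")
  expect_equal(classify_pair(mk_rel(33, 27), p), "none")
  expect_equal(classify_pair(mk_rel(1, 27, parallel = FALSE), p), "none")
  # boundary conventions: strict on gap and on the checkerboard overlap
  expect_equal(classify_pair(mk_rel(3, 7), p), "none")
  expect_equal(classify_pair(mk_rel(1, 18), p), "side_by_side")
  expect_equal(classify_pair(mk_rel(1, 0), p), "none")  # corner contact
  # slight footprint interpenetration still counts as adjacent
  expect_equal(classify_pair(mk_rel(-0.3, 7), p), "checkerboard")
})

test_that("the overlap boundary and footprint follow from the 27-nm side", {
  side <- 27
  expect_equal(arrangement_params()$overlap_cb_max, 2 / 3 * side)
  expect_equal(cluster_params()$tetramer_area, side^2)
})

test_that("classify_pair agrees with the edge-arithmetic oracle on random pairs", {
  set.seed(42)
  p <- arrangement_params()
  n_agree <- 0L
  for (i in 1:1000) {
    a <- list(x = 0, y = 0, theta = runif(1, 0, 90))
    b <- list(x = runif(1, -50, 50), y = runif(1, -50, 50),
              theta = runif(1, 0, 90))
    l1 <- classify_pair(pair_relation(a, b), p)
    l2 <- classify_pair(pair_relation_edges(a, b), p)
    expect_identical(l1, l2)
    n_agree <- n_agree + (l1 == l2)
  }
  expect_identical(n_agree, 1000L)
})

test_that("classify_tetramers assigns the four labels from neighbourhoods", {
  # both: one side-by-side and one checkerboard neighbour
  # (offset (-20, -28): facing across y with gap 1 and overlap 7)
  arr <- tetramer_array(data.frame(id = 1:3,
                                   x = c(0, 28, -20), y = c(0, 0, -28),
                                   theta = 0))
  labs <- classify_tetramers(arr)
  expect_equal(as.character(labs$label[labs$id == 1]), "both")
  expect_equal(as.character(labs$label[labs$id == 2]), "side_by_side")
  expect_equal(as.character(labs$label[labs$id == 3]), "checkerboard")
  expect_equal(classify_tetramer(1, arr), "both")
  # far apart: isolated
  arr <- tetramer_array(data.frame(x = c(0, 200), y = c(0, 200), theta = 0))
  expect_true(all(classify_tetramers(arr)$label == "isolated"))
  # sole checkerboard neighbour
  arr <- tetramer_array(data.frame(x = c(0, 28), y = c(0, 20), theta = 0))
  expect_true(all(classify_tetramers(arr)$label == "checkerboard"))
})

test_that("summarize_arrangements pools counts into unit-sum fractions", {
  a1 <- tetramer_array(data.frame(x = c(0, 28, 200, 228), y = c(0, 0, 200, 220),
                                  theta = 0), group = "Control")
  s <- summarize_arrangements(list(a1))
  expect_equal(s$frac_side_by_side, 0.5)
  expect_equal(s$frac_checkerboard, 0.5)
  expect_equal(s$frac_both + s$frac_isolated, 0)
  expect_equal(s$n_tetramers, 4L)
  # single + far singleton: all isolated
  a2 <- tetramer_array(data.frame(x = c(0, 500), y = c(0, 500), theta = 0),
                       group = "Phos")
  s2 <- summarize_arrangements(list(a1, a2))
  expect_equal(s2$frac_isolated[s2$group == "Phos"], 1)
  fr <- s2[, grep("^frac_", names(s2))]
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  expect_error(summarize_arrangements(list()), "no arrays")
})

test_that("labels are invariant under common scaling of coordinates and thresholds", {
  set.seed(9)
  df <- random_sparse_array(30, seed = 13, spacing = 45)
  for (s in c(0.5, 2, 10)) {
    a1 <- tetramer_array(df, side = 27, overlap_tol = 20)
    df2 <- df; df2$x <- df$x * s; df2$y <- df$y * s
    a2 <- tetramer_array(df2, side = 27 * s, overlap_tol = 20 * s^2)
    p1 <- arrangement_params()
    p2 <- arrangement_params(gap_max = 3 * s, overlap_cb_max = 18 * s)
    expect_identical(as.character(classify_tetramers(a1, p1)$label),
                     as.character(classify_tetramers(a2, p2)$label))
  }
})

test_that("a pure checkerboard lattice classifies 100% checkerboard in the interior", {
  arr <- gen_checkerboard_lattice(5, 5, array_gen_config(seed = 21))
  labs <- classify_tetramers(arr)
  interior <- attr(arr, "interior")
  expect_true(all(labs$label[interior] == "checkerboard"))
})
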