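test_that("tetrahedrality is zero for a regular tetrahedron and scale-free", {
  expect_equal(tetrahedrality(rep(1, 6)), 0, tolerance = 1e-12)
  set.seed(5)
  l <- runif(6, 0.5, 2)
  for (c in c(1e-3, 0.1, 7, 1e4))
    expect_equal(tetrahedrality(c * l), tetrahedrality(l),
                 tolerance = 1e-12)
})

test_that("flat-square limit matches the closed form", {
  # 4 square sides a, 2 diagonals a*sqrt(2): T = 24(3-2sqrt2)/(5(6+4sqrt2))
  want <- 24 * (3 - 2 * sqrt(2)) / (5 * (6 + 4 * sqrt(2)))
  l <- c(1, 1, 1, 1, sqrt(2), sqrt(2))
  expect_equal(tetrahedrality(l), want, tolerance = 1e-12)
  expect_equal(bf_tetrahedrality(l), want, tolerance = 1e-12)
})

test_that("closed form agrees with the 15-pair brute-force sum", {
  set.seed(77)
  for (i in 1:1000) {
    l <- runif(6, 0.2, 3)
    tv <- tetrahedrality(l)
    bf <- bf_tetrahedrality(l)
    expect_equal(tv, bf, tolerance = 1e-12)
  }
})

test_that("tetrahedrality is invariant under edge permutation", {
  set.seed(8)
  l <- runif(6, 0.5, 2)
  t0 <- tetrahedrality(l)
  for (i in 1:20)
    expect_equal(tetrahedrality(sample(l)), t0, tolerance = 1e-13)
})

test_that("stretching one edge of a regular tetrahedron grows T as eps^2", {
  tt <- function(e) tetrahedrality(c(1 + e, 1, 1, 1, 1, 1))
  expect_gt(tt(1e-3), 0)
  # quadratic leading order: T(e)/e^2 approaches a constant
  r1 <- tt(1e-3) / 1e-6
  r2 <- tt(1e-4) / 1e-8
  expect_equal(r1, r2, tolerance = 1e-2)
})

test_that("non-positive edge lengths are rejected", {
  expect_error(tetrahedrality(c(1, 1, 1, 1, 1, 0)), "positive")
  expect_error(tetrahedrality(c(1, 1, 1, 1, 1, -2)), "positive")
})

test_that("class histograms share a grid and sum to the pooled histogram", {
  lc <- generate_ideal(250, p_w = 0.5, seed = 13)
  tess <- tessellate(lc)
  d <- build_distributions(tess, bin_width = 0.05)
  expect_equal(rowSums(d$counts_by_class), d$pooled)
  expect_equal(sum(d$pooled), tess$diagnostics$n_simplices)
  expect_equal(colSums(d$counts_by_class),
               d$n_values[tet_class_names()], ignore_attr = TRUE)
  expect_equal(diff(d$bin_edges), rep(0.05, length(d$pooled)),
               tolerance = 1e-12)
  # densities integrate to one
  df <- as.data.frame(d)
  expect_equal(sum(df$pooled) * d$bin_width, 1, tolerance = 1e-12)
})

test_that("regular simplices put all their mass in the zero bin", {
  tess <- tessellate(fixture_regular_tetrahedron(1))
  d <- build_distributions(tess)
  expect_equal(sum(d$pooled), 1)
  expect_equal(d$pooled[1], 1)
  expect_error(build_distributions(list()), "empty")
  expect_error(build_distributions(tess, bin_width = 0),
               "bin_width")
})

test_that("modes of a constructed bimodal histogram recover the centres", {
  set.seed(99)
  tv <- c(rnorm(4000, 0.05, 0.02), rnorm(2500, 1.7, 0.05))
  tv <- tv[tv >= 0]
  d <- solvtess:::t_distribution_from_values(
    tv, sample(0:4, length(tv), replace = TRUE), 0.05)
  m <- distribution_modes(d, min_prominence = 0.1)
  expect_equal(nrow(m), 2L)
  expect_lt(abs(m$t[1] - 0.05), 0.05)
  expect_lt(abs(m$t[2] - 1.7), 0.05)
})

test_that("unimodal and flat histograms report one and zero modes", {
  set.seed(4)
  uni <- abs(rnorm(3000, 0, 0.04))
  d1 <- solvtess:::t_distribution_from_values(
    uni, rep(4L, length(uni)), 0.05)
  m1 <- distribution_modes(d1)
  expect_equal(nrow(m1), 1L)
  expect_lt(m1$t[1], 0.1)

  flat <- seq(0.001, 0.999, length.out = 500)
  d2 <- solvtess:::t_distribution_from_values(
    flat, rep(2L, 500), 0.05)
  expect_equal(nrow(distribution_modes(d2)), 0L)
})
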