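test_that("classification counts W vertices irrespective of order", {
  ids <- matrix(1:4, 1)
  expect_equal(classify_tetrahedra(ids, c("W", "W", "W", "W")), 4L)
  expect_equal(classify_tetrahedra(ids, c("S", "S", "S", "S")), 0L)
  for (perm in list(c("W", "W", "S", "S"), c("S", "W", "S", "W"),
                    c("S", "S", "W", "W")))
    expect_equal(classify_tetrahedra(ids, perm), 2L)
  expect_error(classify_tetrahedra(matrix(c(1, 2, 3, 9), 1),
                                   c("W", "W", "S", "S")), "vertex id")
})

test_that("the four-vertex two-letter alphabet collapses to five classes", {
  labelings <- expand.grid(rep(list(c("W", "S")), 4),
                           stringsAsFactors = FALSE)
  k <- apply(labelings, 1, function(l)
    classify_tetrahedra(matrix(1:4, 1), l))
  expect_equal(sort(unique(k)), 0:4)
  expect_equal(as.numeric(table(k)), choose(4, 0:4))
})

test_that("expected probabilities are the binomial pmf and normalise", {
  expect_equal(expected_probability(4, 0.5), 0.0625)
  expect_equal(expected_probability(2, 0.5), 0.375)
  expect_equal(expected_probability(3, 0), 0)
  for (p in c(0, 0.17, 0.5, 0.93, 1))
    expect_equal(sum(expected_probability(0:4, p)), 1, tolerance = 1e-15)
  expect_error(expected_probability(5, 0.5), "k must")
  expect_error(expected_probability(2, 1.2), "p_w")
})

test_that("abundance reproduces the pure-class worked example", {
  cc <- composition_counts(c(W4 = 16, S4 = 16), n_w = 50, n_T = 100)
  ab <- abundance(cc)
  w4 <- ab[ab$class == "W4", ]
  expect_equal(w4$p_obs, 0.5)
  expect_equal(w4$p_exp, 0.0625)
  expect_equal(w4$ratio, 8)
  expect_equal(w4$f, log10(8), tolerance = 1e-12)
  # mixed classes were never observed: f is an explicit undefined marker
  expect_true(all(is.na(ab$f[ab$class %in% c("W3S", "W2S2", "WS3")])))
  expect_equal(sum(ab$p_obs), 1)
  expect_equal(sum(ab$p_exp), 1, tolerance = 1e-15)
})

test_that("counts proportional to the binomial null give f = 0", {
  cc <- composition_counts(
    setNames(c(10, 40, 60, 40, 10), c("W4", "W3S", "W2S2", "WS3", "S4")),
    n_w = 250, n_T = 500)
  ab <- abundance(cc)
  expect_equal(ab$f, rep(0, 5), tolerance = 1e-12)
})

test_that("pure-liquid endpoints mark mixed-class f as undefined", {
  cc <- composition_counts(c(W4 = 100), n_w = 60, n_T = 60)
  ab <- abundance(cc)
  expect_equal(ab$f[ab$class == "W4"], 0)
  expect_true(all(is.na(ab$f[ab$class != "W4"])))
  expect_error(abundance(composition_counts(c(W4 = 0), 5, 10)),
               "no simplices")
})

test_that("pooling sums counts and refuses mixed systems", {
  a <- composition_counts(c(W4 = 3, W2S2 = 2), n_w = 10, n_T = 20)
  b <- composition_counts(c(W4 = 1, S4 = 4), n_w = 10, n_T = 20)
  expect_equal(pool_counts(list(a))$n_by_class, a$n_by_class)
  p <- pool_counts(list(a, b))
  expect_equal(p$n_by_class[["W4"]], 4)
  expect_equal(p$n_by_class[["S4"]], 4)
  expect_equal(p$frames_pooled, 2L)
  other <- composition_counts(c(W4 = 1), n_w = 12, n_T = 20)
  expect_error(pool_counts(list(a, other)), "mismatched")
  agg <- pool_counts(list(a, other), match = "aggregate")
  expect_equal(agg$n_w, 22)
  expect_equal(agg$n_T, 40)
})

test_that("relabelling W<->S mirrors classes, p_w and abundance", {
  lc <- generate_ideal(300, p_w = 0.35, seed = 21)
  tess <- tessellate(lc)
  swapped <- ifelse(lc$labels == "W", "S", "W")
  k1 <- classify_tetrahedra(tess)
  k2 <- classify_tetrahedra(tess, swapped)
  expect_equal(k2, 4L - k1)
  ab1 <- abundance(count_composition(tess))
  ab2 <- abundance(count_composition(tess, swapped))
  expect_equal(attr(ab2, "p_w"), 1 - attr(ab1, "p_w"))
  expect_equal(ab2$f[ab2$k == 0], ab1$f[ab1$k == 4], tolerance = 1e-12)
  expect_equal(ab2$f[ab2$k == 1], ab1$f[ab1$k == 3], tolerance = 1e-12)
  expect_equal(ab2$f[ab2$k == 2], ab1$f[ab1$k == 2], tolerance = 1e-12)
})
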