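test_that("four non-coplanar points give one simplex with direct edge lengths", {
  set.seed(101)
  u <- matrix(runif(12), 4, 3)
  lc <- embed_nonperiodic(u)
  tess <- tessellate(lc)
  expect_equal(tess$diagnostics$n_simplices, 1L)
  d <- as.matrix(dist(lc$coords))
  direct <- sort(d[lower.tri(d)])
  expect_equal(sort(as.numeric(tess$edge_lengths)), direct,
               tolerance = 1e-12)
})

test_that("regular tetrahedron plus centroid tessellates into 4 simplices", {
  s <- 1 / sqrt(2)
  pts <- rbind(c(0, 0, 0), c(s, s, 0), c(s, 0, s), c(0, s, s))
  pts <- rbind(pts, colMeans(pts))
  lc <- embed_nonperiodic(pts)
  tess <- tessellate(lc)
  got <- unique(t(apply(tess$vertex_ids, 1, sort)))
  want <- bf_delaunay(lc$coords)
  expect_equal(nrow(got), 4L)
  expect_equal(got[order(got[, 1], got[, 2], got[, 3], got[, 4]), ],
               want[order(want[, 1], want[, 2], want[, 3], want[, 4]), ],
               ignore_attr = TRUE)
})

test_that("every simplex satisfies the empty-circumsphere property", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:30, 1)
    lc <- embed_nonperiodic(matrix(runif(3 * n), n, 3))
    tess <- tessellate(lc)
    for (r in seq_len(nrow(tess$vertex_ids))) {
      idx <- tess$vertex_ids[r, ]
      cs <- circumsphere_of(lc$coords[idx, , drop = FALSE])
      others <- setdiff(seq_len(n), idx)
      d <- sqrt(rowSums(sweep(lc$coords[others, , drop = FALSE], 2,
                              cs$centre)^2))
      expect_true(all(d > cs$r - 1e-7),
                  label = sprintf("circumsphere empty (seed %d row %d)",
                                  seed, r))
    }
  }
})

test_that("periodic simplex volumes tile the box exactly", {
  # random liquid-like frame
  lc <- generate_ideal(200, p_w = 0.5, seed = 31)
  tess <- tessellate(lc)
  expect_lt(abs(sum(tess$volumes) - prod(lc$box)) / prod(lc$box), 1e-6)

  # maximally degenerate case: simple cubic lattice, every simplex at the
  # boundary involves periodic images
  g <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 0.5
  lcc <- labeled_configuration(g, rep("W", 8), rep(1, 3))
  tc <- tessellate(lcc)
  expect_lt(abs(sum(tc$volumes) - 1), 1e-6)
  expect_true(all(abs(tc$image_shifts) <= 1))
})

test_that("tessellation is invariant under rigid periodic translation", {
  lc <- generate_ideal(120, p_w = 0.5, seed = 17)
  tess1 <- tessellate(lc)
  shifted <- labeled_configuration(
    sweep(lc$coords, 2, c(0.31, -0.17, 0.52), "+"), lc$labels, lc$box)
  tess2 <- tessellate(shifted)
  key <- function(tt)
    sort(apply(round(t(apply(tt$edge_lengths, 1, sort)), 8), 1, paste,
               collapse = ","))
  expect_equal(tess2$diagnostics$n_simplices, tess1$diagnostics$n_simplices)
  expect_equal(key(tess2), key(tess1))
})

test_that("identical input produces the identical simplex set", {
  lc <- generate_ideal(150, p_w = 0.4, seed = 9)
  t1 <- tessellate(lc)
  t2 <- tessellate(lc)
  expect_identical(t1$vertex_ids, t2$vertex_ids)
  expect_identical(t1$edge_lengths, t2$edge_lengths)
})

test_that("neighbor_pairs counts edges of simplicial complexes", {
  tess <- tessellate(fixture_regular_tetrahedron(1))
  expect_equal(nrow(neighbor_pairs(tess)), 6L)

  # two simplices sharing a face: 10 point pairs minus the apex-apex pair
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0),
               c(0.5, 0.4, 0.8), c(0.5, 0.4, -0.8))
  lc <- embed_nonperiodic(pts / 2)
  tess2 <- tessellate(lc)
  expect_equal(tess2$diagnostics$n_simplices, 2L)
  expect_equal(nrow(neighbor_pairs(tess2)), 9L)

  expect_equal(nrow(neighbor_pairs(matrix(integer(0), 0, 4))), 0L)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(tessellate(labeled_configuration(matrix(runif(9), 3, 3),
                                                rep("W", 3), rep(10, 3))),
               "at least 4")
  set.seed(3)
  flat <- cbind(matrix(runif(20), 10, 2), 0.5)
  expect_error(tessellate(embed_nonperiodic(flat)), "coplanar")
})

test_that("an undersized ghost buffer is reported, not silently wrong", {
  lc <- generate_ideal(60, p_w = 0.5, seed = 23)
  expect_error(tessellate(lc, buffer_width = 0.01), "buffer_width")
})
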