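# Independent brute-force oracles used against the fast implementations.

# Circumsphere of 4 points (rows of a 4x3 matrix); NULL if coplanar.
circumsphere_of <- function(p) {
  a <- p[1, ]
  M <- 2 * sweep(p[2:4, , drop = FALSE], 2, a)
  rhs <- rowSums(sweep(p[2:4, , drop = FALSE], 2, a)^2)
  if (abs(det(M)) < 1e-12) return(NULL)
  x <- solve(M, rhs)
  list(centre = a + x, r = sqrt(sum(x^2)))
}

# Brute-force Delaunay of a small non-periodic point set: every 4-subset
# whose circumsphere contains no other point.  Rows are sorted indices.
bf_delaunay <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  keep <- list()
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    cs <- circumsphere_of(pts[idx, , drop = FALSE])
    if (is.null(cs)) next
    others <- setdiff(seq_len(n), idx)
    d <- sqrt(rowSums(sweep(pts[others, , drop = FALSE], 2,
                            cs$centre)^2))
    if (all(d > cs$r - tol)) keep[[length(keep) + 1L]] <- sort(idx)
  }
  do.call(rbind, keep)
}

# Direct double-loop evaluation of the 15-pair tetrahedrality sum.
bf_tetrahedrality <- function(l) {
  s <- 0
  for (i in 1:5) for (j in (i + 1):6) s <- s + (l[i] - l[j])^2
  s / (15 * mean(l)^2)
}

# Embed a point cloud (coordinates in [0, 1]^3) at the centre of a huge
# box so the tessellation is effectively non-periodic.
embed_nonperiodic <- function(u, labels = NULL, big = 100) {
  u <- as.matrix(u)
  if (is.null(labels)) labels <- rep("W", nrow(u))
  labeled_configuration(sweep(u, 2, (big - 1) / 2, "+"), labels,
                        rep(big, 3))
}

# Minimum-image distance matrix under an orthorhombic box.
min_image_dists <- function(coords, box) {
  n <- nrow(coords)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- abs(outer(coords[, k], coords[, k], "-"))
    dk <- pmin(dk, box[k] - dk)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Small inline GRO fixture writer for frame-io tests.
write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
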