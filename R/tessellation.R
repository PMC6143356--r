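#' Periodic Delaunay tessellation of a labelled configuration
#'
#' Partitions the periodic box into non-overlapping tetrahedra whose
#' vertices are the heavy atoms of `config`, using ghost replication:
#' atoms within `buffer_width` of a cell face are copied into a buffered
#' slab, the enlarged cloud is tessellated non-periodically, and a
#' simplex is attributed to the primary cell iff its circumcentre
#' (fallback: centroid, for numerically degenerate simplices) lies in the
#' half-open box `[0, box)`.  Each periodic simplex is therefore counted
#' exactly once; a canonical-key pass removes the (measure-zero)
#' duplicates that round-off at cell boundaries can produce.
#'
#' Degenerate point configurations (cospherical sets such as lattices)
#' are handled by a deterministic symbolic perturbation: every atom is
#' displaced by a tiny hash-derived offset, identical for all of its
#' periodic images, so ties are broken consistently across the boundary.
#' The perturbation only steers the topology; all reported edge lengths,
#' volumes and circumcentres are computed from the true coordinates.
#'
#' @param config A [labeled_configuration()].
#' @param buffer_width Ghost-slab width (nm).  Must exceed the largest
#'   circumradius of any kept simplex (validated; an error instructs a
#'   larger buffer otherwise).  Default `min(box)/4`, safe for liquid
#'   densities.
#' @param degeneracy_tol Simplices with volume below this (nm^3) are
#'   discarded and counted in the diagnostics.  Default `1e-10`.
#' @param perturb Relative magnitude of the symbolic perturbation
#'   (fraction of the smallest box edge).  Default `1e-9`.
#'
#' @return An object of class `delaunay_tess`: a list with
#'   * `vertex_ids`: m x 4 matrix of primary-cell atom indices,
#'   * `image_shifts`: m x 12 matrix of per-vertex integer box shifts
#'     (columns v1x,v1y,v1z, v2x, ...), canonicalised so the vertex with
#'     the smallest id has shift 0,
#'   * `edge_lengths`: m x 6 matrix (nm), pair order 12,13,14,23,24,34,
#'   * `volumes`: length-m vector (nm^3),
#'   * `labels`, `box`, `chi_s` copied from `config`,
#'   * `diagnostics`: list with `n_simplices`, `n_degenerate`,
#'     `n_duplicates`, `max_circumradius`, `buffer_width`.
#' @export
#' @examples
#' lc <- fixture_regular_tetrahedron(edge = 1)
#' tess <- tessellate(lc)
#' tess$edge_lengths
tessellate <- function(config, buffer_width = NULL,
                       degeneracy_tol = 1e-10, perturb = 1e-9) {
  stopifnot(inherits(config, "labeled_configuration"))
  coords <- config$coords
  box <- config$box
  n <- nrow(coords)
  if (n < 4L) stop("tessellation requires at least 4 points")
  if (is.null(buffer_width)) buffer_width <- min(box) / 4
  if (buffer_width <= 0) stop("buffer_width must be positive")
  if (buffer_width > min(box))
    stop("buffer_width larger than the box is not supported ",
         "(only first-shell periodic images are replicated)")

  ## -- ghost replication -------------------------------------------------
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0L, , drop = FALSE]
  cloud <- coords
  owner <- seq_len(n)
  cshift <- matrix(0L, n, 3)
  for (r in seq_len(nrow(shifts))) {
    img <- sweep(coords, 2, shifts[r, ] * box, "+")
    keep <- img[, 1] > -buffer_width & img[, 1] < box[1] + buffer_width &
            img[, 2] > -buffer_width & img[, 2] < box[2] + buffer_width &
            img[, 3] > -buffer_width & img[, 3] < box[3] + buffer_width
    if (any(keep)) {
      cloud <- rbind(cloud, img[keep, , drop = FALSE])
      owner <- c(owner, which(keep))
      cshift <- rbind(cshift,
                      matrix(rep(shifts[r, ], sum(keep)), ncol = 3,
                             byrow = TRUE))
    }
  }

  ## -- symbolic perturbation (per primary id, shared by all images) ------
  eps <- perturb * min(box)
  pert <- vapply(1:3, function(d) {
    h <- sin(owner * (12.9898 + 37.719 * d)) * 43758.5453
    (h - floor(h)) - 0.5
  }, numeric(length(owner)))
  cloudp <- cloud + eps * pert

  ## -- condition and tessellate ------------------------------------------
  off <- apply(cloudp, 2, min)
  scl <- max(apply(cloudp, 2, max) - off, .Machine$double.eps)
  simp <- .bw_delaunay(sweep(cloudp, 2, off) / scl)
  if (nrow(simp) == 0L)
    stop("tessellation produced no simplices (coplanar input?)")

  geo <- .simplex_geometry(cloud, simp)

  ## -- degenerate simplices ------------------------------------------------
  degen <- geo$volume < degeneracy_tol
  n_degenerate <- sum(degen)
  if (all(degen)) stop("all simplices degenerate: points are coplanar")

  ## -- attribute one copy of each periodic simplex to the primary cell ---
  centre <- geo$centre
  centre[is.na(geo$radius), ] <-
    centre[is.na(geo$radius), , drop = FALSE]  # centroid fallback already
  keep <- !degen &
    centre[, 1] >= 0 & centre[, 1] < box[1] &
    centre[, 2] >= 0 & centre[, 2] < box[2] &
    centre[, 3] >= 0 & centre[, 3] < box[3]
  if (!any(keep))
    stop("no simplex attributed to the primary cell; check box and buffer")

  simp <- simp[keep, , drop = FALSE]
  edges <- geo$edges[keep, , drop = FALSE]
  vols <- geo$volume[keep]
  rad <- geo$radius[keep]
  cc <- geo$centre[keep, , drop = FALSE]

  ids <- matrix(owner[simp], ncol = 4)
  sh <- cbind(matrix(cshift[simp[, 1], ], ncol = 3),
              matrix(cshift[simp[, 2], ], ncol = 3),
              matrix(cshift[simp[, 3], ], ncol = 3),
              matrix(cshift[simp[, 4], ], ncol = 3))

  ## -- canonical dedup (round-off backstop) -------------------------------
  key <- canonical_simplex_key(ids, sh)
  dup <- duplicated(key)
  n_duplicates <- sum(dup)
  if (n_duplicates > 0L) {
    ids <- ids[!dup, , drop = FALSE]
    sh <- sh[!dup, , drop = FALSE]
    edges <- edges[!dup, , drop = FALSE]
    vols <- vols[!dup]
    rad <- rad[!dup]
    cc <- cc[!dup, , drop = FALSE]
  }

  ## -- buffer validation -------------------------------------------------
  ## A kept simplex is guaranteed Delaunay w.r.t. the periodic set only if
  ## its circumsphere stays inside the ghost slab.  Spheres that reach
  ## beyond it (hull slivers of effectively non-periodic clouds) are
  ## verified directly against all first-shell periodic images, which is
  ## sufficient whenever r < min(box).
  fin <- which(!is.na(rad))
  ccf <- cc[fin, , drop = FALSE]
  rf <- rad[fin]
  exits <- rep(FALSE, length(fin))
  for (d in 1:3)
    exits <- exits | (ccf[, d] - rf < -buffer_width) |
      (ccf[, d] + rf > box[d] + buffer_width)
  reach <- fin[exits]
  if (length(reach)) {
    if (any(rad[reach] >= min(box)))
      stop("a kept simplex's circumsphere (radius ",
           format(max(rad[reach])), " nm) exceeds the box; ",
           "increase buffer_width (current ", format(buffer_width), " nm)")
    allsh <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
    for (r in reach) {
      ctr <- cc[r, ]
      for (srow in seq_len(nrow(allsh))) {
        img <- sweep(coords, 2, allsh[srow, ] * box, "+")
        d2 <- (img[, 1] - ctr[1])^2 + (img[, 2] - ctr[2])^2 +
          (img[, 3] - ctr[3])^2
        if (any(d2 < (rad[r] - 1e-9 * min(box))^2))
          stop("a kept simplex's circumsphere reaches beyond the ghost ",
               "slab and contains an unreplicated periodic image; ",
               "increase buffer_width (current ", format(buffer_width),
               " nm)")
      }
    }
  }

  structure(
    list(vertex_ids = ids, image_shifts = sh, edge_lengths = edges,
         volumes = vols, circumcenters = cc, circumradii = rad,
         labels = config$labels, box = box, chi_s = config$chi_s,
         n_atoms = n,
         diagnostics = list(
           n_simplices = nrow(ids), n_degenerate = n_degenerate,
           n_duplicates = n_duplicates,
           max_circumradius = if (length(rf)) max(rf) else NA_real_,
           buffer_width = buffer_width)),
    class = "delaunay_tess")
}

## Canonical key for a periodic simplex: vertices ordered by
## (id, shift), shifts taken relative to the first vertex in that order.
canonical_simplex_key <- function(ids, sh) {
  m <- nrow(ids)
  ## reference vertex: smallest id (ties: smallest encoded shift)
  enc <- (sh[, c(1, 4, 7, 10)] + 2L) * 25L + (sh[, c(2, 5, 8, 11)] + 2L) * 5L +
    (sh[, c(3, 6, 9, 12)] + 2L)
  ordv <- ids * 256 + enc  # id dominates; enc in [0,124]
  ref <- max.col(-ordv, ties.method = "first")
  idx <- cbind(seq_len(m), ref)
  rsx <- matrix(sh[, c(1, 4, 7, 10)], m)[idx]
  rsy <- matrix(sh[, c(2, 5, 8, 11)], m)[idx]
  rsz <- matrix(sh[, c(3, 6, 9, 12)], m)[idx]
  code <- matrix(0, m, 4)
  for (v in 1:4) {
    cx <- sh[, 3 * v - 2] - rsx + 2L
    cy <- sh[, 3 * v - 1] - rsy + 2L
    cz <- sh[, 3 * v] - rsz + 2L
    code[, v] <- ids[, v] * 125 + cx * 25 + cy * 5 + cz
  }
  ## sorting network over the 4 columns
  lo <- pmin(code[, 1], code[, 2]); hi <- pmax(code[, 1], code[, 2])
  code[, 1] <- lo; code[, 2] <- hi
  lo <- pmin(code[, 3], code[, 4]); hi <- pmax(code[, 3], code[, 4])
  code[, 3] <- lo; code[, 4] <- hi
  lo <- pmin(code[, 1], code[, 3]); hi <- pmax(code[, 1], code[, 3])
  code[, 1] <- lo; code[, 3] <- hi
  lo <- pmin(code[, 2], code[, 4]); hi <- pmax(code[, 2], code[, 4])
  code[, 2] <- lo; code[, 4] <- hi
  lo <- pmin(code[, 2], code[, 3]); hi <- pmax(code[, 2], code[, 3])
  code[, 2] <- lo; code[, 3] <- hi
  paste(code[, 1], code[, 2], code[, 3], code[, 4], sep = ".")
}

#' @export
print.delaunay_tess <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "delaunay_tess: %d simplices over %d atoms (%d degenerate, %d duplicate removed)\n",
    d$n_simplices, x$n_atoms, d$n_degenerate, d$n_duplicates))
  cat(sprintf("  max circumradius %.4f nm (buffer %.4f nm)\n",
              d$max_circumradius, d$buffer_width))
  invisible(x)
}

#' Nearest-neighbour pairs from a tessellation
#'
#' Atoms joined by an edge of any Delaunay tetrahedron are nearest
#' neighbours.  Returns the union of the 6 edges of every simplex as
#' unordered pairs of primary-cell atom indices (an edge between an atom
#' and a periodic image still reports the two primary identities).
#'
#' @param tess A `delaunay_tess`, or a list with a `vertex_ids` matrix.
#' @return Two-column integer matrix of unique unordered pairs (i <= j);
#'   zero rows for an empty tessellation.
#' @export
neighbor_pairs <- function(tess) {
  ids <- if (is.matrix(tess)) tess else tess$vertex_ids
  if (is.null(ids) || nrow(ids) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- rbind(ids[, c(1, 2), drop = FALSE], ids[, c(1, 3), drop = FALSE],
                 ids[, c(1, 4), drop = FALSE], ids[, c(2, 3), drop = FALSE],
                 ids[, c(2, 4), drop = FALSE], ids[, c(3, 4), drop = FALSE])
  pairs <- cbind(i = pmin(pairs[, 1], pairs[, 2]),
                 j = pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

#' Dump simplices as a TSV for inspection
#'
#' One row per tetrahedron: frame, the four primary-cell vertex ids,
#' composition class, volume (nm^3) and tetrahedrality.
#'
#' @param tess A `delaunay_tess`.
#' @param path Output file.
#' @param frame Frame ordinal written in the first column.
#' @return `path`, invisibly.
#' @export
export_simplices <- function(tess, path, frame = 1L) {
  stopifnot(inherits(tess, "delaunay_tess"))
  k <- classify_tetrahedra(tess)
  df <- data.frame(frame = frame,
                   v1 = tess$vertex_ids[, 1], v2 = tess$vertex_ids[, 2],
                   v3 = tess$vertex_ids[, 3], v4 = tess$vertex_ids[, 4],
                   class = class_for_k(k), volume = tess$volumes,
                   T = tetrahedrality(tess$edge_lengths))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
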