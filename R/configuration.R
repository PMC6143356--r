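#' Labelled point configuration
#'
#' One frame of a binary-mixture system: heavy-atom coordinates, a
#' two-letter label per atom (`"W"` for water oxygen, `"S"` for any
#' cosolvent heavy atom) and the orthorhombic periodic box.  Coordinates
#' are wrapped into the primary cell `[0, box)` per dimension on
#' construction.
#'
#' @param coords Numeric N x 3 matrix of coordinates (nm).
#' @param labels Character vector of length N, each `"W"` or `"S"`.
#' @param box Numeric length-3 vector of strictly positive box edge
#'   lengths (nm).  Only orthorhombic boxes are supported.
#' @param frame_index Integer ordinal of the frame within its trajectory.
#' @param chi_s Optional cosolvent mole fraction (molecule-based) carried
#'   as metadata; distinct from the heavy-atom fraction `p_w` used by the
#'   binomial null.
#'
#' @return An object of class `labeled_configuration`: a list with
#'   elements `coords`, `labels`, `box`, `frame_index`, `chi_s`, `n_w`,
#'   `n_s`.
#' @export
#' @examples
#' lc <- labeled_configuration(matrix(runif(30), 10, 3),
#'                             rep(c("W", "S"), 5), box = c(1, 1, 1))
#' lc$n_w
labeled_configuration <- function(coords, labels, box, frame_index = 1L,
                                  chi_s = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have one entry per coordinate row")
  if (!all(labels %in% c("W", "S")))
    stop("labels may contain only \"W\" and \"S\"")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 strictly positive edge lengths (orthorhombic)")
  if (any(!is.finite(coords))) stop("coords contain non-finite values")
  coords <- wrap_coords(coords, box)
  structure(
    list(coords = coords, labels = labels, box = box,
         frame_index = as.integer(frame_index), chi_s = chi_s,
         n_w = sum(labels == "W"), n_s = sum(labels == "S")),
    class = "labeled_configuration")
}

#' Wrap coordinates into the primary cell
#'
#' Applies the half-open convention: each coordinate is mapped into
#' `[0, box_d)` along dimension d.
#'
#' @param coords Numeric N x 3 matrix (nm).
#' @param box Numeric length-3 box edges (nm).
#' @return Wrapped N x 3 matrix.
#' @export
wrap_coords <- function(coords, box) {
  coords <- as.matrix(coords)
  for (d in 1:3) {
    x <- coords[, d] - floor(coords[, d] / box[d]) * box[d]
    x[x >= box[d]] <- 0  # guards the x == box case after round-off
    coords[, d] <- x
  }
  coords
}

#' @export
print.labeled_configuration <- function(x, ...) {
  cat(sprintf(
    "labeled_configuration: %d atoms (%d W, %d S), box %.3f x %.3f x %.3f nm, frame %d\n",
    nrow(x$coords), x$n_w, x$n_s, x$box[1], x$box[2], x$box[3],
    x$frame_index))
  if (!is.na(x$chi_s)) cat(sprintf("  chi_s = %.4f\n", x$chi_s))
  invisible(x)
}

#' Cosolvent mole fraction
#'
#' Mole fraction of cosolvent molecules, `chi_s = n_s / (n_w + n_s)`,
#' computed from molecule counts.  Note this is distinct from the
#' heavy-atom water fraction `p_w` used by the binomial null: one
#' acetonitrile molecule contributes 3 heavy atoms and one DMSO molecule
#' contributes 4, so the two scales differ.
#'
#' @param n_water_molecules Number of water molecules (>= 0).
#' @param n_solvent_molecules Number of cosolvent molecules (>= 0).
#' @return Mole fraction in `[0, 1]`.
#' @export
#' @examples
#' mole_fraction(50, 50)
mole_fraction <- function(n_water_molecules, n_solvent_molecules) {
  if (n_water_molecules < 0 || n_solvent_molecules < 0)
    stop("molecule counts must be non-negative")
  tot <- n_water_molecules + n_solvent_molecules
  if (tot <= 0) stop("at least one molecule count must be positive")
  n_solvent_molecules / tot
}
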