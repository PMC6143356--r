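#' @title Synthetic configuration generators
#' @description Generators for labelled point configurations with
#'   controlled mixing structure, standing in for MD snapshots: an ideal
#'   randomly-mixed liquid (the exact null of the binomial abundance
#'   statistic), and demixed structures (slab or clusters) emulating
#'   microheterogeneity.  Points carry a hard-core exclusion distance
#'   mimicking liquid excluded volume, which keeps the tessellation free
#'   of sliver-dominated pathologies.  All generators are deterministic
#'   under `seed` and leave the caller's RNG state untouched.
#' @name synthetic
NULL

## Default heavy-atom number density (atoms / nm^3) used when no box is
## given; liquid water is ~33 oxygen/nm^3, typical organic cosolvents are
## less dense, so 30/nm^3 is a realistic mixture value.
DEFAULT_DENSITY <- 30

default_box <- function(n_points) rep((n_points / DEFAULT_DENSITY)^(1/3), 3)

## Sequential hard-core insertion with periodic minimum-image distances.
place_hardcore <- function(n, box, min_sep, max_tries = 5000L) {
  vol <- prod(box)
  packing <- n * (4 / 3) * pi * (min_sep / 2)^3 / vol
  if (packing > 0.35)
    stop(sprintf(
      "hard-core packing fraction %.2f infeasible for random insertion",
      packing))
  .place_hardcore(as.integer(n), as.numeric(box), min_sep,
                  as.integer(max_tries))
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Ideal randomly-mixed configuration
#'
#' Points are placed uniformly in the box under hard-core rejection and
#' labelled independently of their positions -- the exact null of the
#' binomial composition expectation.  With `label_mode = "bernoulli"`
#' (default) each atom is W with probability `p_w` independently; with
#' `"exact"` exactly `round(p_w * n)` atoms are W (a uniformly random
#' subset), which fixes `n_w` across frames but makes the per-tetrahedron
#' null hypergeometric rather than binomial.
#'
#' @param n_points Number of heavy atoms (>= 4).
#' @param p_w Target water-atom fraction in `[0, 1]`.
#' @param box Length-3 box (nm); default a cube at heavy-atom density
#'   30 nm^-3.
#' @param min_separation Hard-core exclusion distance (nm), default 0.25.
#' @param seed Integer seed; fully determines the output.
#' @param label_mode `"bernoulli"` or `"exact"`.
#' @param chi_s Optional mole-fraction metadata to carry.
#' @param frame_index Frame ordinal.
#' @return A [labeled_configuration()].
#' @export
#' @examples
#' lc <- generate_ideal(100, p_w = 0.5, seed = 1)
generate_ideal <- function(n_points, p_w, box = NULL,
                           min_separation = 0.25, seed = NULL,
                           label_mode = c("bernoulli", "exact"),
                           chi_s = NA_real_, frame_index = 1L) {
  label_mode <- match.arg(label_mode)
  if (p_w < 0 || p_w > 1) stop("p_w must lie in [0, 1]")
  if (is.null(box)) box <- default_box(n_points)
  with_seed_maybe(seed, {
    coords <- place_hardcore(n_points, box, min_separation)
    labels <- if (label_mode == "bernoulli") {
      ifelse(runif(n_points) < p_w, "W", "S")
    } else {
      l <- rep("S", n_points)
      l[sample.int(n_points, round(p_w * n_points))] <- "W"
      l
    }
    labeled_configuration(coords, labels, box, frame_index = frame_index,
                          chi_s = chi_s)
  })
}

#' Demixed (microheterogeneous) configuration
#'
#' Generates a phase-separated structure at the same overall composition
#' as [generate_ideal()]:
#' * `structure = "slab"`: positions are uniform hard-core; labels
#'   depend on position.  An S-rich slab of thickness
#'   `(1 - slab_fraction) * Lz` sits at the centre of the z axis with
#'   diffuse logistic interfaces of width `interface_width`; the
#'   probability that an atom at height z is labelled W is one minus the
#'   slab profile.  `interface_width` much larger than the box recovers
#'   an ideal mixture; small widths give sharp demixing.
#' * `structure = "clusters"`: the S atoms are placed around
#'   `cluster_count` uniformly drawn centres with isotropic Gaussian
#'   spread `cluster_sd` (periodically wrapped, hard-core enforced), W
#'   atoms uniformly elsewhere.
#'
#' @inheritParams generate_ideal
#' @param structure `"slab"` or `"clusters"`.
#' @param slab_fraction Fraction of the z axis assigned to the W-rich
#'   region (slab only); defaults to `p_w`.
#' @param interface_width Logistic interface width (nm), default 0.3 --
#'   about one molecular diameter, a realistic diffuse liquid-liquid
#'   interface.
#' @param cluster_count Number of S clusters (clusters only), default 2.
#' @param cluster_sd Gaussian spread of each cluster (nm); default
#'   `min(box)/8`.
#' @return A [labeled_configuration()].
#' @export
#' @examples
#' lc <- generate_demixed(200, p_w = 0.5, structure = "slab", seed = 1)
generate_demixed <- function(n_points, p_w, box = NULL,
                             structure = c("slab", "clusters"),
                             slab_fraction = p_w, interface_width = 0.3,
                             cluster_count = 2L, cluster_sd = NULL,
                             min_separation = 0.25, seed = NULL,
                             chi_s = NA_real_, frame_index = 1L) {
  structure <- match.arg(structure)
  if (p_w < 0 || p_w > 1) stop("p_w must lie in [0, 1]")
  if (is.null(box)) box <- default_box(n_points)
  with_seed_maybe(seed, {
    if (structure == "slab") {
      if (interface_width <= 0) stop("interface_width must be positive")
      coords <- place_hardcore(n_points, box, min_separation)
      labels <- if (slab_fraction >= 1) rep("W", n_points)
        else if (slab_fraction <= 0) rep("S", n_points)
        else ifelse(
          runif(n_points) < 1 - slab_profile(coords[, 3], box[3],
                                             slab_fraction,
                                             interface_width),
          "W", "S")
    } else {
      n_s <- round((1 - p_w) * n_points)
      n_w <- n_points - n_s
      if (cluster_count < 1L) stop("cluster_count must be >= 1")
      if (is.null(cluster_sd)) cluster_sd <- min(box) / 8
      centres <- matrix(runif(3 * cluster_count), ncol = 3) %*% diag(box)
      coords <- matrix(NA_real_, n_points, 3)
      ms2 <- min_separation^2
      for (i in seq_len(n_points)) {
        placed <- FALSE
        for (try in seq_len(5000L)) {
          p <- if (i <= n_s) {
            ctr <- centres[1L + (i - 1L) %% cluster_count, ]
            (ctr + rnorm(3, sd = cluster_sd)) %% box
          } else {
            runif(3) * box
          }
          if (i > 1L) {
            d <- sweep(coords[seq_len(i - 1L), , drop = FALSE], 2, p)
            d <- sweep(abs(d), 2, box / 2,
                       function(a, h) ifelse(a > h, 2 * h - a, a))
            if (min(rowSums(d * d)) < ms2) next
          }
          coords[i, ] <- p
          placed <- TRUE
          break
        }
        if (!placed)
          stop("cluster placement failed; increase cluster_sd or box")
      }
      labels <- c(rep("S", n_s), rep("W", n_w))
    }
    labeled_configuration(coords, labels, box, frame_index = frame_index,
                          chi_s = chi_s)
  })
}

## S-slab composition profile along z: 1 inside the centred S slab,
## 0 outside, logistic edges of width w.
slab_profile <- function(z, lz, slab_fraction, w) {
  h <- (1 - slab_fraction) * lz
  z1 <- (lz - h) / 2
  z2 <- (lz + h) / 2
  stats::plogis((z - z1) / w) * stats::plogis((z2 - z) / w)
}

#' Synthetic trajectory
#'
#' A list of independent frames from one generator, emulating
#' uncorrelated snapshots of a single system.
#'
#' @param n_frames Number of frames.
#' @param generator `"ideal"`, `"slab"` or `"clusters"`.
#' @param seed Integer seed determining the whole trajectory.
#' @param ... Passed to [generate_ideal()] or [generate_demixed()].
#' @return List of [labeled_configuration()] with increasing
#'   `frame_index`.
#' @export
generate_trajectory <- function(n_frames, generator = c("ideal", "slab",
                                                        "clusters"),
                                seed = NULL, ...) {
  generator <- match.arg(generator)
  with_seed_maybe(seed, {
    lapply(seq_len(n_frames), function(i) {
      if (generator == "ideal")
        generate_ideal(..., seed = NULL, frame_index = i)
      else
        generate_demixed(..., structure = generator, seed = NULL,
                         frame_index = i)
    })
  })
}

#' Regular-tetrahedron fixture
#'
#' Four points at alternating vertices of a cube, scaled to the
#' requested edge length and centred in a box large enough that the
#' tessellation has no periodic contact.  All six pairwise distances are
#' equal, so the single resulting simplex has tetrahedrality 0.
#'
#' @param edge Edge length (nm), > 0.
#' @param labels Four labels in `{"W","S"}`; default all `"W"`.
#' @param box Box edges (nm); default `100 * edge` per side.
#' @return A [labeled_configuration()].
#' @export
#' @examples
#' tessellate(fixture_regular_tetrahedron(1))
fixture_regular_tetrahedron <- function(edge = 1, labels = rep("W", 4),
                                        box = NULL) {
  if (edge <= 0) stop("edge must be positive")
  if (is.null(box)) box <- rep(100 * edge, 3)
  s <- edge / sqrt(2)
  pts <- rbind(c(0, 0, 0), c(s, s, 0), c(s, 0, s), c(0, s, s))
  pts <- sweep(pts, 2, (box - s) / 2, "+")
  labeled_configuration(pts, labels, box)
}

#' Microheterogeneity series parameters
#'
#' The default concentration series used to demonstrate demixing
#' detection: slab configurations whose interface sharpens as the
#' cosolvent fraction grows, emulating concentration-strengthening
#' microheterogeneity (as observed for water-acetonitrile).  The
#' interface width follows `w(chi_s) = 0.65 - chi_s` nm over
#' `chi_s = 0.2, 0.3, 0.4, 0.5`.
#'
#' @return Data frame with columns `chi_s`, `p_w` (= 1 - chi_s) and
#'   `interface_width` (nm).
#' @export
demix_series_params <- function() {
  chi <- c(0.2, 0.3, 0.4, 0.5)
  data.frame(chi_s = chi, p_w = 1 - chi, interface_width = 0.65 - chi)
}
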