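#' Tetrahedrality of a tetrahedron
#'
#' Distortion measure of a tetrahedron with edge lengths
#' `l_1 ... l_6`:
#' \deqn{T = \sum_{i<j} \frac{(l_i - l_j)^2}{15\,\bar{l}^2}}
#' where the sum runs over the 15 unordered pairs of the 6 edges and
#' `l-bar` is their mean.  A perfectly regular tetrahedron has T = 0 and
#' increasing deviation from regularity increases T; the statistic is
#' invariant under vertex relabelling and under uniform scaling of all
#' edges.  Internally the pair sum is evaluated via the identity
#' `sum_{i<j}(l_i - l_j)^2 = 6 sum l^2 - (sum l)^2`.
#'
#' @param edge_lengths Numeric vector of 6 positive lengths, or an
#'   m x 6 matrix (one tetrahedron per row).
#' @return Tetrahedrality value(s), dimensionless and >= 0.
#' @export
#' @examples
#' tetrahedrality(rep(1, 6))                 # 0
#' tetrahedrality(c(1, 1, 1, 1, sqrt(2), sqrt(2)))
tetrahedrality <- function(edge_lengths) {
  l <- if (is.matrix(edge_lengths)) edge_lengths else
    matrix(edge_lengths, nrow = 1)
  if (ncol(l) != 6L) stop("expected 6 edge lengths per tetrahedron")
  if (any(!is.finite(l)) || any(l <= 0))
    stop("edge lengths must be positive and finite")
  s1 <- rowSums(l)
  s2 <- rowSums(l * l)
  lbar <- s1 / 6
  tval <- (6 * s2 - s1 * s1) / (15 * lbar * lbar)
  tval[tval < 0] <- 0  # guard round-off at the regular point
  if (is.matrix(edge_lengths)) tval else tval[[1]]
}

## Internal constructor shared by build_distributions() and tests:
## histogram a vector of T values with their classes on a common grid.
t_distribution_from_values <- function(tvals, k, bin_width) {
  if (!length(tvals)) stop("no tetrahedrality values")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  nb <- max(1L, ceiling(max(tvals) / bin_width - 1e-9))
  edges <- seq(0, nb * bin_width, by = bin_width)
  idx <- pmin(findInterval(tvals, edges, rightmost.closed = TRUE,
                           left.open = FALSE), nb)
  idx[idx < 1L] <- 1L
  counts <- sapply(4:0, function(kk)
    tabulate(idx[k == kk], nbins = nb))
  counts <- matrix(counts, nrow = nb,
                   dimnames = list(NULL, tet_class_names()))
  pooled <- rowSums(counts)
  structure(
    list(bin_edges = edges,
         counts_by_class = counts,
         pooled = pooled,
         n_values = c(colSums(counts), pooled = sum(pooled)),
         bin_width = bin_width),
    class = "t_distribution")
}

#' Tetrahedrality distributions per composition class
#'
#' Computes T for every tetrahedron of a tessellation and histograms the
#' values per composition class on a shared grid from 0 to the maximum
#' observed T (rounded up to a bin edge).  The pooled histogram -- all
#' classes clubbed together -- is the bin-wise sum of the five class
#' histograms.
#'
#' @param tess A `delaunay_tess` (or list of them, pooled).
#' @param labels Optional label override for a single tessellation.
#' @param bin_width Histogram bin width (dimensionless T units).  The
#'   default 0.05 resolves both the near-0 and the near-1.75 peak
#'   regions.
#' @return An object of class `t_distribution` with `bin_edges`,
#'   `counts_by_class` (bins x 5 matrix), `pooled`, `n_values`,
#'   `bin_width`.
#' @export
build_distributions <- function(tess, labels = NULL, bin_width = 0.05) {
  if (inherits(tess, "delaunay_tess")) tess <- list(tess)
  if (!length(tess)) stop("empty tessellation list")
  tvals <- unlist(lapply(tess, function(tt)
    tetrahedrality(tt$edge_lengths)))
  k <- unlist(lapply(tess, function(tt) classify_tetrahedra(tt, labels)))
  t_distribution_from_values(tvals, k, bin_width)
}

#' @export
print.t_distribution <- function(x, ...) {
  cat(sprintf(
    "t_distribution: %d bins of width %.3g, %d values (by class: %s)\n",
    length(x$pooled), x$bin_width, x$n_values[["pooled"]],
    paste(sprintf("%s=%d", tet_class_names(),
                  x$n_values[tet_class_names()]), collapse = ", ")))
  invisible(x)
}

#' Tidy data frame of a tetrahedrality distribution
#'
#' @param x A `t_distribution`.
#' @param ... Unused.
#' @return Data frame with `bin_left`, `bin_right`, one density column
#'   per class (`W4` ... `S4`) and `pooled`.  Densities integrate to 1
#'   over each non-empty histogram.
#' @export
as.data.frame.t_distribution <- function(x, ...) {
  nb <- length(x$pooled)
  dens <- function(cnt) {
    tot <- sum(cnt)
    if (tot > 0) cnt / (tot * x$bin_width) else rep(0, nb)
  }
  out <- data.frame(bin_left = x$bin_edges[-(nb + 1)],
                    bin_right = x$bin_edges[-1])
  for (cl in tet_class_names()) out[[cl]] <- dens(x$counts_by_class[, cl])
  out$pooled <- dens(x$pooled)
  out
}

#' Modes of a tetrahedrality distribution
#'
#' Locates local maxima of the (optionally smoothed) histogram whose
#' topographic prominence exceeds a threshold, for reporting uni- versus
#' bi-modality.  Prominence of a peak is its height minus the highest
#' valley separating it from a taller peak (or from the histogram edge),
#' and the threshold is expressed as a fraction of the tallest bin.
#'
#' @param dist A `t_distribution`.
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   (smoothed) bin height.  Default 0.05.
#' @param class Which histogram: `"pooled"` (default) or a class name.
#' @param smooth Apply a 3-bin moving-average before peak search
#'   (default `TRUE`).
#' @return Data frame with one row per mode, columns `t` (bin centre),
#'   `height` (density) and `prominence`, ordered by `t`.  May have zero
#'   rows.
#' @export
distribution_modes <- function(dist, min_prominence = 0.05,
                               class = "pooled", smooth = TRUE) {
  stopifnot(inherits(dist, "t_distribution"))
  counts <- if (class == "pooled") dist$pooled else
    dist$counts_by_class[, class]
  nb <- length(counts)
  if (nb < 3L) stop("histogram must have at least 3 bins")
  tot <- sum(counts)
  dens <- if (tot > 0) counts / (tot * dist$bin_width) else counts
  s <- if (smooth) {
    padded <- c(dens[1], dens, dens[nb])
    (padded[1:nb] + padded[2:(nb + 1)] + padded[3:(nb + 2)]) / 3
  } else dens
  centres <- (dist$bin_edges[-(nb + 1)] + dist$bin_edges[-1]) / 2
  peaks <- which(diff(sign(diff(c(-Inf, s, -Inf)))) == -2)
  if (!length(peaks) || max(s) <= 0)
    return(data.frame(t = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  ## topographic prominence: h minus the key saddle (the higher of the two
  ## lowest points on the paths to the nearest taller bin on each side)
  prom <- vapply(peaks, function(p) {
    h <- s[p]
    saddle <- function(idx) {  # idx ordered walking away from the peak
      v <- h
      for (q in idx) {
        if (s[q] > h) return(v)  # reached taller ground
        v <- min(v, s[q])
      }
      -Inf  # no taller bin on this side
    }
    sl <- saddle(rev(seq_len(p - 1)))
    sr <- saddle(if (p < nb) (p + 1):nb else integer(0))
    key <- max(sl, sr)
    if (is.infinite(key)) h - min(s) else h - key
  }, numeric(1))
  keep <- prom >= min_prominence * max(s)
  data.frame(t = centres[peaks[keep]], height = dens[peaks[keep]],
             prominence = prom[keep])
}
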