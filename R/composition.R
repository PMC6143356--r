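#' Classify tetrahedra by water/cosolvent vertex composition
#'
#' Each tetrahedron falls in one of five classes according to the number
#' k of its vertices carrying the water label `W`: `W4` (k = 4), `W3S`,
#' `W2S2`, `WS3`, `S4` (k = 0).  Classification depends only on the
#' multiset of vertex labels, not their order; a vertex that is a
#' periodic image carries the label of its primary atom.
#'
#' @param tess A `delaunay_tess`, or an m x 4 matrix of atom indices.
#' @param labels Per-atom label vector (`"W"`/`"S"`); defaults to the
#'   labels stored on the tessellation.
#' @return Integer vector of k values in `0:4`, one per tetrahedron.
#' @export
#' @examples
#' classify_tetrahedra(matrix(1:4, 1), labels = c("W", "W", "S", "S"))
classify_tetrahedra <- function(tess, labels = NULL) {
  ids <- if (is.matrix(tess)) tess else tess$vertex_ids
  if (is.null(labels)) labels <- tess$labels
  if (any(ids < 1L) || any(ids > length(labels)))
    stop("vertex id outside the label vector")
  isw <- labels == "W"
  as.integer(matrix(isw[ids], ncol = 4) %*% rep(1L, 4))
}

#' Composition-class counts
#'
#' Counts of the five tetrahedron composition classes for one frame or a
#' pool of frames of a single system, together with the heavy-atom
#' bookkeeping needed by the binomial null: `n_w` (water oxygens) and
#' `n_T` (all heavy atoms).
#'
#' @param n_by_class Named integer vector with entries `W4`, `W3S`,
#'   `W2S2`, `WS3`, `S4` (missing names default to 0).
#' @param n_w Water heavy-atom count.
#' @param n_T Total heavy-atom count.
#' @param frames_pooled Number of frames aggregated.
#' @return An object of class `composition_counts`.
#' @export
composition_counts <- function(n_by_class, n_w, n_T, frames_pooled = 1L) {
  full <- setNames(numeric(5), tet_class_names())
  if (is.null(names(n_by_class)) && length(n_by_class) == 5L)
    names(n_by_class) <- tet_class_names()
  if (!all(names(n_by_class) %in% names(full)))
    stop("unknown class name in n_by_class")
  full[names(n_by_class)] <- n_by_class
  if (any(full < 0)) stop("class counts must be non-negative")
  if (n_w < 0 || n_T < n_w) stop("need 0 <= n_w <= n_T")
  structure(list(n_by_class = full, n_w = n_w, n_T = n_T,
                 frames_pooled = as.integer(frames_pooled)),
            class = "composition_counts")
}

#' @export
print.composition_counts <- function(x, ...) {
  cat(sprintf("composition_counts (%d frame%s, n_w = %d, n_T = %d):\n",
              x$frames_pooled, if (x$frames_pooled == 1L) "" else "s",
              x$n_w, x$n_T))
  print(x$n_by_class)
  invisible(x)
}

#' Count composition classes in a tessellation
#'
#' @param tess A `delaunay_tess`.
#' @param labels Optional label override (defaults to the tessellation's).
#' @return A [composition_counts()] for one frame.
#' @export
count_composition <- function(tess, labels = NULL) {
  if (is.null(labels)) labels <- tess$labels
  k <- classify_tetrahedra(tess, labels)
  tab <- tabulate(k + 1L, nbins = 5L)  # index 1 ... 5 <-> k = 0 ... 4
  composition_counts(setNames(rev(tab), tet_class_names()),
                     n_w = sum(labels == "W"), n_T = length(labels))
}

#' Binomial expected class probability
#'
#' Under random mixing the probability that a tetrahedron has k
#' water-labelled vertices is binomial with 4 trials at the heavy-atom
#' water fraction `p_w`: `C(4,k) p_w^k (1-p_w)^(4-k)`.  The five values
#' over k sum to 1 for any `p_w`.
#'
#' @param k Number of water vertices, in `0:4` (vectorised).
#' @param p_w Heavy-atom water fraction in `[0, 1]`.
#' @return Probability (same length as `k`).
#' @export
#' @examples
#' expected_probability(4, 0.5)  # (1/2)^4 = 0.0625
expected_probability <- function(k, p_w) {
  if (any(k != round(k)) || any(k < 0) || any(k > 4))
    stop("k must be an integer in [0, 4]")
  if (any(p_w < 0) || any(p_w > 1)) stop("p_w must lie in [0, 1]")
  dbinom(k, size = 4, prob = p_w)
}

#' Log-odds abundance of composition classes
#'
#' Compares the observed class probabilities `P_obs = n_i / sum(n_i)`
#' against the binomial random-mixing expectation at
#' `p_w = n_w / n_T`, reporting both the plain ratio
#' `P_obs / P_exp` and the log-odds `f = log10(ratio)`.  Positive `f`
#' marks a class occurring more often than random mixing predicts.
#' Classes with `P_obs = 0` or `P_exp = 0` (e.g. mixed classes in a pure
#' liquid, where `p_w` is 0 or 1) carry `NA` for `f` -- an explicit
#' undefined marker, never a silent 0.
#'
#' @param counts A [composition_counts()].
#' @return A data frame of class `abundance_result` with columns
#'   `class`, `k`, `n`, `p_obs`, `p_exp`, `ratio`, `f`, and attributes
#'   `p_w` and `frames_pooled`.
#' @export
#' @examples
#' cc <- composition_counts(c(W4 = 16, S4 = 16), n_w = 50, n_T = 100)
#' abundance(cc)  # ratio_W4 = 8, f_W4 = log10(8)
abundance <- function(counts) {
  stopifnot(inherits(counts, "composition_counts"))
  total <- sum(counts$n_by_class)
  if (total <= 0) stop("no simplices: cannot compute abundance")
  k <- 4:0  # class order W4 ... S4
  n <- as.numeric(counts$n_by_class[tet_class_names()])
  p_w <- counts$n_w / counts$n_T
  p_obs <- n / total
  p_exp <- expected_probability(k, p_w)
  ratio <- ifelse(p_exp > 0, p_obs / p_exp,
                  ifelse(p_obs > 0, Inf, NaN))
  f <- ifelse(p_obs > 0 & p_exp > 0, log10(p_obs / p_exp), NA_real_)
  out <- data.frame(class = tet_class_names(), k = k, n = n,
                    p_obs = p_obs, p_exp = p_exp, ratio = ratio, f = f,
                    stringsAsFactors = FALSE)
  attr(out, "p_w") <- p_w
  attr(out, "frames_pooled") <- counts$frames_pooled
  class(out) <- c("abundance_result", "data.frame")
  out
}

#' @export
print.abundance_result <- function(x, digits = 4, ...) {
  pw <- attr(x, "p_w")
  fp <- attr(x, "frames_pooled")
  if (!is.null(pw) && !is.null(fp))
    cat(sprintf("abundance_result (p_w = %.4f, %d frame%s pooled):\n",
                pw, fp, if (fp == 1L) "" else "s"))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
`[.abundance_result` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' Pool composition counts across frames
#'
#' Counts are summed before normalisation (the abundance statistic is
#' computed once from the pooled counts, not averaged over per-frame
#' statistics).  In the default `"strict"` mode every entry must report
#' identical `n_w` and `n_T`: frames of different systems (different
#' concentrations) must not be pooled.  Mode `"aggregate"` instead sums
#' `n_w` and `n_T` alongside the class counts; this is appropriate for
#' label-resampling null studies where the per-frame water count is
#' itself random.
#'
#' @param counts_list List of [composition_counts()].
#' @param match `"strict"` (default) or `"aggregate"`.
#' @return A pooled [composition_counts()].
#' @export
pool_counts <- function(counts_list, match = c("strict", "aggregate")) {
  match <- match.arg(match)
  if (!length(counts_list)) stop("nothing to pool")
  stopifnot(all(vapply(counts_list, inherits, TRUE, "composition_counts")))
  nw <- vapply(counts_list, function(x) x$n_w, numeric(1))
  nT <- vapply(counts_list, function(x) x$n_T, numeric(1))
  if (match == "strict") {
    if (length(unique(nw)) != 1L || length(unique(nT)) != 1L)
      stop("refusing to pool counts with mismatched n_w/n_T: ",
           "frames appear to come from different systems ",
           "(use match = \"aggregate\" for label-resampled nulls)")
    n_w <- nw[1]; n_T <- nT[1]
  } else {
    n_w <- sum(nw); n_T <- sum(nT)
  }
  nbc <- Reduce(`+`, lapply(counts_list, function(x) x$n_by_class))
  composition_counts(nbc, n_w = n_w, n_T = n_T,
                     frames_pooled =
                       sum(vapply(counts_list,
                                  function(x) x$frames_pooled, integer(1))))
}
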