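#' Full statistical-geometry analysis of one system
#'
#' Tessellates every frame, pools the composition counts, and computes
#' the log-odds abundance table and the tetrahedrality distributions.
#' Frames with identical atom bookkeeping (`n_w`, `n_T`) are pooled
#' strictly; when labels were resampled per frame (so `n_w` varies) the
#' counts are aggregated and `p_w` becomes the across-frame atom
#' fraction -- the choice taken is recorded in the diagnostics.
#'
#' @param x A [labeled_configuration()], a list of them, or a file path
#'   (dispatched through [read_frames()]).
#' @param ... For a file path: passed to [read_frames()] (`format`,
#'   `spec`, `box`, `chi_s`).
#' @param frame_stride Keep every `stride`-th frame (applied after
#'   reading when `x` is in-memory).
#' @param buffer_width Ghost-slab width (nm); default `min(box)/4`.
#' @param bin_width Tetrahedrality histogram bin width; default 0.05.
#' @return An object of class `solvtess_result`: list with `counts`
#'   ([composition_counts()]), `abundance` ([abundance()] table),
#'   `t_distribution`, `chi_s` and `diagnostics` (frames processed,
#'   simplices per frame, degenerate-simplex count, `p_w`, pooling
#'   mode).
#' @export
#' @examples
#' frames <- generate_trajectory(3, "ideal", n_points = 120, p_w = 0.5,
#'                               seed = 7)
#' res <- run_single(frames)
#' res$abundance
run_single <- function(x, ..., frame_stride = 1L, buffer_width = NULL,
                       bin_width = 0.05) {
  frames <- if (is.character(x)) {
    read_frames(x, ..., stride = frame_stride)
  } else if (inherits(x, "labeled_configuration")) {
    list(x)
  } else if (is.list(x)) {
    x[seq(1L, length(x), by = max(1L, frame_stride))]
  } else stop("x must be a configuration, a list of them, or a path")
  if (!length(frames)) stop("no frames to analyse")
  stopifnot(all(vapply(frames, inherits, TRUE, "labeled_configuration")))

  tess <- lapply(frames, tessellate, buffer_width = buffer_width)
  counts <- lapply(tess, count_composition)
  nw <- vapply(counts, function(cc) cc$n_w, numeric(1))
  nT <- vapply(counts, function(cc) cc$n_T, numeric(1))
  mode <- if (length(unique(nw)) == 1L && length(unique(nT)) == 1L)
    "strict" else "aggregate"
  pooled <- pool_counts(counts, match = mode)
  ab <- abundance(pooled)
  td <- build_distributions(tess, bin_width = bin_width)
  chi <- unique(vapply(frames, function(fr)
    if (is.null(fr$chi_s)) NA_real_ else fr$chi_s, numeric(1)))
  structure(
    list(counts = pooled, abundance = ab, t_distribution = td,
         chi_s = if (length(chi) == 1L) chi else NA_real_,
         diagnostics = list(
           frames_processed = length(frames),
           simplices_per_frame = vapply(
             tess, function(tt) tt$diagnostics$n_simplices, numeric(1)),
           degenerate_simplices = sum(vapply(
             tess, function(tt) tt$diagnostics$n_degenerate, numeric(1))),
           duplicate_simplices = sum(vapply(
             tess, function(tt) tt$diagnostics$n_duplicates, numeric(1))),
           p_w = attr(ab, "p_w"), pooling = mode)),
    class = "solvtess_result")
}

#' @export
print.solvtess_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "solvtess_result: %d frame(s), %d simplices pooled (p_w = %.4f, %s pooling)\n",
    d$frames_processed, sum(x$counts$n_by_class), d$p_w, d$pooling))
  print(x$abundance)
  invisible(x)
}

#' Concentration-series analysis
#'
#' Runs [run_single()] for every entry of a series and assembles the
#' long-format table behind abundance-versus-concentration plots.
#'
#' @param inputs Named or unnamed list; each entry is either a list of
#'   [labeled_configuration()] frames (with `chi_s` metadata) or a list
#'   with elements `frames`/`path` plus `chi_s`.
#' @param chi_s Optional numeric vector overriding the per-entry mole
#'   fractions; must be unique.
#' @param ... Passed to [run_single()].
#' @return An object of class `solvtess_series`: list with `table`
#'   (long-format data frame: `chi_s`, `class`, `k`, `n`, `p_obs`,
#'   `p_exp`, `ratio`, `f`) and `results` (per-concentration
#'   `solvtess_result`s, named by `chi_s`).
#' @export
run_series <- function(inputs, chi_s = NULL, ...) {
  if (length(inputs) < 2L)
    stop("a concentration series needs at least 2 inputs")
  get_chi <- function(entry) {
    if (inherits(entry, "labeled_configuration")) return(entry$chi_s)
    if (!is.null(entry$chi_s)) return(entry$chi_s)
    if (is.list(entry) && length(entry) &&
        inherits(entry[[1]], "labeled_configuration"))
      return(entry[[1]]$chi_s)
    NA_real_
  }
  if (is.null(chi_s)) chi_s <- vapply(inputs, get_chi, numeric(1))
  if (any(is.na(chi_s)))
    stop("chi_s missing for at least one series entry")
  if (anyDuplicated(chi_s))
    stop("duplicate chi_s values in series: ",
         paste(chi_s[duplicated(chi_s)], collapse = ", "))
  results <- lapply(seq_along(inputs), function(i) {
    entry <- inputs[[i]]
    frames <- if (inherits(entry, "labeled_configuration")) entry
      else if (!is.null(entry$frames)) entry$frames
      else if (!is.null(entry$path)) entry$path
      else entry
    run_single(frames, ...)
  })
  names(results) <- as.character(chi_s)
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    ab <- results[[i]]$abundance
    cbind(chi_s = chi_s[i], as.data.frame(ab))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab[order(tab$chi_s, -tab$k), ],
                 results = results),
            class = "solvtess_series")
}

#' @export
print.solvtess_series <- function(x, ...) {
  cat(sprintf("solvtess_series over %d concentrations:\n",
              length(x$results)))
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write result tables
#'
#' Writes `abundance.tsv` (one row per class), `tdist.tsv` (histogram
#' densities per class and pooled) and `result.json` (counts, modes and
#' run diagnostics) into a directory.  Output is deterministic: no
#' timestamps, so identical inputs reproduce identical files.
#'
#' @param result A `solvtess_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_result_tables <- function(result, dir) {
  stopifnot(inherits(result, "solvtess_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "abundance.tsv")
  write.table(as.data.frame(result$abundance), f1, sep = "\t",
              quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "tdist.tsv")
  write.table(as.data.frame(result$t_distribution), f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir, "result.json")
  modes <- distribution_modes(result$t_distribution)
  jsonlite::write_json(
    list(chi_s = result$chi_s,
         p_w = result$diagnostics$p_w,
         frames_pooled = result$counts$frames_pooled,
         n_by_class = as.list(result$counts$n_by_class),
         degenerate_simplices = result$diagnostics$degenerate_simplices,
         pooling = result$diagnostics$pooling,
         modes = modes,
         package_version = as.character(utils::packageVersion("solvtess"))),
    f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
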