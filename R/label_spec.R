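#' Atom label specification
#'
#' Rules mapping atoms of a coordinate file to the two analysis labels:
#' `W` (water oxygen atoms) and `S` (cosolvent heavy atoms).  A selector
#' matches an atom when its residue name matches one of the selector's
#' residue patterns (or any residue, when `residues` is `NULL`) and its
#' atom name matches one of the atom patterns (or any, when `atoms` is
#' `NULL`).  Patterns are glob-style: `*` matches any run of characters.
#' Hydrogens are excluded before selection and can never be labelled;
#' atoms matched by neither selector are dropped and counted.
#'
#' @param water Selector for water oxygen atoms, a list with optional
#'   character vectors `residues` and `atoms`.
#' @param solvent Selector for cosolvent heavy atoms, same shape.
#' @return An object of class `label_spec`.
#' @export
#' @examples
#' label_spec(water = list(residues = "SOL", atoms = "OW*"),
#'            solvent = list(residues = "ACN"))
label_spec <- function(water, solvent) {
  norm <- function(sel, who) {
    if (!is.list(sel)) stop(who, " selector must be a list")
    sel <- sel[intersect(names(sel), c("residues", "atoms"))]
    if (!length(sel))
      stop(who, " selector needs at least one of residues/atoms")
    sel
  }
  structure(list(water = norm(water, "water"),
                 solvent = norm(solvent, "solvent")),
            class = "label_spec")
}

#' Default label specification for common water/cosolvent topologies
#'
#' Water: the oxygen atom of the usual water residues (SOL, WAT, HOH,
#' TIP3 ...).  Cosolvent: every heavy atom of the common acetonitrile
#' and DMSO residue names, plus the `W`/`S` single-letter names written
#' by the package's own synthetic output.
#'
#' @return A [label_spec()].
#' @export
default_label_spec <- function() {
  label_spec(
    water = list(residues = c("SOL", "WAT", "HOH", "TIP3", "TIP4", "SPC",
                              "W"),
                 atoms = c("OW*", "O", "OH2", "W")),
    solvent = list(residues = c("ACN", "MeCN", "ACT", "CH3CN", "DMS",
                                "DMSO", "POS", "S")))
}

glob_to_regex <- function(p)
  paste0("^", gsub("\\*", ".*", gsub("([.\\\\+?^$(){}\\[\\]|])", "\\\\\\1",
                                     p)), "$")

match_selector <- function(sel, resname, atomname) {
  hit <- rep(TRUE, length(resname))
  if (!is.null(sel$residues)) {
    rx <- paste(vapply(sel$residues, glob_to_regex, ""), collapse = "|")
    hit <- hit & grepl(rx, resname, ignore.case = TRUE)
  }
  if (!is.null(sel$atoms)) {
    rx <- paste(vapply(sel$atoms, glob_to_regex, ""), collapse = "|")
    hit <- hit & grepl(rx, atomname, ignore.case = TRUE)
  }
  hit
}

## Hydrogen heuristic: element H when known, else atom names like
## H, HW1, 1H2, 2HB ...
is_hydrogen <- function(atomname, element = NULL) {
  byname <- grepl("^[0-9]*H", toupper(trimws(atomname)))
  if (!is.null(element)) {
    el <- toupper(trimws(element))
    known <- !is.na(el) & nzchar(el)
    byname[known] <- el[known] == "H"
  }
  byname
}

#' Apply a label specification to one parsed frame
#'
#' @param frame List with `resname`, `atomname`, `coords`, `box` and
#'   optionally `element` (as produced by the frame readers).
#' @param spec A [label_spec()].
#' @param frame_index Frame ordinal to record.
#' @param chi_s Optional mole-fraction metadata.
#' @return A [labeled_configuration()]; the number of dropped
#'   (unmatched, non-hydrogen) atoms is attached as attribute
#'   `n_excluded`.
#' @export
apply_label_spec <- function(frame, spec, frame_index = 1L,
                             chi_s = NA_real_) {
  stopifnot(inherits(spec, "label_spec"))
  hyd <- is_hydrogen(frame$atomname, frame$element)
  w <- match_selector(spec$water, frame$resname, frame$atomname) & !hyd
  s <- match_selector(spec$solvent, frame$resname, frame$atomname) & !hyd
  if (any(w & s))
    stop("water and solvent selectors overlap on ",
         sum(w & s), " atom(s), e.g. ",
         frame$resname[which(w & s)[1]], "/",
         frame$atomname[which(w & s)[1]])
  if (!any(w)) stop("water selector matched zero atoms")
  if (!any(s)) stop("solvent selector matched zero atoms")
  keep <- w | s
  labels <- ifelse(w[keep], "W", "S")
  lc <- labeled_configuration(frame$coords[keep, , drop = FALSE], labels,
                              frame$box, frame_index = frame_index,
                              chi_s = chi_s)
  attr(lc, "n_excluded") <- sum(!keep & !hyd)
  lc
}

#' Read a label specification from a key/value text file
#'
#' Lines of the form `water.residues = SOL WAT`, `water.atoms = OW*`,
#' `solvent.residues = ACN`; values are whitespace- or comma-separated
#' patterns, `#` starts a comment.
#'
#' @param path File path.
#' @return A [label_spec()].
#' @export
read_label_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([a-z]+)\\.(residues|atoms)\\s*=\\s*(.*)$",
                                  lines))
  sels <- list(water = list(), solvent = list())
  for (j in seq_along(kv)) {
    m <- kv[[j]]
    if (length(m) != 4L)
      stop("unparseable label-spec line: ", lines[[j]])
    who <- m[2]; what <- m[3]
    if (!who %in% c("water", "solvent"))
      stop("unknown selector '", who, "' in label spec")
    sels[[who]][[what]] <- strsplit(m[4], "[,[:space:]]+")[[1]]
  }
  label_spec(water = sels$water, solvent = sels$solvent)
}
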