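#' Read multi-frame coordinate files into labelled configurations
#'
#' Supported formats: GROMACS `.gro` (multi-frame, box line required),
#' PDB (multi-MODEL, `CRYST1` required; parsed through \pkg{bio3d}) and
#' plain XYZ (boxless: orthorhombic box lengths must be supplied via
#' `box`).  Coordinates are wrapped into the primary cell and the label
#' specification is applied to every frame.  GRO and XYZ coordinates are
#' taken as nm; PDB Angstroms are converted to nm.
#'
#' @param path File path.
#' @param format `"gro"`, `"pdb"`, `"xyz"` or `"auto"` (by extension).
#' @param spec A [label_spec()]; default [default_label_spec()].
#' @param box Length-3 box (nm), required for XYZ, ignored otherwise.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @param chi_s Optional mole-fraction metadata attached to each frame.
#' @return List of [labeled_configuration()] in file order.
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                        spec = default_label_spec(), box = NULL,
                        stride = 1L, chi_s = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (stride < 1L) stop("stride must be >= 1")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", ent = "pdb",
                     xyz = "xyz",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  frames <- switch(format,
                   gro = read_gro_frames(path),
                   pdb = read_pdb_frames(path),
                   xyz = read_xyz_frames(path, box))
  frames <- frames[seq(1L, length(frames), by = stride)]
  lapply(seq_along(frames), function(i)
    apply_label_spec(frames[[i]], spec, frame_index = i, chi_s = chi_s))
}

## ---- GRO ----------------------------------------------------------------

read_gro_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L)
      stop("GRO format error at line ", i + 1L,
           ": expected an atom count, got '", lines[i + 1L], "'")
    if (i + 1L + nat + 1L > length(lines))
      stop("GRO format error: truncated frame starting at line ", i)
    at <- lines[(i + 2L):(i + 1L + nat)]
    coords <- cbind(as.numeric(substr(at, 21, 28)),
                    as.numeric(substr(at, 29, 36)),
                    as.numeric(substr(at, 37, 44)))
    if (any(is.na(coords)))
      stop("GRO format error: unparseable coordinates near line ",
           i + 1L + which(is.na(coords[, 1]))[1])
    boxline <- strsplit(trimws(lines[i + 1L + nat + 1L]), "\\s+")[[1]]
    bv <- suppressWarnings(as.numeric(boxline))
    if (length(bv) < 3L || any(is.na(bv[1:3])))
      stop("GRO format error: missing box line for frame at line ", i)
    if (length(bv) > 3L && any(abs(bv[-(1:3)]) > 1e-9))
      stop("triclinic boxes are not supported (off-diagonal box ",
           "components present)")
    frames[[length(frames) + 1L]] <-
      list(resname = trimws(substr(at, 6, 10)),
           atomname = trimws(substr(at, 11, 15)),
           coords = coords, box = bv[1:3])
    i <- i + 1L + nat + 2L
  }
  if (!length(frames)) stop("no frames found in GRO file ", path)
  frames
}

#' Write a labelled configuration as a GRO frame
#'
#' W atoms are written as residue `SOL`, atom `OW`; S atoms as residue
#' `POS`, atom `S1` (one residue per atom).  [default_label_spec()]
#' recovers the labels on re-read.  Appending frames to one file builds
#' a multi-frame trajectory.
#'
#' @param config A [labeled_configuration()].
#' @param path Output path.
#' @param append Append as an extra frame (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_gro <- function(config, path, append = FALSE) {
  stopifnot(inherits(config, "labeled_configuration"))
  n <- nrow(config$coords)
  res <- ifelse(config$labels == "W", "SOL", "POS")
  atm <- ifelse(config$labels == "W", "OW", "S1")
  lines <- c(
    sprintf("solvtess frame %d", config$frame_index),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            seq_len(n) %% 100000L, res, atm, seq_len(n) %% 100000L,
            config$coords[, 1], config$coords[, 2], config$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2],
            config$box[3]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## ---- XYZ ----------------------------------------------------------------

read_xyz_frames <- function(path, box) {
  if (is.null(box))
    stop("XYZ files carry no box information: supply box lengths ",
         "(nm) via the 'box' argument")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0))
    stop("box must be 3 positive lengths (nm)")
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("XYZ format error at line ", i, ": expected an atom count")
    if (i + 1L + nat > length(lines))
      stop("XYZ format error: truncated frame starting at line ", i)
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad))
      stop("XYZ format error at line ", i + 1L + bad[1],
           ": expected 'name x y z'")
    nm <- vapply(toks, `[[`, "", 1L)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]),
                       numeric(3)))
    if (any(is.na(coords)))
      stop("XYZ format error: non-numeric coordinate near line ", i + 2L)
    frames[[length(frames) + 1L]] <-
      list(resname = nm, atomname = nm, coords = coords, box = box)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames found in XYZ file ", path)
  frames
}

#' Write a labelled configuration as an XYZ frame
#'
#' Atoms are named by their label (`W`/`S`), which
#' [default_label_spec()] maps back on re-read.  The box is not stored
#' in the file (XYZ has no box field) and must be re-supplied on read.
#'
#' @inheritParams write_gro
#' @export
write_xyz <- function(config, path, append = FALSE) {
  stopifnot(inherits(config, "labeled_configuration"))
  n <- nrow(config$coords)
  lines <- c(sprintf("%d", n),
             sprintf("solvtess frame %d box %.5f %.5f %.5f",
                     config$frame_index, config$box[1], config$box[2],
                     config$box[3]),
             sprintf("%-2s %12.6f %12.6f %12.6f", config$labels,
                     config$coords[, 1], config$coords[, 2],
                     config$coords[, 3]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## ---- PDB (via bio3d) ----------------------------------------------------

read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  ## bio3d does not expose CRYST1; fetch the box from the raw file.
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(cl))
    stop("PDB file has no CRYST1 record: box information is required ",
         "for periodic tessellation")
  abc <- suppressWarnings(as.numeric(c(substr(cl[1], 7, 15),
                                       substr(cl[1], 16, 24),
                                       substr(cl[1], 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(cl[1], 34, 40),
                                       substr(cl[1], 41, 47),
                                       substr(cl[1], 48, 54))))
  if (any(is.na(abc)) || any(abc <= 0))
    stop("unparseable CRYST1 record: ", cl[1])
  if (any(!is.na(ang)) && any(abs(ang[!is.na(ang)] - 90) > 1e-6))
    stop("triclinic boxes are not supported (CRYST1 angles != 90)")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(fr) {
    coords <- matrix(xyz[fr, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
    list(resname = pdb$atom$resid, atomname = pdb$atom$elety,
         element = pdb$atom$elesy, coords = coords, box = abc / 10)
  })
}
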