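# Inline GRO fixtures in GROMACS fixed-width layout (coordinates in nm).
gro_water3 <- c(
  "three waters",
  "    9",
  "    1SOL    OW    1   0.100   0.100   0.100",
  "    1SOL   HW1    2   0.190   0.100   0.100",
  "    1SOL   HW2    3   0.100   0.190   0.100",
  "    2SOL    OW    4   0.500   0.500   0.500",
  "    2SOL   HW1    5   0.590   0.500   0.500",
  "    2SOL   HW2    6   0.500   0.590   0.500",
  "    3SOL    OW    7   0.900   0.900   0.900",
  "    3SOL   HW1    8   0.990   0.900   0.900",
  "    3SOL   HW2    9   0.900   0.990   0.900",
  "   2.00000   2.00000   2.00000")

# 2 waters + 1 acetonitrile (heavy atoms CH3 carbon, nitrile C, N)
gro_mecn <- c(
  "water + MeCN",
  "   11",
  "    1SOL    OW    1   0.100   0.100   0.100",
  "    1SOL   HW1    2   0.190   0.100   0.100",
  "    1SOL   HW2    3   0.100   0.190   0.100",
  "    2SOL    OW    4   0.600   0.600   0.600",
  "    2SOL   HW1    5   0.690   0.600   0.600",
  "    2SOL   HW2    6   0.600   0.690   0.600",
  "    3ACN    C1    7   1.200   1.200   1.200",
  "    3ACN   H11    8   1.260   1.260   1.260",
  "    3ACN    C2    9   1.340   1.200   1.200",
  "    3ACN     N   10   1.460   1.200   1.200",
  "    3ACN   H12   11   1.200   1.260   1.140",
  "   2.00000   2.00000   2.00000")

# 1 water + 1 DMSO: heavy atoms S, O and two methyl carbons
gro_dmso <- c(
  "water + DMSO",
  "    9",
  "    1SOL    OW    1   0.100   0.100   0.100",
  "    1SOL   HW1    2   0.190   0.100   0.100",
  "    1SOL   HW2    3   0.100   0.190   0.100",
  "    2DMS     S    4   1.000   1.000   1.000",
  "    2DMS     O    5   1.000   1.000   1.150",
  "    2DMS    C1    6   1.150   1.000   0.930",
  "    2DMS    H1    7   1.200   1.050   0.980",
  "    2DMS    C2    8   0.850   1.000   0.930",
  "    2DMS    H2    9   0.800   1.050   0.980",
  "   2.00000   2.00000   2.00000")

test_that("a pure-water frame errors on the empty solvent selector", {
  f <- write_lines_tmp(gro_water3, ".gro")
  expect_error(read_frames(f), "solvent selector matched zero atoms")
})

test_that("mixed water/MeCN frame books 2 W and 3 S heavy atoms", {
  f <- write_lines_tmp(gro_mecn, ".gro")
  lc <- read_frames(f)[[1]]
  expect_equal(nrow(lc$coords), 5L)
  expect_equal(lc$n_w, 2L)
  expect_equal(lc$n_s, 3L)
  expect_equal(lc$box, c(2, 2, 2))
})

test_that("one DMSO molecule contributes 4 S atoms (2 C, O, S)", {
  f <- write_lines_tmp(gro_dmso, ".gro")
  lc <- read_frames(f)[[1]]
  expect_equal(lc$n_w, 1L)
  expect_equal(lc$n_s, 4L)
})

test_that("GRO round trip preserves labels and format-precision coords", {
  lc <- generate_ideal(40, 0.5, seed = 6)
  f <- tempfile(fileext = ".gro")
  write_gro(lc, f)
  lc2 <- read_frames(f)[[1]]
  expect_identical(lc2$labels, lc$labels)
  expect_lt(max(abs(lc2$coords - lc$coords)), 5.01e-4)  # 3 decimals in nm
  expect_equal(lc2$box, lc$box, tolerance = 1e-5)
  # multi-frame append preserves order
  write_gro(lc, f)
  lc3 <- generate_ideal(40, 0.5, seed = 8)
  write_gro(lc3, f, append = TRUE)
  frames <- read_frames(f)
  expect_length(frames, 2L)
  expect_lt(max(abs(frames[[2]]$coords - lc3$coords)), 5.01e-4)
})

test_that("XYZ requires a box and round-trips labels and coordinates", {
  lc <- generate_ideal(30, 0.4, seed = 19)
  f <- tempfile(fileext = ".xyz")
  write_xyz(lc, f)
  expect_error(read_frames(f), "box")
  lc2 <- read_frames(f, box = lc$box)[[1]]
  expect_identical(lc2$labels, lc$labels)
  expect_lt(max(abs(lc2$coords - lc$coords)), 1e-6)
})

test_that("frame stride subsamples a multi-frame file", {
  lc <- generate_ideal(20, 0.5, seed = 2)
  f <- tempfile(fileext = ".gro")
  write_gro(lc, f)
  for (i in 1:4) write_gro(lc, f, append = TRUE)  # 5 frames total
  expect_length(read_frames(f), 5L)
  expect_length(read_frames(f, stride = 2), 3L)
})

test_that("multi-model PDB frames are read with CRYST1 box in nm", {
  pdb <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "MODEL        1",
    "ATOM      1  OW  SOL A   1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  HW1 SOL A   1       1.900   2.000   3.000  1.00  0.00           H",
    "ATOM      3  C1  ACN A   2       5.000   5.000   5.000  1.00  0.00           C",
    "ATOM      4  C2  ACN A   2       6.400   5.000   5.000  1.00  0.00           C",
    "ATOM      5  N   ACN A   2       7.600   5.000   5.000  1.00  0.00           N",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  OW  SOL A   1       1.100   2.100   3.100  1.00  0.00           O",
    "ATOM      2  HW1 SOL A   1       2.000   2.100   3.100  1.00  0.00           H",
    "ATOM      3  C1  ACN A   2       5.100   5.100   5.100  1.00  0.00           C",
    "ATOM      4  C2  ACN A   2       6.500   5.100   5.100  1.00  0.00           C",
    "ATOM      5  N   ACN A   2       7.700   5.100   5.100  1.00  0.00           N",
    "ENDMDL",
    "END")
  f <- write_lines_tmp(pdb, ".pdb")
  frames <- read_frames(f)
  expect_length(frames, 2L)
  lc <- frames[[1]]
  expect_equal(lc$box, c(2, 2, 2))
  expect_equal(lc$n_w, 1L)
  expect_equal(lc$n_s, 3L)
  expect_equal(lc$coords[1, ], c(0.1, 0.2, 0.3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(frames[[2]]$coords[1, ], c(0.11, 0.21, 0.31),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("format errors are reported with context", {
  bad <- c("title", "  not-a-number", "junk")
  expect_error(read_frames(write_lines_tmp(bad, ".gro")), "atom count")
  tric <- gro_water3
  tric[length(tric)] <- "   2.00000   2.00000   2.00000   0.50000   0.00000   0.00000"
  expect_error(read_frames(write_lines_tmp(tric, ".gro")), "triclinic")
  trunc <- gro_water3[1:5]
  expect_error(read_frames(write_lines_tmp(trunc, ".gro")), "truncated")
  expect_error(read_frames("/nonexistent/file.gro"), "no such file")
})

test_that("selectors can be loaded from a key/value text file", {
  f <- write_lines_tmp(c(
    "# labelling for water/MeCN",
    "water.residues = SOL TIP3",
    "water.atoms = OW*",
    "solvent.residues = ACN, MECN"), ".cfg")
  spec <- read_label_spec(f)
  expect_s3_class(spec, "label_spec")
  expect_equal(spec$water$residues, c("SOL", "TIP3"))
  expect_equal(spec$solvent$residues, c("ACN", "MECN"))
  g <- write_lines_tmp(gro_mecn, ".gro")
  lc <- read_frames(g, spec = spec)[[1]]
  expect_equal(lc$n_w, 2L)
  expect_equal(lc$n_s, 3L)
})

test_that("mole fraction follows molecule counts", {
  expect_equal(mole_fraction(100, 0), 0)
  expect_equal(mole_fraction(0, 100), 1)
  expect_equal(mole_fraction(50, 50), 0.5)
  expect_error(mole_fraction(0, 0), "positive")
  expect_error(mole_fraction(-1, 5), "non-negative")
})

test_that("overlapping selectors are refused", {
  f <- write_lines_tmp(gro_mecn, ".gro")
  spec <- label_spec(water = list(residues = c("SOL", "ACN")),
                     solvent = list(residues = "ACN"))
  expect_error(read_frames(f, spec = spec), "overlap")
})
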