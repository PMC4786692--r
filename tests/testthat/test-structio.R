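# Structure reading, writing and terminal C-alpha extraction.

make_fixture_pdb <- function(path, cell = FALSE, blank_lines = FALSE) {
  lines <- character(0)
  if (cell)
    lines <- "CRYST1   61.221  147.128  175.171  90.00  90.00  90.00 I 2 2 2      8"
  atoms <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   3.000   4.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       5.000   6.000   7.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       8.000   9.000  10.000  1.00  0.00           C",
    "TER",
    "ATOM      5  CA  ALA B  10      -1.000  -2.000  -3.000  1.00  0.00           C",
    "TER", "END")
  if (blank_lines) atoms <- c(atoms[1:3], "", atoms[4:length(atoms)],
                              "   ")
  writeLines(c(lines, atoms), path)
  path
}

test_that("PDB fixture parses with chains, residues and cell metadata", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_fixture_pdb(p, cell = TRUE)
  s <- read_structure(p)
  expect_s3_class(s, "structure3d")
  expect_identical(chain_ids(s), c("A", "B"))
  expect_equal(nrow(chain_atoms(s, "A")), 4)
  expect_equal(s$cell$a, 61.221)
  expect_equal(s$cell$z, 8L)
  expect_equal(s$cell$space_group, "I 2 2 2")
})

test_that("parsing tolerates blank lines and trailing whitespace", {
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  make_fixture_pdb(p1)
  make_fixture_pdb(p2, blank_lines = TRUE)
  s1 <- read_structure(p1); s2 <- read_structure(p2)
  expect_equal(s1$atoms, s2$atoms)
})

test_that("file with no atom records raises an empty-structure error", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST", "END"), p)
  expect_error(read_structure(p), "parse|empty")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("waters are excluded by default but kept on request", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   1.000   1.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), p)
  expect_equal(nrow(read_structure(p)$atoms), 1)
  expect_equal(nrow(read_structure(p, keep_waters = TRUE)$atoms), 2)
})

test_that("round trip preserves chains, counts and coordinates to 1e-3", {
  toy <- make_toy_complex()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$vh_complex, p)
  s2 <- read_structure(p)
  expect_identical(chain_ids(s2), chain_ids(toy$vh_complex))
  expect_equal(nrow(s2$atoms), nrow(toy$vh_complex$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(toy$vh_complex$atoms[, c("x", "y", "z")]))),
            1e-3 + 1e-9)
  # cell metadata survives the round trip
  s3 <- toy$vh_complex
  s3$cell <- crystal_cell(61.221, 147.128, 175.171,
                          space_group = "I 2 2 2", z = 8)
  p3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s3, p3)
  expect_equal(read_structure(p3)$cell, s3$cell)
})

test_that("writing an empty structure errors", {
  toy <- make_toy_complex()
  s <- toy$vh_complex
  s$atoms <- s$atoms[0, ]
  expect_error(write_structure(s, tempfile()), "empty")
})

test_that("mmCIF dialect parses atoms and cell", {
  cif <- c(
    "data_test",
    "_cell.length_a 10.0", "_cell.length_b 12.0", "_cell.length_c 14.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0",
    "_cell.angle_gamma 90.0",
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.0 2.0 3.0 1.00 20.0 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.0 5.0 6.0 1.00 20.0 ? 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 7.0 8.0 9.0 1.00 20.0 ? 3 SER A CA 1")
  p <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, p)
  s <- read_structure(p)
  expect_equal(length(chain_ids(s)), 1)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x, c(1, 4, 7))
  expect_equal(s$cell$b, 12)
})

test_that("terminal C-alpha honors file order and falls back when missing", {
  p <- withr::local_tempfile(fileext = ".pdb")
  make_fixture_pdb(p)
  s <- read_structure(p)
  expect_equal(chain_terminal_ca(s, "A", "n_term"), c(2, 3, 4))
  expect_equal(chain_terminal_ca(s, "A", "c_term"), c(8, 9, 10))
  # single-residue chain: both ends coincide
  expect_equal(chain_terminal_ca(s, "B", "n_term"),
               chain_terminal_ca(s, "B", "c_term"))
  # terminal residue lacking CA falls back to nearest residue with one
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   2       1.000   1.000   1.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       2.000   2.000   2.000  1.00  0.00           C",
    "END"), p2)
  s2 <- read_structure(p2)
  expect_equal(chain_terminal_ca(s2, "A", "n_term"), c(1, 1, 1))
  # no CA anywhere is an error
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), p3)
  expect_error(chain_terminal_ca(read_structure(p3), "A"), "C-alpha")
})
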