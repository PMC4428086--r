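test_that("PDB write/read round-trips coordinates, chains and ordering", {
  s <- make_amylin_monomer_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  r <- read_pdb(f)
  expect_equal(nrow(r$atoms), nrow(s$atoms))
  expect_equal(r$atoms$name, s$atoms$name)
  expect_equal(r$atoms$chain, s$atoms$chain)
  expect_equal(r$atoms$resid, s$atoms$resid)
  expect_close(fibrilforge:::coords(r), round(fibrilforge:::coords(s), 3), 1e-9)
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(r, f2)
  r2 <- read_pdb(f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(r2, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("written PDB agrees with an independent reader (bio3d)", {
  skip_if_not_installed("bio3d")
  s <- make_amylin_monomer_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  p <- bio3d::read.pdb(f)
  expect_equal(nrow(p$atom), nrow(s$atoms))
  expect_close(as.numeric(p$atom$x), round(s$atoms$x, 3), 1e-9)
  expect_close(as.numeric(p$atom$z), round(s$atoms$z, 3), 1e-9)
  expect_equal(p$atom$resid, s$atoms$resname)
})

test_that("reader error contracts: missing file, no atoms, malformed fields", {
  expect_error(read_pdb(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM records")
  # HETATM-only file with skip_het drops everything
  writeLines(c(
    "HETATM    1  O   HOH A   1      10.000  10.000  10.000  1.00  0.00",
    "END"), f)
  expect_error(read_pdb(f, skip_het = TRUE), "no atoms selected")
  expect_equal(nrow(read_pdb(f, skip_het = FALSE)$atoms), 1L)
  # malformed coordinate names the line
  writeLines(c(
    "ATOM      1  CA  ALA A   1      xx.xxx  10.000  10.000  1.00  0.00",
    "END"), f)
  expect_error(read_pdb(f), "line 1")
})

test_that("empty or oversized structures are refused by the writer", {
  s <- make_atom_fixture()
  s$atoms <- s$atoms[0, ]
  expect_error(write_pdb(s, tempfile()), "empty")
})

test_that("altloc keeps the highest occupancy and icodes are renumbered", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      4  CA  SER A   2A      7.600   0.000   0.000  1.00  0.00",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$x[1], 1.0)  # occupancy 0.60 wins
  expect_equal(s$atoms$resid, c(1L, 2L, 3L))  # icode folded
  expect_false(is.null(attr(s, "renumber_map")))
})

test_that("multi-model files return the requested model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00",
    "ENDMDL", "END"), f)
  expect_equal(read_pdb(f)$atoms$x, 0)
  expect_equal(read_pdb(f, model = 2)$atoms$x, 5)
  expect_error(read_pdb(f, model = 3), "has 2")
})

test_that("PQR-style input fills charges and radii", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000 -0.3000 1.7000",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  0.3000 1.9000"),
    f)
  s <- read_pdb(f, format = "pqr")
  expect_equal(s$atoms$charge, c(-0.3, 0.3))
  expect_equal(s$atoms$radius, c(1.7, 1.9))
})

test_that("the Amylin fixture is a deterministic 37-residue monomer", {
  s1 <- make_amylin_monomer_fixture()
  s2 <- make_amylin_monomer_fixture()
  expect_equal(fibrilforge:::n_residues(s1), 37L)
  expect_equal(structure_chains(s1), "A")
  expect_identical(s1$atoms, s2$atoms)
  seq <- extract_sequence(s1)
  expect_length(seq, 37)
  expect_equal(unname(seq$residues[1:4]), c("K", "C", "N", "T"))
  expect_equal(unname(seq$residues[37]), "Y")
})

test_that("fixture turn region has non-strand backbone dihedrals", {
  s <- make_amylin_monomer_fixture()
  bb <- fibrilforge:::backbone_of_chain(s, "A")
  for (i in 19:24) {
    psi <- fibrilforge:::dihedral_angle(bb$N[[i]], bb$CA[[i]], bb$C[[i]],
                                        bb$N[[i + 1]])
    expect_true(psi < 45 && psi > -135)  # outside the beta band
  }
})

test_that("generated residues pass the bonded-geometry sanity check", {
  s <- make_amylin_monomer_fixture()
  bonds <- fibrilforge:::detect_bonds(s)
  # every bond detected by the 0.9-1.9 A criterion, and enough of them to
  # cover the backbone (3 per residue minus 1) plus side chains
  expect_gte(nrow(bonds), 37 * 3 - 1)
  xyz <- fibrilforge:::coords(s)
  d <- sqrt(rowSums((xyz[bonds[, 1] + 1, ] - xyz[bonds[, 2] + 1, ])^2))
  expect_true(all(d > 0.9 & d < 1.9))
})

test_that("sequence extraction respects chains and warns on non-canonical", {
  pair <- make_residue_pair_fixture("ASP", "LYS", 4.0)
  expect_equal(unname(extract_sequence(pair, "B")$residues), "K")
  expect_equal(unname(extract_sequence(pair, "A")$residues), "D")
  expect_error(extract_sequence(pair, "Z"), "chain not present")
  one <- fibrilforge:::build_peptide("G", -120, 120)
  expect_length(extract_sequence(one), 1)
  bad <- make_atom_fixture()
  expect_warning(sq <- extract_sequence(bad), "non-canonical")
  expect_equal(unname(sq$residues), "X")
})

test_that("residue pair fixtures hit the requested group distance", {
  for (case in list(list("ASP", "LYS", 4.0), list("GLU", "ARG", 6.0),
                    list("ALA", "LYS", 4.0))) {
    s <- make_residue_pair_fixture(case[[1]], case[[2]], case[[3]])
    a <- s$atoms
    ga <- a[a$chain == "A" &
            a$name %in% fibrilforge:::reference_atoms_for(case[[1]]), ]
    gb <- a[a$chain == "B" &
            a$name %in% fibrilforge:::reference_atoms_for(case[[2]]), ]
    d <- min(sqrt(outer(seq_len(nrow(ga)), seq_len(nrow(gb)),
                        Vectorize(function(i, j)
                          sum((c(ga$x[i], ga$y[i], ga$z[i]) -
                               c(gb$x[j], gb$y[j], gb$z[j]))^2)))))
    expect_equal(d, case[[3]], tolerance = 1e-3)
  }
  expect_error(make_residue_pair_fixture("ASP", "LYS", -1), "positive")
  expect_error(make_residue_pair_fixture("XXX", "LYS", 4), "non-canonical")
})
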