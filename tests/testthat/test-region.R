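test_that("secondary structure: strand-turn-strand pattern is recovered", {
  # ideal hairpin-like construct: two beta-band segments joined by an
  # alpha-region linker
  n <- 16
  phi <- c(rep(-120, 6), rep(-70, 4), rep(-120, 6))
  psi <- c(rep(120, 6), rep(-30, 4), rep(120, 6))
  s <- fibrilforge:::build_peptide(strrep("A", n), phi, psi)
  ss <- unname(assign_secondary_structure(s))
  expect_equal(ss[1:6], rep("E", 6))
  expect_equal(ss[7:10], rep("T", 4))
  expect_equal(ss[11:16], rep("E", 6))
})

test_that("an isolated extended tripeptide is never a turn", {
  s <- fibrilforge:::build_peptide("AAA", rep(-120, 3), rep(120, 3))
  ss <- assign_secondary_structure(s)
  expect_true(all(ss %in% c("E", "C")))
})

test_that("every residue receives exactly one label and errors name residues", {
  s <- make_amylin_monomer_fixture()
  ss <- assign_secondary_structure(s)
  expect_length(ss, 37)
  expect_true(all(ss %in% c("E", "T", "C")))
  broken <- s
  broken$atoms <- broken$atoms[!(broken$atoms$resid == 10 &
                                 broken$atoms$name == "O"), ]
  expect_error(assign_secondary_structure(broken), "residue A10")
})

test_that("Amylin fixture turn row spans the canonical S19-G24 region", {
  ss <- assign_secondary_structure(make_amylin_monomer_fixture())
  expect_equal(unname(ss[19:24]), rep("T", 6))
  expect_equal(unname(ss[c(18, 25)]), c("E", "E"))
})

test_that("SASA matches closed forms on toy systems", {
  # isolated atom: 4*pi*(r+probe)^2
  a <- make_atom_fixture(radius = 1.7)
  s1 <- compute_sasa(a)$sasa
  expect_equal(s1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  # far-separated atoms are additive
  two <- make_particles_fixture(rbind(c(0, 0, 0), c(50, 0, 0)), radius = 1.7)
  expect_equal(sum(compute_sasa(two)$sasa), 2 * s1, tolerance = 1e-6)
  # fully caged atom has zero SASA
  pts <- as.matrix(expand.grid(x = c(-2.2, 0, 2.2), y = c(-2.2, 0, 2.2),
                               z = c(-2.2, 0, 2.2)))
  cage <- make_particles_fixture(rbind(c(0, 0, 0), pts[rowSums(pts^2) > 0, ]),
                                 radius = 1.9)
  expect_equal(compute_sasa(cage)$sasa[1], 0)
  expect_error(compute_sasa(make_particles_fixture(matrix(0, 0, 3))))
})

test_that("salt-bridge detection follows the pair list and cutoff", {
  expect_equal(nrow(detect_salt_bridges(
    make_residue_pair_fixture("ASP", "LYS", 4.0))), 1L)
  expect_equal(nrow(detect_salt_bridges(
    make_residue_pair_fixture("ASP", "LYS", 4.6))), 0L)
  expect_equal(nrow(detect_salt_bridges(
    make_residue_pair_fixture("ALA", "LYS", 4.0))), 0L)
  expect_equal(nrow(detect_salt_bridges(
    make_residue_pair_fixture("GLU", "ARG", 4.2))), 1L)
  # Amylin has no acidic residues, so no bridges at any cutoff
  expect_equal(nrow(detect_salt_bridges(make_amylin_monomer_fixture(),
                                        cutoff = 10)), 0L)
})

test_that("salt-bridge sets are monotone in the cutoff", {
  s <- make_residue_pair_fixture("GLU", "LYS", 4.4)
  cuts <- c(3, 4, 4.5, 6, 8)
  ns <- vapply(cuts, function(cc) nrow(detect_salt_bridges(s, cc)), integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("the classifier reports exactly six region categories", {
  ann <- classify_regions(make_amylin_monomer_fixture())
  expect_length(region_categories(ann), 6L)
  expect_true(all(region_categories(ann) %in% names(ann$residues)))
})

test_that("Amylin fixture: K1 and R11 charged, core avoids charged residues", {
  ann <- classify_regions(make_amylin_monomer_fixture())
  r <- ann$residues
  expect_true(all(r$resid[r$charged] == c(1, 11)))
  expect_false(any(r$hydrophobic_core & r$charged))
  # histidine is polar, not charged
  expect_true(r$polar_region[r$aa == "H"])
  expect_false(r$charged[r$aa == "H"])
})

test_that("fully exposed poly-alanine strand has an empty hydrophobic core", {
  s <- fibrilforge:::build_peptide(strrep("A", 10), rep(-120, 10),
                                   rep(120, 10))
  ann <- classify_regions(s)
  expect_false(any(ann$residues$hydrophobic_core))
})

test_that("classification is invariant under rigid motion", {
  s <- make_amylin_monomer_fixture()
  R <- fibrilforge:::rotation_about_axis(c(1, 2, 3), 1.1)
  moved <- fibrilforge:::set_coords(
    s, sweep(fibrilforge:::coords(s) %*% t(R), 2, c(10, -5, 3), `+`))
  a1 <- classify_regions(s)$residues
  a2 <- classify_regions(moved)$residues
  for (cc in region_categories(NULL))
    expect_equal(a1[[cc]], a2[[cc]])
  expect_equal(a1$rel_sasa, a2$rel_sasa, tolerance = 0.03)
})

test_that("annotation export writes consistent TSV and JSON", {
  ann <- classify_regions(make_amylin_monomer_fixture())
  ft <- withr::local_tempfile(fileext = ".tsv")
  fj <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann, ft, "tsv")
  write_annotation(ann, fj, "json")
  tsv <- utils::read.delim(ft)
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(tsv), 37)
  expect_equal(js$residues$aa, tsv$aa)
  expect_equal(js$residues$hydrophobic_core, tsv$hydrophobic_core)
})
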