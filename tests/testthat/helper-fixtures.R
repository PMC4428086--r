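# shared test helpers: tiny structures built in code

two_particle <- function(r, sigma = 3.4, eps = 0.238, q = c(0, 0)) {
  make_particles_fixture(rbind(c(0, 0, 0), c(r, 0, 0)),
                         sigma = sigma, eps = eps, charge = q)
}

# a small flat extended peptide that stacks cleanly along z
flat_strand_monomer <- function(seq1 = "AVAVAVA") {
  n <- nchar(seq1)
  s <- build_strand <- fibrilforge:::build_peptide(
    seq1, phi = rep(-120, n), psi = rep(120, n))
  assign_parameters(s)
}

expect_close <- function(x, y, tol = 1e-6) expect_lt(max(abs(x - y)), tol)

# A disc-shaped toy monomer with a charged knob/partner pair that keys each
# layer to the next at a specific screw rotation and rise: the stacking
# energy is minimized when layers are 5.0 A apart and rotated 9 degrees.
knob_monomer <- function(rotation = 9, radius = 8) {
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  th <- -rotation * pi / 180
  knob <- c(radius, 0, 1.5)
  partner <- c(radius * cos(th), radius * sin(th), -1.5)
  xyz <- rbind(ring, knob, partner)
  n <- nrow(xyz)
  make_particles_fixture(xyz,
                         charge = c(rep(0, n - 2), 0.5, -0.5),
                         sigma = c(rep(3.4, n - 2), 1.78, 1.78),
                         eps = c(rep(0.238, n - 2), 1.0, 1.0))
}

amylin_candidates <- function(strand_rule = TRUE) {
  s <- make_amylin_monomer_fixture()
  propose_mutations(classify_regions(s), extract_sequence(s),
                    strand_rule = strand_rule)
}

# The canonical 23-row candidate table for the Amylin monomer:
# (position, target, method) triples.
amylin_expected <- function() {
  txt <- c(
    "2 Q Making protein surface hydrophobic",
    "3 H Making protein surface hydrophobic",
    "4 S Making protein surface hydrophobic",
    "6 M Making protein surface hydrophobic",
    "7 T Making protein surface hydrophobic",
    "8 E Making an amino acid on a beta strand charged",
    "9 N Making protein surface hydrophobic",
    "10 H Making protein surface hydrophobic",
    "12 E Making core charged",
    "13 R Making core charged",
    "15 D Making core charged",
    "15 P Mutating an amino acid on a beta strand",
    "16 D Making core charged",
    "17 E Making core charged",
    "21 P Mutating an amino acid at a turn",
    "23 E Making core charged",
    "24 D Making core charged",
    "24 P Mutating GLY at a turn",
    "25 R Making core charged",
    "26 R Making core charged",
    "27 R Making an amino acid on a beta strand charged",
    "32 K Making an amino acid on a beta strand charged",
    "33 E Making an amino acid on a beta strand charged")
  parts <- strsplit(txt, " ", fixed = TRUE)
  data.frame(position = vapply(parts, function(p) as.integer(p[1]),
                               integer(1)),
             target = vapply(parts, `[`, character(1), 2),
             method = vapply(parts, function(p)
               paste(p[-(1:2)], collapse = " "), character(1)),
             stringsAsFactors = FALSE)
}

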