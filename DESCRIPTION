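Package: fibrilforge
Title: Rule-Based Destabilizing Mutagenesis and Stability Scoring of Amyloid Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes an amyloid monomer structure for six categories of
    stability regions (hydrophobic core, hydrophilic surface, beta sheets,
    beta turns, salt bridges, polar regions), proposes destabilizing point
    mutations by explicit disruption rules, assembles fibrils of arbitrary
    length by rigid affine transforms, scores structures with a free energy
    combining Lennard-Jones, Coulomb and a dipolar
    Poisson-Boltzmann-Langevin solvation term, and ranks mutations with
    amyloidogenicity, nucleation and elongation-stability metrics.
    Native-fold preservation is checked with RMSD and RMSF diagnostics on
    multi-model PDB trajectories. Includes a deterministic synthetic
    Amylin fixture generator so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
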