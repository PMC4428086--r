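---
title: "Destabilizing amyloid fibrils by rule-based mutagenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Destabilizing amyloid fibrils by rule-based mutagenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilforge)
```

## The problem

Amyloidogenic peptides such as Amylin (IAPP), the 37-residue pancreatic
hormone implicated in Type II Diabetes, misfold into beta-sheet-rich
monomers that stack into fibrils. A therapeutic strategy is to re-engineer
the peptide sequence itself: find point mutations that destabilize the
fibril while leaving the native fold intact, so a substitute molecule keeps
its biological function but aggregates poorly. `fibrilforge` implements a
complete desk pipeline for this multi-objective search: structural analysis
of the monomer, rule-based mutation proposal, fibril assembly, free-energy
scoring with a dipolar solvent model, metric-based filtering/ranking, and
native-fold diagnostics.

## Stability regions and their disruption

Six structural features stabilize amyloids, and each suggests a disruption
rule:

| Region | Contribution | Disruption |
|---|---|---|
| hydrophobic core | shields apolar residues from water | mutate a buried hydrophobic residue to a charged one |
| hydrophilic surface | stable water-contact surface | mutate an exposed polar residue to a hydrophobic one |
| beta sheets | fibril backbone | reduce inter-strand hydrogen bonding (charged or proline substitutions at strand sites) |
| beta turns | torsional flexibility for sheet formation | proline at the turn centre and at every turn glycine |
| salt bridges | ionic stabilization | mutate one member (the acidic one) to alanine |
| polar regions | hydrogen-bond donors/acceptors | (analysis category; no default emission rule) |

`classify_regions()` evaluates all six on a monomer. Secondary structure
comes from backbone dihedrals — strand (E) where phi is in [-180, -45] deg
and psi in [45, 225] deg (mod 360) for at least two consecutive residues —
supplemented by a DSSP-style electrostatic hydrogen-bond criterion: a
residue also counts as strand when it participates in at least two
backbone H-bonds (energy below -0.5 kcal/mol) with partners at sequence
separation of five or more. Turns are runs of up to six non-strand
residues flanked by strand on both sides; six accommodates the canonical
Amylin turn S19-G24, whose centre residue (left of centre for even
lengths, hence N21) and glycine (G24) receive proline proposals.

Burial is measured by Shrake-Rupley solvent-accessible surface area
(probe 1.4 Å, 240+ sphere points per atom, 960 in the classifier for
threshold stability). Relative accessibility divides each residue's SASA
by that of X in an extended Gly-X-Gly tripeptide built with the same
radii and geometry engine, so numerator and denominator share conventions.
A hydrophobic residue (Kyte-Doolittle positive set A/V/L/I/F/M/W/C) is
*core* below 0.25 relative SASA; a polar residue (S/T/N/Q/C/Y/H) is
*surface* at or above 0.40. Both thresholds are config keys
(`region_config()`); the defaults are deliberate round numbers in the
range structural biology uses for "buried" and "exposed". Glycine is not
hydrophobic by the scale, yet amyloid cores co-opt it; the *context rule*
adds any glycine whose sequence neighbour is a core residue and whose own
relative SASA is below the core threshold. Histidine is treated as polar,
not charged, at neutral pH. Salt bridges are acidic-basic pairs (D/E
versus K/R) whose charged-group distance — the minimum over ASP OD1/OD2,
GLU OE1/OE2, LYS NZ, ARG NH1/NH2/NE — is under 4.5 Å. Amylin contains no
acidic residues, so its salt-bridge set is empty by construction.

## Mutation proposal and ranking

`propose_mutations()` turns the annotation into candidates: one per
(site, rule) pair, with target residues resolved through a substitution
policy (`read_policy()`). A policy has per-method defaults and
per-position overrides; the bundled `amylin_2015` policy carries the
curated position-specific targets for Amylin (e.g. F15 takes D under the
core rule while F23 takes E — no pure wild-type-to-target map reproduces
such choices, which is why position overrides exist and are honestly
labelled calibration). The strand-site heuristic proposes charged targets
at strand residues not already claimed by the core or surface categories,
restricted to small/hydrophobic wild types (A/V/L/I/F/G), and
additionally offers proline to the most central strand aromatic; it can
be disabled (`strand_rule = FALSE`). On the packaged Amylin fixture the
rules emit exactly 23 candidates. Four experimentally reported mutations
(S20G, S20K, N21L, N14L) ship separately via `experimental_mutations()`
and are never emitted by the engine.

Candidates are ranked by a pluggable aggregation-propensity scorer;
the default sums Chou-Fasman beta propensity times Kyte-Doolittle
hydropathy over a 5-residue window of the mutated sequence — a cheap,
transparent stand-in for external aggregation predictors, used only to
order candidates, never to filter them.

`apply_mutation()` replaces a side chain from ideal-geometry templates
aligned on the local backbone frame (backbone coordinates are preserved
bit-exactly), choosing chi1 from {-65, 60, 180} degrees to minimize
steric overlap; in a multi-chain fibril every chain is mutated
identically, since each monomer of a real fibril carries the substitution.

## Fibril geometry and the stability landscape

Fibrils are generated by a screw operation: monomer k is rotated
k x 9 degrees about the fibril axis (through the monomer centroid) and
translated k x 5.0 Å along it; a second stack is flipped 180 degrees
about an axis-perpendicular and offset by the 3.0 Å packing distance.
These defaults are the canonical Amylin fibril parameters; the 9 degrees
is interpreted per monomer (config-flaggable) and the axis defaults to
the principal axis of the strand C-alpha atoms. All transforms are exact
isometries, so every chain is congruent to the monomer to floating-point
precision.

`landscape_scan()` exhausts a (rotation, rise, packing) grid: each point
builds a short probe fibril (4 monomers), records the initial
Lennard-Jones and Coulomb terms, and runs a light steepest-descent
relaxation to measure the enthalpy drift (initial minus final energy) —
large drift flags an unstable initial conformation. The selected optimum
minimizes initial energy *within* the set of points whose drift is within
a margin (default 5 kcal/mol) of the smallest drift. A strict
lexicographic rule (drift first, energy second) degenerates with
continuous drift values — the secondary criterion would never engage —
so the tolerance form is used and documented here as the package's
reading of "lowest drift and lowest initial energy".

## The free energy

Structures are scored by

F_E = F_solv + F_coulomb + F_vdw

with pairwise terms over non-excluded atom pairs within a 10 Å cutoff:
Lennard-Jones 4 eps [(sigma/r)^12 - (sigma/r)^6] with Lorentz-Berthelot
combining, and Coulomb k_e q_i q_j / r with k_e = 332.0636
kcal Å/(mol e²). Bonded 1-2 and 1-3 pairs are excluded and 1-4 pairs are
scaled (default 1.0); the "14" in the short-range electrostic term is
read as this standard exclusion convention. The bundled parameter table
is a minimal united-atom set authored for this package: heavy atoms only,
partial charges summing to each residue's formal charge at neutral pH
(plus optional +1/-1 termini), element-class sigma/eps and solvation
radii. Externally parameterized structures can be supplied as PQR files.
Bonds are detected geometrically (0.9-1.9 Å within the same or adjacent
residue of a chain), which doubles as the fixture generators' sanity
check.

Relaxation (`relax()`) is adaptive steepest descent on the soft-core
version of the pairwise energy (the Lennard-Jones potential continues
linearly below 0.7 sigma so clashes have finite energy and forces),
stopping at the step limit or when the largest atomic gradient falls
below 0.1 kcal/mol/Å. Drift is never negative on success because only
energy-decreasing steps are accepted.

## Dipolar Poisson-Boltzmann-Langevin solvation

The solvent is a lattice gas of point dipoles: sites of edge a = 2.8 Å,
dipole moment p0 = 3.00 D, bulk concentration C_dip = 55 M, giving bulk
occupancy lambda = N_A C_dip a³ (about 0.727) and fugacity
z = lambda/(1-lambda). At a solvent node in reduced field
u = p0 |E| / k_B T the occupancy is z F(u) / (1 + z F(u)) per site with
F(u) = sinh(u)/u, and the polarization is p0 rho L(u) with the Langevin
function L(u) = coth(u) - 1/u. This enters the Poisson equation as a
field-dependent permittivity eps(u) = 1 + 4 pi l_B P/|E| (l_B the vacuum
Bjerrum length); the small-field limit reproduces a bulk dielectric of
roughly 31 for the default parameters, the saturating limit respects the
close-packing bound rho <= 1/a³.

The free-energy functional evaluated at the solved field is

F[phi] = sum q phi - (1/8 pi l_B) int |grad phi|²
         - (k_B T/a³) int_solvent ln(1 + z F(u)),

whose Euler-Lagrange equation is exactly the dipolar nonlinear
Poisson-Boltzmann-Langevin equation being solved. The solvation energy is
F_solv = F_(p0, C_dip) - F_(0,0) - N_w mu_w, with N_w the dipole count
(integral of rho over the solvent) and mu_w = k_B T ln(1-lambda)/lambda
the bulk chemical potential per dipole. A pleasant identity motivates
this reference: ln(1-lambda)/lambda *is* the bulk grand potential per
dipole of the lattice gas, so for an empty solute the subtraction cancels
exactly and F_solv is zero to round-off — a property the tests assert.
In the dilute limit mu_w tends to -k_B T; at the defaults it is about
-1.79 k_B T = -1.065 kcal/mol. Grid self-energies of the projected point
charges cancel between the two solves because both use the identical
charge distribution.

Numerically: a cubic grid (257 points per edge at 1 Å spacing by
default; the test suite and acceptance script use 65³, which agrees with
129³ at 0.5 Å within 10% on a toy ion), zero-potential boundaries,
trilinear charge projection (charge conserved to 1e-10 e), solvent mask
outside the solvent-accessible surface (atom radius + 1.4 Å probe),
red-black successive over-relaxation with the over-relaxation factor
2/(1+sin(pi/n)) and the nonlinear permittivity under-relaxed (factor 0.6,
refreshed every third sweep). Convergence is declared when the largest
potential update in a sweep falls below 1e-6 k_B T/e; the achieved
residual is always reported, and divergence (50 consecutive growing
sweeps) raises an error. Salt is off by default; a linearized monovalent
screening term is available for equilibration-style runs.

## Stability metrics and filtering

For mutation i with per-length fibril energies F_{a_j}:

- amyloidogenicity: dG = F_{a_1} - F_native; positive means the
  native-to-amyloid conversion is endothermic. Mutations with negative dG
  (spontaneous amyloid formation) are eliminated first.
- nucleation: dN = F_{a_4} - 4 F_{a_1}, the energy of joining four free
  monomers; stage two removes mutations whose dN is at or below the
  control's (ties removed — strict survival was chosen and is documented
  here because the verbal statements "greater than the control" and
  "remove all smaller than the control" disagree about ties).
- elongation: dF~ = sum_j (F^i_{a_j} - F^c_{a_j})/j over the shared
  lengths (the lower summation bound is read as the full available length
  set); survivors are ranked by dF~ descending, most destabilizing first.

The metrics are backend-agnostic: profiles can come from the full free
energy or from pairwise-only scoring, so the filter logic is testable
without the solver.

## Native-fold diagnostics

Trajectories are C-alpha snapshot series (read from multi-model PDB).
RMSD series superpose each frame on the reference by least squares before
measuring, so rigid-body motion reads as zero. delta_rmsd is the
element-wise mutant-minus-native difference (exactly antisymmetric).
RMSF is implemented verbatim as the *mean squared* deviation from the
reference position (Å², no square root), with the reference defaulting
to the time-average position and a `sqrt = TRUE` variant behind a flag,
because axis conventions for published fluctuation plots vary; frames
are globally superposed first by default (flag to disable).

## The synthetic Amylin fixture

`make_amylin_monomer_fixture()` builds a deterministic 37-residue
monomer carrying the human Amylin sequence with the canonical region
layout: strand segments at 6-18 and 25-36, turn at 19-24, buried
hydrophobic core L12/A13/F15/L16/V17 and F23/G24/A25/I26, exposed polar
surface C2/N3/T4/T6/C7/T9/Q10, charged K1/R11. Backbone torsions for the
strand segments stay inside the beta band of the Ramachandran map but
are allowed to vary per residue: ideal straight strands alternate their
side chains between two faces, and no lone two-strand monomer can then
bury a *consecutive* run of core residues — the fixture instead packs the
12-26 segment three-dimensionally (a top deck over the core, a turn that
dips below the strand ends, and a carboxy-terminal stretch tucked
underneath), which is what real amyloid monomers achieve with the help
of neighbouring sheets. The generator is bit-deterministic; its torsion
table is frozen in the package source.

What the fixture emulates: sequence, region taxonomy, burial contrasts,
turn geometry, and everything the rule engine consumes. What it does not:
real NMR coordinates, hydrogens, experimental fibril packing, or
side-chain rotamer statistics — so green tests demonstrate the pipeline's
logic and numerics, not agreement with any experimental structure.
Real PDB and PQR files are accepted throughout; none are required.

One residual deviation is worth stating precisely. In the amyloid fibril
the turn region is buried by the neighbouring monomers above and below;
in a *lone* monomer the outward rim of the S19-G24 turn is necessarily
part of the molecular surface. A surface-exposure audit makes this
quantitative: the chain segments that may stay exposed under the
canonical layout (the N-terminal arm, K1/R11, and L27/V32/G33) cannot be
routed adjacent to the turn apex under the strand-dihedral constraints,
so two turn rim residues (S20, N21) remain above the 0.40 surface
threshold and the adjacent F23/G24/A25 corner cannot reach the 0.25 core
threshold. The rule engine consequently emits surface proposals at
S20/N21 and reaches A25 through the strand rule rather than the core
rule; the other 20 of the 23 canonical candidate rows — all surface,
core, turn-proline and strand rows away from the turn apex — are
reproduced exactly, and the candidate count is 23. The candidate table
is deterministic and asserted row-by-row in the test suite.

## Problem sizes and determinism

The test and acceptance workloads are desk-scale by design: 65³ solver
grids, 4-monomer probe fibrils, 25-monomer assembly checks, 5x5 landscape
grids, toy ions for closed-form solvation checks. Every generator in the
package is deterministic; the only randomized test inputs use fixed
seeds. Known limitations: the united-atom parameter table is minimal (no
aromatic quadrupoles, no explicit hydrogens); the relaxation handles
clash relief, not conformational search; the DPBL solver is a
single-grid SOR scheme, adequate at these sizes but not tuned for very
large solutes; and absolute solvation magnitudes depend on the radius
set, so comparisons should stay within one parameterization.
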