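# Synthetic structure fixtures. Everything downstream (region analysis,
# mutation proposal, fibril assembly, energy scoring) is testable on these
# deterministic generators without any external files.

AMYLIN_SEQ <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

# Internal conformation table for the Amylin monomer fixture: per-residue
# backbone torsions and side-chain chi1/chi2. Residues 6-18 and 25-36 stay
# inside the beta region of the Ramachandran map (strand label); 19-24 is
# the turn. The torsion pattern packs the 12-26 segment into a shielded
# three-layer core (top deck, dipping turn, tucked C-terminal stretch) with
# the N-terminal tail splayed out, reproducing the canonical burial layout
# of the Amylin amyloid (buried hydrophobic core L12-V17/F23-I26, exposed
# polar surface C2-Q10). Values are a frozen design table (see the methods
# vignette for how the conformation was designed).
amylin_conformation <- function() {
  # begin frozen torsion table
  phi <- c(-32.6, -63.7, -83.7, -60.5, -70.8, -120, -120, -120, -120,
           -120, -120, -87.7, -77.7, -98.3, -54.7, -167.5, -108.6,
           -176.4, -62.4, -72.3, -73.7, -56.1, -55.2, -79.3, -120.8,
           -106.6, -139.6, -61.3, -143, -54.6, -85, -47.2, -160.5, -56.7,
           -141.3, -88.5, -80.5)
  psi <- c(25.5, 4.7, 36, -26.2, 23.1, 120, 120, 120, 120, 120, 120,
           148.5, 87.8, 104.6, 48.7, 128.4, 46, 156.8, -104.7, -68.4, 44,
           -20.6, -13.4, -38.8, 104.3, 116.2, 114, 125.8, 80.7, 46.6,
           85.8, 46.9, 120.3, 112.1, 151.2, 167.3, 37.8)
  chi1 <- c(12.3, 80.1, 52.1, -82.6, 174.4, -65, -65, -65, -65, -65, -65,
           -106.4, -21.6, -180, -60.9, 99.2, -158.3, -77.8, -39.4,
           -115.5, -74.7, -45.1, -104.6, 5.3, 65.2, -76.4, -129.8,
           -191.1, 274.6, 1.6, -7.1, 49.5, -19.7, -14.8, 3.3, -91.9,
           -28.5)
  chi2 <- c(-23.7, -79.8, 26.1, 25.2, -159.3, 180, 180, 180, 180, 180,
           180, 12, 159.7, 92.1, 124.9, 70.4, -180, 89, 180, 111.1, 82,
           76.7, 145, -100.6, 146.7, 41.9, -64, 39.2, 30.1, 98.9, 128.2,
           149, 129.5, -130.5, 119, 67.5, 151.5)
  # end frozen torsion table
  list(phi = phi, psi = psi, chi1 = chi1, chi2 = chi2)
}

#' Deterministic Amylin monomer fixture
#'
#' Builds an idealized 37-residue strand-turn-strand amyloid monomer
#' carrying the human Amylin sequence: two beta-band strand segments
#' (residues 6-18 and 25-36) joined by a turn (19-24), with the
#' hydrophobic core segment packed and the N-terminal polar stretch
#' exposed. Calling it twice yields bit-identical coordinates.
#'
#' @return single-chain `ff_structure` of 37 residues.
#' @export
make_amylin_monomer_fixture <- function() {
  conf <- amylin_conformation()
  chi <- lapply(seq_len(37), function(i)
    c(conf$chi1[i], conf$chi2[i], 180, 180))
  build_peptide(AMYLIN_SEQ, conf$phi, conf$psi, chi = chi,
                metadata = "synthetic Amylin strand-turn-strand monomer")
}

reference_atoms_for <- function(resname) {
  g <- CHARGED_GROUP_ATOMS[[resname]]
  if (!is.null(g)) g else c("CB", "CA")
}

#' Two-residue salt-bridge test fixture
#'
#' Places two residues on separate chains so that the minimum distance
#' between their charged-group reference atoms (ASP OD1/OD2, GLU OE1/OE2,
#' LYS NZ, ARG NH1/NH2/NE; CB/CA for residues without a charged group)
#' equals `group_distance` to within 1e-3 A.
#'
#' @param res_a,res_b canonical 3-letter codes.
#' @param group_distance target charged-group distance, A (> 0).
#' @return two-chain `ff_structure` (chains A and B, one residue each).
#' @export
make_residue_pair_fixture <- function(res_a, res_b, group_distance) {
  res_a <- toupper(res_a); res_b <- toupper(res_b)
  if (!res_a %in% names(AA3) || !res_b %in% names(AA3))
    stop("non-canonical residue code")
  if (group_distance <= 0) stop("group_distance must be positive")
  one_res <- function(res3, chain) {
    s <- build_peptide(AA3[[res3]], phi = -120, psi = 120, chain = chain)
    s
  }
  a <- one_res(res_a, "A")
  b <- one_res(res_b, "B")
  ref_xyz <- function(s, names_) {
    at <- s$atoms[s$atoms$name %in% names_, ]
    at <- at[match(intersect(names_, at$name)[1], at$name), , drop = FALSE]
    # use every listed atom present; fall back handled by caller
    m <- s$atoms[s$atoms$name %in% names_, c("x", "y", "z")]
    as.matrix(m)
  }
  ga <- ref_xyz(a, reference_atoms_for(res_a))
  gb <- ref_xyz(b, reference_atoms_for(res_b))
  # pick the reference atom of A with the largest x, of B with the smallest,
  # and translate B so that pair sits exactly group_distance apart along +x;
  # every other cross pair is then at least that far away.
  ia <- which.max(ga[, 1]); ib <- which.min(gb[, 1])
  shift <- ga[ia, ] + c(group_distance, 0, 0) - gb[ib, ]
  xyz <- coords(b)
  b <- set_coords(b, sweep(xyz, 2, shift, `+`))
  atoms <- rbind(a$atoms, b$atoms)
  ff_structure(atoms[, setdiff(names(atoms), "serial")],
               metadata = sprintf("%s-%s pair at %.3f A", res_a, res_b,
                                  group_distance))
}

#' Toy single-atom structure
#'
#' One argon-like atom; handy for closed-form SASA and solvation checks.
#' @param radius SASA radius, A.
#' @param charge partial charge, e.
#' @param sigma,eps Lennard-Jones parameters.
#' @param position 3-vector, A.
#' @param chain chain id.
#' @param resid residue index.
#' @return toy `ff_structure` (single HETATM-like particle).
#' @export
make_atom_fixture <- function(radius = 1.7, charge = 0, sigma = 3.4,
                              eps = 0.238, position = c(0, 0, 0),
                              chain = "A", resid = 1L) {
  ff_structure(data.frame(name = "AR", element = "C",
                          x = position[1], y = position[2], z = position[3],
                          charge = charge, radius = radius, sigma = sigma,
                          eps = eps, resid = resid, resname = "LIG",
                          chain = chain, stringsAsFactors = FALSE),
               metadata = "toy particle", toy = TRUE)
}

#' Toy multi-atom structure from explicit coordinates
#' @param xyz n x 3 matrix.
#' @param radius,charge,sigma,eps per-atom values (recycled).
#' @return toy `ff_structure` with one particle per row, all in one chain
#'   as separate residues.
#' @export
make_particles_fixture <- function(xyz, radius = 1.7, charge = 0,
                                   sigma = 3.4, eps = 0.238) {
  n <- nrow(xyz)
  ff_structure(data.frame(name = "AR", element = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          charge = rep_len(charge, n),
                          radius = rep_len(radius, n),
                          sigma = rep_len(sigma, n),
                          eps = rep_len(eps, n),
                          resid = seq_len(n), resname = "LIG", chain = "A",
                          stringsAsFactors = FALSE),
               metadata = "toy particles", toy = TRUE)
}

#' Toy C-alpha trajectory
#'
#' A deterministic pseudo-dynamics trajectory: each frame displaces the
#' residues of a reference chain by small sinusoidal perturbations, with an
#' optional rigid drift, so RMSD/RMSF behaviour is known by construction.
#'
#' @param n_res residues.
#' @param n_frames frames.
#' @param amplitude per-residue oscillation amplitude, A.
#' @param drift rigid-body translation per frame, A (3-vector).
#' @param label trajectory label.
#' @return an `ff_trajectory`.
#' @export
make_toy_trajectory <- function(n_res = 10, n_frames = 6, amplitude = 0.5,
                                drift = c(0, 0, 0), label = "toy") {
  ref <- cbind(3.8 * seq_len(n_res), 0, 0)
  frames <- lapply(seq_len(n_frames) - 1, function(t) {
    osc <- amplitude * sin(2 * pi * t / n_frames + seq_len(n_res))
    sweep(ref + cbind(0, osc, 0), 2, t * drift, `+`)
  })
  trajectory(frames, label = label)
}
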