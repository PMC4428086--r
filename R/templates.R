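# Amino-acid tables and ideal-geometry residue templates.
#
# Structures are built heavy-atom-only (united-atom convention, as in the
# GROMOS family of force fields): aliphatic/aromatic hydrogens are folded into
# their parent heavy atom. Side chains are grown from per-residue internal
# coordinate templates (bond, angle, dihedral), with chi angles exposed so the
# fixture generators and the mutation engine can select rotamers.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA1 <- structure(names(AA3), names = unname(AA3))

#' Convert between 1- and 3-letter amino-acid codes
#' @param x character vector of codes.
#' @return character vector of converted codes; unknown codes give NA.
#' @export
aa_three_to_one <- function(x) unname(AA3[toupper(x)])

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA1[toupper(x)])

# Kyte-Doolittle hydropathy (sign convention: positive = hydrophobic).
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                    E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                    M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                    Y = -1.3, V = 4.2)

# Chou-Fasman beta-sheet conformational propensities.
BETA_PROPENSITY <- c(V = 1.70, I = 1.60, Y = 1.47, F = 1.38, W = 1.37,
                     L = 1.30, C = 1.19, T = 1.19, Q = 1.10, M = 1.05,
                     R = 0.93, N = 0.89, H = 0.87, A = 0.83, S = 0.75,
                     G = 0.75, K = 0.74, P = 0.55, D = 0.54, E = 0.37)

# Residue class sets used by the region classifier (Kyte-Doolittle sign for
# the hydrophobic set; histidine treated as polar, not charged, at neutral pH).
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "F", "M", "W", "C")
POLAR_SET <- c("S", "T", "N", "Q", "C", "Y", "H")
CHARGED_SET <- c("D", "E", "K", "R")
ACIDIC_SET <- c("D", "E")
BASIC_SET <- c("K", "R")

# Charged-group reference atoms for salt-bridge distance rules.
CHARGED_GROUP_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  LYS = "NZ",
  ARG = c("NH1", "NH2", "NE")
)

# Ideal backbone geometry (Engh-Huber-like).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

# Side-chain internal-coordinate templates. Each row places one atom bonded to
# `c`, with bond length `bond` (A), bond angle b-c-atom `angle` (deg) and
# dihedral a-b-c-atom equal to chi[chi] + off when chi > 0, else off.
sc_row <- function(atom, a, b, c, bond, angle, chi, off) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = chi, off = off, stringsAsFactors = FALSE)
}

SIDECHAIN_TEMPLATES <- local({
  t <- list()
  t$GLY <- NULL
  t$ALA <- NULL  # CB placed by the common rule
  t$VAL <- rbind(sc_row("CG1", "N", "CA", "CB", 1.52, 110.5, 1, 0),
                 sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -122))
  t$LEU <- rbind(sc_row("CG", "N", "CA", "CB", 1.53, 116.3, 1, 0),
                 sc_row("CD1", "CA", "CB", "CG", 1.52, 110.5, 2, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.52, 110.5, 2, 122))
  t$ILE <- rbind(sc_row("CG1", "N", "CA", "CB", 1.53, 110.4, 1, 0),
                 sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -122),
                 sc_row("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2, 0))
  t$PRO <- rbind(sc_row("CG", "N", "CA", "CB", 1.49, 104.5, 1, 0),
                 sc_row("CD", "CA", "CB", "CG", 1.50, 106.1, 2, 0))
  t$PHE <- rbind(sc_row("CG", "N", "CA", "CB", 1.51, 113.8, 1, 0),
                 sc_row("CD1", "CA", "CB", "CG", 1.39, 120.7, 2, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.39, 120.7, 2, 180),
                 sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.7, 0, 180),
                 sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.7, 0, 180),
                 sc_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0, 0))
  t$TYR <- rbind(t$PHE,
                 sc_row("OH", "CD1", "CE1", "CZ", 1.38, 119.9, 0, 180))
  t$TRP <- rbind(sc_row("CG", "N", "CA", "CB", 1.50, 113.6, 1, 0),
                 sc_row("CD1", "CA", "CB", "CG", 1.37, 126.9, 2, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.43, 126.8, 2, 180),
                 sc_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
                 sc_row("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0, 180),
                 sc_row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, 0),
                 sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0, 180),
                 sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 0, 180),
                 sc_row("CH2", "CE3", "CE2", "CZ2", 1.37, 117.5, 0, 0))
  t$MET <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
                 sc_row("SD", "CA", "CB", "CG", 1.80, 112.7, 2, 0),
                 sc_row("CE", "CB", "CG", "SD", 1.79, 100.9, 3, 0))
  t$SER <- sc_row("OG", "N", "CA", "CB", 1.42, 111.1, 1, 0)
  t$THR <- rbind(sc_row("OG1", "N", "CA", "CB", 1.43, 109.6, 1, 0),
                 sc_row("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -122))
  t$CYS <- sc_row("SG", "N", "CA", "CB", 1.81, 114.4, 1, 0)
  t$ASN <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 1, 0),
                 sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, 2, 0),
                 sc_row("ND2", "CA", "CB", "CG", 1.33, 116.4, 2, 180))
  t$GLN <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2, 0),
                 sc_row("OE1", "CB", "CG", "CD", 1.23, 120.8, 3, 0),
                 sc_row("NE2", "CB", "CG", "CD", 1.33, 116.4, 3, 180))
  t$ASP <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 1, 0),
                 sc_row("OD1", "CA", "CB", "CG", 1.25, 118.4, 2, 0),
                 sc_row("OD2", "CA", "CB", "CG", 1.25, 118.4, 2, 180))
  t$GLU <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 2, 0),
                 sc_row("OE1", "CB", "CG", "CD", 1.25, 118.4, 3, 0),
                 sc_row("OE2", "CB", "CG", "CD", 1.25, 118.4, 3, 180))
  t$LYS <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2, 0),
                 sc_row("CE", "CB", "CG", "CD", 1.52, 111.3, 3, 0),
                 sc_row("NZ", "CG", "CD", "CE", 1.49, 111.9, 4, 0))
  t$ARG <- rbind(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 1, 0),
                 sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 2, 0),
                 sc_row("NE", "CB", "CG", "CD", 1.46, 111.5, 3, 0),
                 sc_row("CZ", "CG", "CD", "NE", 1.33, 124.2, 4, 0),
                 sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
                 sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180))
  t$HIS <- rbind(sc_row("CG", "N", "CA", "CB", 1.49, 113.8, 1, 0),
                 sc_row("ND1", "CA", "CB", "CG", 1.38, 122.7, 2, 0),
                 sc_row("CD2", "CA", "CB", "CG", 1.36, 131.0, 2, 180),
                 sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.0, 0, 180),
                 sc_row("NE2", "CB", "CG", "CD2", 1.37, 107.0, 0, 180))
  t
})

# Default chi angles (a common rotamer; enough chis for the longest chain).
DEFAULT_CHI <- c(-65, 180, 180, 180)

element_of_atom <- function(atom_name) {
  # First character of the standard atom name gives the element for the
  # heavy-atom alphabet used here (C, N, O, S).
  substr(gsub("^[0-9]", "", atom_name), 1, 1)
}

# Grow the side chain of one residue given its backbone atoms.
# Returns a named list of atom positions (excluding backbone).
build_sidechain <- function(resname, n, ca, c, chi = DEFAULT_CHI) {
  out <- list()
  if (resname == "GLY") return(out)
  chi <- c(chi, rep(180, 4))[1:6]
  # Common CB rule (L-chirality; improper dihedral C-N-CA-CB).
  cb <- nerf_place(c, n, ca, 1.53, 110.4, 122.6)
  out$CB <- cb
  tpl <- SIDECHAIN_TEMPLATES[[resname]]
  if (is.null(tpl)) return(out)
  pos <- list(N = n, CA = ca, C = c, CB = cb)
  for (i in seq_len(nrow(tpl))) {
    r <- tpl[i, ]
    dih <- if (r$chi > 0) chi[r$chi] + r$off else r$off
    p <- nerf_place(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, dih)
    pos[[r$atom]] <- p
    out[[r$atom]] <- p
  }
  out
}

# Build an ideal backbone from per-residue (phi, psi) torsions (deg).
# omega is fixed trans (180). Returns a list of per-residue lists with N, CA,
# C, O positions. phi[1] and psi[n] are not used geometrically except to
# place O of the last residue.
build_backbone <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  g <- BB_GEOM
  res <- vector("list", n)
  # Seed residue 1 in a canonical frame.
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n - 1)) {
    p <- res[[i]]
    Nn <- nerf_place(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i])
    CAn <- nerf_place(p$CA, p$C, Nn, g$n_ca, g$ang_c_n_ca, omega[i])
    Cn <- nerf_place(p$C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi[i + 1])
    res[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  # Carbonyl oxygens: O_i anti to the next N (dihedral psi_i + 180).
  for (i in seq_len(n)) {
    p <- res[[i]]
    res[[i]]$O <- nerf_place(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o,
                             psi[i] + 180)
  }
  res
}
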