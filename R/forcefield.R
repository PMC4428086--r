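# Force-field parameter assignment (charges, Lennard-Jones, radii) and the
# bonded topology used for non-bonded exclusions.
#
# The bundled table is a minimal united-atom (heavy-atom) parameter set
# authored for this package: side-chain and backbone partial charges sum to
# the formal residue charge at neutral pH, and sigma/eps/radius are assigned
# per element class. Externally parameterized structures can be supplied as
# PQR files via read_pdb(format = "pqr").

#' Load a force-field parameter table
#'
#' @param path TSV with columns residue, atom, charge, sigma, eps, radius;
#'   defaults to the bundled table.
#' @param scale14_lj,scale14_coul scale factors applied to 1-4 pairs.
#' @return object of class `ff_params`.
#' @export
load_forcefield <- function(path = system.file("extdata", "forcefield.tsv",
                                               package = "fibrilforge"),
                            scale14_lj = 1.0, scale14_coul = 1.0) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "atom", "charge", "sigma", "eps", "radius")
                %in% names(tab)))
  if (any(tab$sigma <= 0) || any(tab$eps < 0))
    stop("invalid LJ parameters in table (need sigma > 0, eps >= 0)")
  structure(list(table = tab, scale14_lj = scale14_lj,
                 scale14_coul = scale14_coul),
            class = "ff_params")
}

#' Assign charges, radii and Lennard-Jones parameters to every atom
#'
#' Terminal charges (+1 on the N of a chain's first residue, -1 on the
#' OXT/O of its last residue) model free termini at neutral pH and can be
#' switched off for capped or amidated peptides.
#'
#' @param structure an `ff_structure` with canonical residues.
#' @param params an `ff_params` (default: bundled table).
#' @param charged_termini add the +1/-1 terminal charges (default TRUE).
#' @return the structure with charge/radius/sigma/eps columns filled.
#' @export
assign_parameters <- function(structure, params = load_forcefield(),
                              charged_termini = TRUE) {
  a <- structure$atoms
  tab <- params$table
  key <- paste(tab$residue, tab$atom)
  i <- match(paste(a$resname, a$name), key)
  # OXT shares the carbonyl-oxygen parameters.
  oxt <- is.na(i) & a$name == "OXT"
  if (any(oxt)) i[oxt] <- match(paste(a$resname[oxt], "O"), key)
  if (anyNA(i)) {
    bad <- unique(paste(a$resname, a$name)[is.na(i)])
    stop("no force-field parameters for atom(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  a$charge <- tab$charge[i]
  a$sigma <- tab$sigma[i]
  a$eps <- tab$eps[i]
  a$radius <- tab$radius[i]
  if (charged_termini) {
    for (ch in unique(a$chain)) {
      rows <- which(a$chain == ch)
      first_res <- min(a$resid[rows]); last_res <- max(a$resid[rows])
      nt <- rows[a$resid[rows] == first_res & a$name[rows] == "N"]
      if (length(nt)) a$charge[nt[1]] <- a$charge[nt[1]] + 1
      ct <- rows[a$resid[rows] == last_res & a$name[rows] == "OXT"]
      if (!length(ct)) ct <- rows[a$resid[rows] == last_res & a$name[rows] == "O"]
      if (length(ct)) a$charge[ct[1]] <- a$charge[ct[1]] - 1
    }
  }
  structure$atoms <- a
  structure$params <- list(scale14_lj = params$scale14_lj,
                           scale14_coul = params$scale14_coul)
  structure
}

#' Net charge of a structure
#' @param structure a parameterized `ff_structure`.
#' @return total charge in e.
#' @export
net_charge <- function(structure) {
  if (anyNA(structure$atoms$charge)) stop("parameters not assigned")
  sum(structure$atoms$charge)
}

# Covalent bonds by distance (0.9-1.9 A between heavy atoms of the same
# chain and the same or sequence-adjacent residue; covers side chains plus
# the peptide C-N link). Non-canonical residues (toy particles, ligands)
# carry no bonds, so every pair among them is non-bonded.
# Returns a 2-column 0-based integer matrix.
detect_bonds <- function(structure, lo = 0.9, hi = 1.9) {
  a <- structure$atoms
  xyz <- coords(structure)
  out <- list()
  canon <- a$resname %in% names(AA3)
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch & canon)
    if (!length(rows)) next
    # limit the pair search to nearby residues for speed
    sub <- xyz[rows, , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    near <- abs(outer(a$resid[rows], a$resid[rows], `-`)) <= 1
    hit <- which(d > lo & d < hi & near, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit))
      out[[ch]] <- cbind(rows[hit[, 1]] - 1L, rows[hit[, 2]] - 1L)
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# 1-2/1-3 exclusions and 1-4 pairs from the bond graph.
exclusion_lists <- function(structure) {
  bonds <- detect_bonds(structure)
  n <- nrow(structure$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1] + 1L; j <- bonds[k, 2] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- list(); p14 <- list()
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    if (is.null(n1)) next
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[n2])), c(i, n1, n2))
    ex <- c(n1, n2); ex <- ex[ex > i]
    if (length(ex)) excl[[length(excl) + 1L]] <- cbind(i - 1L, ex - 1L)
    p4 <- n3[n3 > i]
    if (length(p4)) p14[[length(p14) + 1L]] <- cbind(i - 1L, p4 - 1L)
  }
  list(excl = if (length(excl)) do.call(rbind, excl) else matrix(integer(0), 0, 2),
       pairs14 = if (length(p14)) do.call(rbind, p14) else matrix(integer(0), 0, 2))
}
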