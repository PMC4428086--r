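# The core structural container. A `ff_structure` is a list with an atom
# table (one row per atom) and free-text metadata. It is the universal solute
# representation passed between every module.
#
# Atom table columns:
#   serial   integer, 1-based
#   name     atom name (PDB convention, e.g. "CA", "OD1")
#   element  element symbol
#   x, y, z  coordinates, Angstrom
#   charge   partial charge, e (NA until parameters assigned)
#   radius   solvation/SASA radius, Angstrom (NA until assigned)
#   sigma    Lennard-Jones sigma, Angstrom (NA until assigned)
#   eps      Lennard-Jones epsilon, kcal/mol (NA until assigned)
#   resid    1-based residue index within its chain
#   resname  3-letter residue code
#   chain    single-character chain id

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with at least columns name, x, y, z, resid,
#'   resname, chain; missing optional columns are filled with NA.
#' @param metadata free-text provenance string.
#' @param toy logical; toy fragments skip the every-residue-has-CA check.
#' @return object of class `ff_structure`.
#' @export
ff_structure <- function(atoms, metadata = "", toy = FALSE) {
  needed <- c("name", "x", "y", "z", "resid", "resname", "chain")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  opt <- c("charge", "radius", "sigma", "eps")
  for (col in opt) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (is.null(atoms$element)) atoms$element <- element_of_atom(atoms$name)
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "name", "element", "x", "y", "z", "charge",
                     "radius", "sigma", "eps", "resid", "resname", "chain")]
  rownames(atoms) <- NULL
  x <- structure(list(atoms = atoms, metadata = metadata, toy = toy),
                 class = "ff_structure")
  validate_structure(x)
  x
}

validate_structure <- function(x) {
  a <- x$atoms
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    stop("non-finite atom coordinates")
  if (any(!is.na(a$radius) & a$radius < 0)) stop("negative atom radius")
  key <- paste(a$chain, a$resid, a$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name): ",
         key[duplicated(key)][1])
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    if (is.unsorted(unique(r), strictly = TRUE) || is.unsorted(r))
      stop("residue indices not increasing in chain ", ch)
  }
  if (!isTRUE(x$toy)) {
    per_res <- split(a$name, paste(a$chain, a$resid))
    no_ca <- !vapply(per_res, function(nm) "CA" %in% nm, logical(1))
    if (any(no_ca))
      stop("residue(s) without CA atom: ",
           paste(names(per_res)[no_ca][1:min(3, sum(no_ca))], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.ff_structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resid")]))
  cat(sprintf("<ff_structure> %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(a), nres, length(unique(a$chain)),
              paste(unique(a$chain), collapse = "")))
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Chains of a structure
#' @param structure an `ff_structure`.
#' @return character vector of chain ids in order of appearance.
#' @export
structure_chains <- function(structure) unique(structure$atoms$chain)

n_residues <- function(structure, chain = NULL) {
  a <- structure$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, ]
  nrow(unique(a[, c("chain", "resid")]))
}

coords <- function(structure) as.matrix(structure$atoms[, c("x", "y", "z")])

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Coordinates of one named atom per residue for a chain (default CA).
chain_atom_coords <- function(structure, chain, atom = "CA") {
  a <- structure$atoms
  a <- a[a$chain == chain & a$name == atom, ]
  a <- a[order(a$resid), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resid
  m
}

#' Extract the 1-letter sequence of a chain
#'
#' @param structure an `ff_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return object of class `ff_sequence`: list with `id` and `residues`
#'   (named character vector, names = 1-based residue positions). Residues
#'   with non-canonical 3-letter codes become "X" with a warning.
#' @export
extract_sequence <- function(structure, chain = structure_chains(structure)[1]) {
  a <- structure$atoms
  if (!chain %in% a$chain) stop("chain not present: ", chain)
  a <- a[a$chain == chain, ]
  res <- unique(a[, c("resid", "resname")])
  res <- res[order(res$resid), ]
  one <- aa_three_to_one(res$resname)
  if (anyNA(one)) {
    warning("non-canonical residue(s) replaced with X: ",
            paste(unique(res$resname[is.na(one)]), collapse = ", "))
    one[is.na(one)] <- "X"
  }
  structure(list(id = chain,
                 residues = structure(one, names = res$resid)),
            class = "ff_sequence")
}

#' @export
print.ff_sequence <- function(x, ...) {
  cat(sprintf("<ff_sequence> %s (%d residues)\n%s\n", x$id,
              length(x$residues), paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
length.ff_sequence <- function(x) length(x$residues)

sequence_string <- function(seq) paste(seq$residues, collapse = "")

# Assemble an ff_structure from per-residue atom position lists.
# residues: list of lists; each element has resname and a named list `atoms`
# of 3-vectors in the order they should be written.
assemble_structure <- function(residues, chain = "A", metadata = "",
                               toy = FALSE, start_resid = 1) {
  rows <- lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    nm <- names(r$atoms)
    xyz <- do.call(rbind, r$atoms)
    data.frame(name = nm, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               resid = start_resid + i - 1L, resname = r$resname,
               chain = chain, stringsAsFactors = FALSE)
  })
  ff_structure(do.call(rbind, rows), metadata = metadata, toy = toy)
}

# Build a full peptide (backbone + side chains) from sequence + torsions.
# chi: list per residue (or NULL for defaults).
build_peptide <- function(seq1, phi, psi, chi = NULL, chain = "A",
                          metadata = "", omega = NULL) {
  n <- nchar(seq1)
  codes <- strsplit(seq1, "")[[1]]
  res3 <- aa_one_to_three(codes)
  if (anyNA(res3)) stop("non-canonical 1-letter code in sequence")
  bb <- build_backbone(phi, psi, omega)
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    p <- bb[[i]]
    ch <- if (is.null(chi) || is.null(chi[[i]])) DEFAULT_CHI else chi[[i]]
    sc <- build_sidechain(res3[i], p$N, p$CA, p$C, ch)
    atoms <- c(list(N = p$N, CA = p$CA, C = p$C, O = p$O), sc)
    residues[[i]] <- list(resname = res3[i], atoms = atoms)
  }
  assemble_structure(residues, chain = chain, metadata = metadata)
}
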