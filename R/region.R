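# Stability-region analysis of an amyloid monomer: secondary structure from
# backbone dihedrals (plus a DSSP-style backbone H-bond criterion), numerical
# SASA, salt-bridge detection, and the six-category region classification
# (hydrophobic core, hydrophilic surface, beta sheets, beta turns, salt
# bridges, polar regions).

#' Region-analysis configuration
#'
#' @param core_threshold relative SASA below which a hydrophobic residue is
#'   core (default 0.25).
#' @param surface_threshold relative SASA at or above which a polar residue
#'   is surface (default 0.40).
#' @param salt_cutoff salt-bridge charged-group distance cutoff, A.
#' @param probe SASA probe radius, A.
#' @param max_turn_len longest non-strand run between strands still counted
#'   as a turn; 6 accommodates the canonical Amylin turn S19-G24.
#' @param hydrophobic_set,polar_set residue-class overrides (1-letter codes).
#' @param hbond_energy_cutoff DSSP-style H-bond energy threshold, kcal/mol.
#' @return list of class `ff_region_config`.
#' @export
region_config <- function(core_threshold = 0.25, surface_threshold = 0.40,
                          salt_cutoff = 4.5, probe = 1.4, max_turn_len = 6,
                          hydrophobic_set = HYDROPHOBIC_SET,
                          polar_set = POLAR_SET,
                          hbond_energy_cutoff = -0.5) {
  structure(list(core_threshold = core_threshold,
                 surface_threshold = surface_threshold,
                 salt_cutoff = salt_cutoff, probe = probe,
                 max_turn_len = max_turn_len,
                 hydrophobic_set = hydrophobic_set, polar_set = polar_set,
                 hbond_energy_cutoff = hbond_energy_cutoff),
            class = "ff_region_config")
}

backbone_of_chain <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, ]
  resids <- sort(unique(a$resid))
  get <- function(resid, name) {
    r <- a[a$resid == resid & a$name == name, ]
    if (!nrow(r))
      stop(sprintf("missing backbone atom %s in residue %s%d (%s)",
                   name, chain, resid, a$resname[a$resid == resid][1]),
           call. = FALSE)
    c(r$x[1], r$y[1], r$z[1])
  }
  list(resids = resids,
       N = lapply(resids, get, name = "N"),
       CA = lapply(resids, get, name = "CA"),
       C = lapply(resids, get, name = "C"),
       O = lapply(resids, get, name = "O"))
}

# DSSP-style electrostatic backbone H-bond energy between donor residue i
# (N-H) and acceptor residue j (C=O); amide H placed geometrically.
dssp_hbond_energy <- function(bb, i, j) {
  Ni <- bb$N[[i]]; Oj <- bb$O[[j]]; Cj <- bb$C[[j]]
  # H on N: opposite the bisector of C(i-1)->N and CA->N directions
  H <- if (i > 1) {
    d <- unit(unit(Ni - bb$C[[i - 1]]) + unit(Ni - bb$CA[[i]]))
    Ni + d
  } else Ni + unit(Ni - bb$CA[[i]])
  q1q2 <- 0.42 * 0.20 * 332
  q1q2 * (1 / vnorm(Ni - Oj) + 1 / vnorm(H - Cj) -
          1 / vnorm(H - Oj) - 1 / vnorm(Ni - Cj))
}

#' Assign secondary-structure labels (E/T/C)
#'
#' Strand (E): backbone dihedrals in the beta region (phi in [-180, -45],
#' psi >= 45 or <= -135) for at least 2 consecutive residues, or
#' participation in a cross-strand backbone H-bond (DSSP-style electrostatic
#' energy below the cutoff, sequence separation >= 3 or different chain).
#' Turn (T): runs of at most `max_turn_len` non-E residues flanked by E.
#' Everything else is coil (C).
#'
#' @param structure an `ff_structure` with complete backbones.
#' @param config a [region_config()].
#' @return character vector of labels (one per residue, all chains in order)
#'   with names "chain:resid".
#' @export
assign_secondary_structure <- function(structure, config = region_config()) {
  out <- c()
  chains <- structure_chains(structure)
  # gather backbones (also validates their completeness)
  bbs <- lapply(chains, backbone_of_chain, structure = structure)
  names(bbs) <- chains
  for (ch in chains) {
    bb <- bbs[[ch]]
    n <- length(bb$resids)
    phi <- psi <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i > 1)
        phi[i] <- dihedral_angle(bb$C[[i - 1]], bb$N[[i]], bb$CA[[i]], bb$C[[i]])
      if (i < n)
        psi[i] <- dihedral_angle(bb$N[[i]], bb$CA[[i]], bb$C[[i]], bb$N[[i + 1]])
    }
    phi_ok <- is.na(phi) | (phi >= -180 & phi <= -45)
    psi_ok <- is.na(psi) | psi >= 45 | psi <= -135
    eligible <- phi_ok & psi_ok
    # terminal residues only join a strand through a defined neighbour
    e <- rep(FALSE, n)
    r <- rle(eligible)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values))
      if (r$values[k] && r$lengths[k] >= 2)
        e[pos[k]:(pos[k + 1] - 1)] <- TRUE
    # H-bond criterion: a residue joins a strand when it sits in a ladder,
    # i.e. participates in at least two cross-strand backbone H-bonds
    # (helical i,i+3 / i,i+4 contacts are not strand)
    cutoff2 <- 7^2
    nhb <- integer(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) < 5) next
      if (sum((bb$N[[i]] - bb$O[[j]])^2) > cutoff2) next
      if (dssp_hbond_energy(bb, i, j) < config$hbond_energy_cutoff) {
        nhb[i] <- nhb[i] + 1L; nhb[j] <- nhb[j] + 1L
      }
    }
    e <- e | nhb >= 2L
    lab <- ifelse(e, "E", "C")
    # turns: short non-E runs flanked by E on both sides
    r <- rle(lab)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (r$values[k] != "C") next
      if (k == 1 || k == length(r$values)) next
      if (r$lengths[k] <= config$max_turn_len &&
          r$values[k - 1] == "E" && r$values[k + 1] == "E")
        lab[pos[k]:(pos[k + 1] - 1)] <- "T"
    }
    names(lab) <- paste0(ch, ":", bb$resids)
    out <- c(out, lab)
  }
  out
}

# Reference maximum accessibilities: SASA of X in an extended Gly-X-Gly
# tripeptide built with the package's own templates and radii (computed once
# per session and cached, so numerator and denominator share geometry
# conventions).
max_sasa_env <- new.env(parent = emptyenv())

max_sasa_gxg <- function(probe = 1.4) {
  key <- paste0("p", probe)
  if (!is.null(max_sasa_env[[key]])) return(max_sasa_env[[key]])
  vals <- vapply(names(AA3), function(res3) {
    s <- build_peptide(paste0("G", AA3[[res3]], "G"),
                       phi = rep(-120, 3), psi = rep(120, 3),
                       chi = list(NULL, c(180, 180, 180, 180), NULL))
    s <- assign_parameters(s, charged_termini = FALSE)
    area <- .sasa_cpp(coords(s), s$atoms$radius, probe = probe, npts = 960)
    sum(area[s$atoms$resid == 2])
  }, numeric(1))
  names(vals) <- unname(AA3[names(vals)])
  max_sasa_env[[key]] <- vals
  vals
}

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley numerical SASA (default 240 sphere points per atom).
#' Relative accessibility divides each residue's SASA by the accessibility
#' of X in an extended Gly-X-Gly tripeptide computed with the same radii.
#'
#' @param structure an `ff_structure`; radii are auto-assigned from the
#'   bundled table when absent.
#' @param probe probe radius, A (default 1.4).
#' @param n_points sphere points per atom (>= 240 recommended).
#' @return data.frame with chain, resid, resname, sasa (A^2) and rel_sasa.
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 240) {
  if (nrow(structure$atoms) == 0) stop("SASA of an empty structure")
  if (anyNA(structure$atoms$radius))
    structure <- assign_parameters(structure, charged_termini = FALSE)
  # canonicalise the orientation (principal-axis frame, proper rotation)
  # so the sphere-point sampling, and hence the SASA, is exactly invariant
  # under rigid motion of the input
  xyz <- coords(structure)
  if (nrow(xyz) > 2) {
    c0 <- colMeans(xyz)
    xc <- sweep(xyz, 2, c0)
    ev <- eigen(crossprod(xc), symmetric = TRUE)$vectors
    # deterministic axis signs; keep a proper rotation
    for (k in 1:2) if (ev[which.max(abs(ev[, k])), k] < 0) ev[, k] <- -ev[, k]
    ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
                 ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
                 ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
    xyz <- xc %*% ev
  }
  area <- .sasa_cpp(xyz, structure$atoms$radius,
                    probe = probe, npts = n_points)
  a <- structure$atoms
  key <- paste(a$chain, a$resid)
  per <- rowsum(area, key)
  ord <- unique(key)
  res <- unique(a[, c("chain", "resid", "resname")])
  res <- res[match(ord, paste(res$chain, res$resid)), ]
  res$sasa <- per[match(ord, rownames(per)), 1]
  one <- aa_three_to_one(res$resname)
  mx <- max_sasa_gxg(probe)[one]
  res$rel_sasa <- pmin(1, res$sasa / unname(mx))
  rownames(res) <- NULL
  res
}

#' Detect salt bridges
#'
#' Returns every acidic-basic residue pair among ASP-LYS, ASP-ARG, GLU-LYS
#' and GLU-ARG whose charged-group distance (minimum over the groups'
#' reference atoms: ASP OD1/OD2, GLU OE1/OE2, LYS NZ, ARG NH1/NH2/NE) is
#' below the cutoff.
#'
#' @param structure an `ff_structure`.
#' @param cutoff distance cutoff, A (default 4.5).
#' @return data.frame (possibly empty) with the two residues and their
#'   distance, sorted by distance.
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.5) {
  a <- structure$atoms
  grp <- a[a$resname %in% names(CHARGED_GROUP_ATOMS), ]
  empty <- data.frame(chain_a = character(), resid_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resid_b = integer(), resname_b = character(),
                      distance = numeric())
  if (!nrow(grp)) return(empty)
  keep <- mapply(function(rn, nm) nm %in% CHARGED_GROUP_ATOMS[[rn]],
                 grp$resname, grp$name)
  grp <- grp[keep, ]
  acid <- grp[grp$resname %in% c("ASP", "GLU"), ]
  base <- grp[grp$resname %in% c("LYS", "ARG"), ]
  if (!nrow(acid) || !nrow(base)) return(empty)
  out <- list()
  for (ra in unique(paste(acid$chain, acid$resid))) {
    aa <- acid[paste(acid$chain, acid$resid) == ra, ]
    for (rb in unique(paste(base$chain, base$resid))) {
      bb <- base[paste(base$chain, base$resid) == rb, ]
      d2 <- outer(seq_len(nrow(aa)), seq_len(nrow(bb)), Vectorize(function(i, j)
        sum((c(aa$x[i], aa$y[i], aa$z[i]) - c(bb$x[j], bb$y[j], bb$z[j]))^2)))
      d <- sqrt(min(d2))
      if (d < cutoff)
        out[[length(out) + 1L]] <- data.frame(
          chain_a = aa$chain[1], resid_a = aa$resid[1], resname_a = aa$resname[1],
          chain_b = bb$chain[1], resid_b = bb$resid[1], resname_b = bb$resname[1],
          distance = d)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$distance), ]
}

#' Classify the six stability-region categories
#'
#' Per-residue membership in hydrophobic core (hydrophobic residue with
#' relative SASA below the core threshold, plus the glycine context rule:
#' a buried Gly sequence-adjacent to a core residue joins the core),
#' hydrophilic surface (polar residue at or above the surface threshold),
#' beta sheet (label E), beta turn (label T), salt-bridge membership and
#' polar region (all polar residues); histidine counts as polar, D/E/K/R as
#' charged.
#'
#' @param structure an `ff_structure`.
#' @param config a [region_config()].
#' @return object of class `ff_region_annotation`: data.frame `residues`
#'   (one row per residue with flags), `salt_bridges`, `turn_runs` and the
#'   config used.
#' @export
classify_regions <- function(structure, config = region_config()) {
  ss <- assign_secondary_structure(structure, config)
  # denser sphere sampling than the compute_sasa default so that category
  # membership near the thresholds is stable under rigid motion
  sasa <- compute_sasa(structure, probe = config$probe, n_points = 960)
  sasa$aa <- aa_three_to_one(sasa$resname)
  sasa$aa[is.na(sasa$aa)] <- "X"
  key <- paste0(sasa$chain, ":", sasa$resid)
  sasa$ss <- unname(ss[key])
  bridges <- detect_salt_bridges(structure, cutoff = config$salt_cutoff)
  bridge_keys <- c(paste0(bridges$chain_a, ":", bridges$resid_a),
                   paste0(bridges$chain_b, ":", bridges$resid_b))

  hydro <- sasa$aa %in% config$hydrophobic_set
  polar <- sasa$aa %in% config$polar_set
  core <- hydro & sasa$rel_sasa < config$core_threshold
  # glycine context rule: buried Gly next to a core residue joins the core
  repeat {
    gly_ctx <- sasa$aa == "G" & !core & sasa$rel_sasa < config$core_threshold
    add <- rep(FALSE, nrow(sasa))
    for (i in which(gly_ctx)) {
      nb <- which(sasa$chain == sasa$chain[i] &
                  abs(sasa$resid - sasa$resid[i]) == 1)
      if (any(core[nb])) add[i] <- TRUE
    }
    if (!any(add)) break
    core <- core | add
  }
  res <- data.frame(
    chain = sasa$chain, resid = sasa$resid, aa = sasa$aa, ss = sasa$ss,
    sasa = sasa$sasa, rel_sasa = sasa$rel_sasa,
    hydrophobic_core = core,
    hydrophilic_surface = polar & sasa$rel_sasa >= config$surface_threshold,
    beta_sheet = sasa$ss == "E",
    beta_turn = sasa$ss == "T",
    salt_bridge_member = key %in% bridge_keys,
    polar_region = polar,
    charged = sasa$aa %in% CHARGED_SET,
    stringsAsFactors = FALSE)

  # turn runs (per chain) with their centre residues
  turn_runs <- list()
  for (ch in unique(res$chain)) {
    sub <- res[res$chain == ch, ]
    r <- rle(sub$ss == "T")
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      ids <- sub$resid[pos[k]:(pos[k + 1] - 1)]
      centre <- ids[ceiling(length(ids) / 2)]  # left-of-centre when even
      turn_runs[[length(turn_runs) + 1L]] <-
        list(chain = ch, resids = ids, centre = centre)
    }
  }
  structure(list(residues = res, salt_bridges = bridges,
                 turn_runs = turn_runs, config = config),
            class = "ff_region_annotation")
}

#' @export
print.ff_region_annotation <- function(x, ...) {
  r <- x$residues
  cats <- c("hydrophobic_core", "hydrophilic_surface", "beta_sheet",
            "beta_turn", "salt_bridge_member", "polar_region")
  cat("<ff_region_annotation>", nrow(r), "residues; six categories:\n")
  for (cc in cats)
    cat(sprintf("  %-20s %s\n", cc,
                paste0(r$aa[r[[cc]]], r$resid[r[[cc]]], collapse = " ")))
  invisible(x)
}

#' Number of region categories evaluated by the classifier
#' @param annotation an `ff_region_annotation`.
#' @return character vector of the category names (length 6).
#' @export
region_categories <- function(annotation) {
  c("hydrophobic_core", "hydrophilic_surface", "beta_sheet", "beta_turn",
    "salt_bridge_member", "polar_region")
}

#' Export a region annotation
#' @param annotation an `ff_region_annotation`.
#' @param path output file.
#' @param format "tsv" or "json".
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(annotation$residues, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(residues = annotation$residues,
                              salt_bridges = annotation$salt_bridges),
                         path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
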