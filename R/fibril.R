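# Fibril assembly by rigid affine transforms, light energy minimization, and
# the geometry-parameter stability landscape.

#' Fibril geometry
#'
#' Defaults follow the canonical Amylin fibril parameters: 9 degrees of
#' rotation per monomer about the fibril axis, 5.0 A axial rise (the
#' inter-monomer hydrogen-bonding distance), 3.0 A packing offset between
#' the two protofibril stacks.
#'
#' @param rotation rotation per monomer, degrees.
#' @param rise axial rise per monomer, A (> 0).
#' @param packing perpendicular offset of the second stack, A.
#' @param n_monomers monomers per stack (>= 1).
#' @param n_stacks 1 or 2.
#' @param axis fibril axis (unit 3-vector); NULL lets [build_fibril()] use
#'   the principal axis of the monomer's strand C-alpha atoms.
#' @return object of class `ff_fibril_geometry`.
#' @export
fibril_geometry <- function(rotation = 9, rise = 5.0, packing = 3.0,
                            n_monomers = 1L, n_stacks = 1L,
                            axis = c(0, 0, 1)) {
  if (rise <= 0) stop("axial_rise must be positive")
  if (n_monomers < 1) stop("n_monomers must be >= 1")
  if (!n_stacks %in% 1:2) stop("n_stacks must be 1 or 2")
  if (!is.null(axis)) axis <- unit(axis)
  structure(list(rotation = rotation, rise = rise, packing = packing,
                 n_monomers = as.integer(n_monomers),
                 n_stacks = as.integer(n_stacks), axis = axis),
            class = "ff_fibril_geometry")
}

# A deterministic unit vector perpendicular to the axis.
perp_of_axis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(axis, ref))
}

#' Rigid transform for monomer k of a fibril
#'
#' Monomer k (0-based) is rotated by k*rotation about the fibril axis
#' (through `centre`) and translated k*rise along it. Monomers of stack 1
#' are additionally flipped 180 degrees about an axis-perpendicular (the
#' 2-fold symmetry of a 2-stack) and offset by the packing distance along
#' that perpendicular.
#'
#' @param geometry an `ff_fibril_geometry` with a concrete axis.
#' @param k 0-based monomer index (k < n_monomers).
#' @param stack 0 or 1.
#' @param centre point the axis passes through (default origin).
#' @return an `ff_transform`: list(rotation = 3x3, translation = 3-vector);
#'   apply as `xyz %*% t(rotation) + translation`.
#' @export
monomer_transform <- function(geometry, k, stack = 0, centre = c(0, 0, 0)) {
  if (k < 0 || k >= geometry$n_monomers)
    stop("monomer index k = ", k, " out of range [0, ",
         geometry$n_monomers - 1, "]")
  ax <- geometry$axis
  if (is.null(ax)) stop("geometry has no concrete axis")
  R <- rotation_about_axis(ax, k * geometry$rotation * pi / 180)
  t0 <- as.numeric(centre - R %*% centre) + k * geometry$rise * ax
  if (stack == 1) {
    p <- perp_of_axis(ax)
    Rf <- rotation_about_axis(p, pi)
    # flip about the perpendicular through centre, then pack along it,
    # then the stack-0 screw transform
    tf <- as.numeric(centre - Rf %*% centre) + geometry$packing * p
    R2 <- R %*% Rf
    t2 <- as.numeric(R %*% tf) + t0
    return(structure(list(rotation = R2, translation = t2),
                     class = "ff_transform"))
  }
  structure(list(rotation = R, translation = t0), class = "ff_transform")
}

apply_transform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, `+`)
}

compose_transforms <- function(a, b) {
  # (a o b)(x) = a(b(x))
  structure(list(rotation = a$rotation %*% b$rotation,
                 translation = as.numeric(a$rotation %*% b$translation) +
                   a$translation),
            class = "ff_transform")
}

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Assemble a fibril from a monomer
#'
#' Replicates a single-chain monomer into n_monomers x n_stacks chains,
#' each under its rigid [monomer_transform()] about the fibril axis through
#' the monomer centroid. Intra-chain geometry is preserved exactly.
#'
#' @param monomer single-chain `ff_structure`.
#' @param geometry an `ff_fibril_geometry`; a NULL axis is replaced by the
#'   principal axis of the monomer's strand C-alpha atoms (all C-alpha if no
#'   strand is detected).
#' @return multi-chain `ff_structure` with chains A, B, C, ...
#' @export
build_fibril <- function(monomer, geometry = fibril_geometry()) {
  if (length(structure_chains(monomer)) != 1)
    stop("monomer must be single-chain")
  nchains <- geometry$n_monomers * geometry$n_stacks
  if (nchains > length(CHAIN_ALPHABET))
    stop("chain-id alphabet exhausted (> 62 chains); write the fibril in ",
         "segments instead")
  if (is.null(geometry$axis)) geometry$axis <- fibril_axis(monomer)
  xyz <- coords(monomer)
  centre <- colMeans(xyz)
  tmpl <- monomer$atoms
  out <- vector("list", nchains)
  ci <- 0L
  for (stack in seq_len(geometry$n_stacks) - 1L) {
    for (k in seq_len(geometry$n_monomers) - 1L) {
      ci <- ci + 1L
      tr <- monomer_transform(geometry, k, stack, centre)
      b <- tmpl
      nxyz <- apply_transform(xyz, tr)
      b$x <- nxyz[, 1]; b$y <- nxyz[, 2]; b$z <- nxyz[, 3]
      b$chain <- CHAIN_ALPHABET[ci]
      out[[ci]] <- b
    }
  }
  s <- ff_structure(do.call(rbind, out),
                    metadata = sprintf(
                      "fibril: %d monomer(s) x %d stack(s), %.1f deg, %.2f A rise",
                      geometry$n_monomers, geometry$n_stacks,
                      geometry$rotation, geometry$rise),
                    toy = monomer$toy)
  s$params <- monomer$params
  s
}

# Principal axis of the strand C-alpha subset (fallback: all C-alpha).
fibril_axis <- function(monomer) {
  ss <- tryCatch(assign_secondary_structure(monomer), error = function(e) NULL)
  ca <- chain_atom_coords(monomer, structure_chains(monomer)[1], "CA")
  if (!is.null(ss) && sum(ss == "E") >= 3)
    ca <- ca[ss == "E", , drop = FALSE]
  v <- svd(scale(ca, scale = FALSE))$v[, 1]
  unit(v)
}

#' Light energy minimization
#'
#' Steepest descent on the soft-core Lennard-Jones + Coulomb energy with an
#' adaptive step, stopping at the step limit or when the largest atomic
#' gradient falls below `gtol`. Returns the relaxed structure and the
#' enthalpy drift (initial minus final energy, >= 0 on success).
#'
#' @param structure parameterized `ff_structure`.
#' @param max_steps step limit (default 500).
#' @param gtol gradient norm stop, kcal/mol/A.
#' @param cutoff pair cutoff, A.
#' @return list(structure, drift, steps, converged, failed).
#' @export
relax <- function(structure, max_steps = 500L, gtol = 0.1, cutoff = 10) {
  structure <- with_exclusions(structure)
  e <- pairwise_terms(structure, cutoff, gradient = TRUE, softcore = TRUE)
  e0 <- e$vdw + e$coulomb
  if (!is.finite(e0))
    return(list(structure = structure, drift = NA_real_, steps = 0L,
                converged = FALSE, failed = TRUE))
  xyz <- coords(structure)
  step <- 0.02
  ecur <- e0
  g <- e$gradient
  converged <- FALSE
  steps <- 0L
  for (i in seq_len(max_steps)) {
    steps <- i
    gmax <- sqrt(max(rowSums(g^2)))
    if (gmax < gtol) { converged <- TRUE; break }
    trial <- xyz - step * g / max(gmax, 1)
    et <- pairwise_terms(set_coords(structure, trial), cutoff,
                         gradient = TRUE, softcore = TRUE)
    enew <- et$vdw + et$coulomb
    if (is.finite(enew) && enew < ecur) {
      xyz <- trial; ecur <- enew; g <- et$gradient
      step <- min(step * 1.2, 0.5)
    } else {
      step <- step * 0.5
      if (step < 1e-6) { converged <- TRUE; break }
    }
  }
  list(structure = set_coords(structure, xyz), drift = e0 - ecur,
       steps = steps, converged = converged, failed = FALSE)
}

#' Fibril stability landscape scan
#'
#' Exhausts a grid of (rotation, rise, packing) values: for each
#' combination an n_probe fibril is built, its initial Lennard-Jones and
#' Coulomb terms recorded, and a light relaxation run to measure the
#' enthalpy drift. The selected optimum minimises the initial energy among
#' the points whose drift is within `drift_margin` of the smallest drift
#' (a tolerance form of drift-first lexicographic selection).
#'
#' @param monomer parameterized single-chain `ff_structure`.
#' @param rotation_grid,rise_grid,packing_grid non-empty numeric grids.
#' @param n_probe monomers in each probe fibril (default 4).
#' @param n_stacks stacks in each probe fibril.
#' @param axis fibril axis (default: derived from the monomer).
#' @param relax_steps minimization steps per point.
#' @param drift_margin kcal/mol tolerance on the drift criterion.
#' @return list(table = data.frame of all points, optimum = selected row).
#' @export
landscape_scan <- function(monomer, rotation_grid, rise_grid,
                           packing_grid = 3.0, n_probe = 4L, n_stacks = 1L,
                           axis = NULL, relax_steps = 150L,
                           drift_margin = 5) {
  if (!length(rotation_grid) || !length(rise_grid) || !length(packing_grid))
    stop("parameter grids must be non-empty")
  if (is.null(axis)) axis <- fibril_axis(monomer)
  grid <- expand.grid(rotation = rotation_grid, rise = rise_grid,
                      packing = packing_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- fibril_geometry(rotation = grid$rotation[i], rise = grid$rise[i],
                         packing = grid$packing[i], n_monomers = n_probe,
                         n_stacks = n_stacks, axis = axis)
    fib <- with_exclusions(build_fibril(monomer, g))
    pt <- pairwise_terms(fib, gradient = FALSE, softcore = TRUE)
    rx <- relax(fib, max_steps = relax_steps)
    data.frame(rotation = grid$rotation[i], rise = grid$rise[i],
               packing = grid$packing[i],
               drift = rx$drift, vdw0 = pt$vdw, coul0 = pt$coulomb,
               failed = rx$failed)
  })
  tab <- do.call(rbind, res)
  ok <- !tab$failed & is.finite(tab$drift)
  if (!any(ok)) stop("all landscape points failed relaxation")
  feasible <- ok & tab$drift <= min(tab$drift[ok]) + drift_margin
  e0 <- tab$vdw0 + tab$coul0
  sel <- which(feasible)[which.min(e0[feasible])]
  tab$selected <- seq_len(nrow(tab)) == sel
  list(table = tab, optimum = tab[sel, ])
}

#' Write a landscape table as TSV
#' @param scan result of [landscape_scan()].
#' @param path output file.
#' @export
write_landscape <- function(scan, path) {
  utils::write.table(scan$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
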