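# Free-energy decomposition: F_E = F_solv + F_coulomb + F_vdw.
# Pairwise terms use a 10 A cutoff with standard 1-2/1-3 exclusions and
# configurable 1-4 scaling; the solvation term comes from the dipolar
# Poisson-Boltzmann-Langevin solver.

COULOMB_KE <- 332.0636  # kcal*A/(mol*e^2)
KB_KCAL <- 0.0019872041  # kcal/(mol*K)

pairwise_terms <- function(structure, cutoff = 10, gradient = FALSE,
                           softcore = FALSE) {
  a <- structure$atoms
  if (anyNA(a$charge) || anyNA(a$sigma))
    stop("parameters not assigned; call assign_parameters() first")
  ex <- structure$exclusions
  if (is.null(ex)) ex <- exclusion_lists(structure)
  p <- structure$params
  if (is.null(p)) p <- list(scale14_lj = 1.0, scale14_coul = 1.0)
  .pair_energy_cpp(coords(structure), a$charge, a$sigma, a$eps,
                   ex$excl, ex$pairs14, cutoff = cutoff,
                   scale14_lj = p$scale14_lj, scale14_coul = p$scale14_coul,
                   gradient = gradient, softcore = softcore)
}

# Cache the exclusion lists on the structure (topology does not change under
# rigid transforms or minimization).
with_exclusions <- function(structure) {
  if (is.null(structure$exclusions))
    structure$exclusions <- exclusion_lists(structure)
  structure
}

#' Lennard-Jones energy
#'
#' Sum over non-excluded pairs within the cutoff of
#' 4*eps*((sigma/r)^12 - (sigma/r)^6) with Lorentz-Berthelot combining.
#'
#' @param structure parameterized `ff_structure`.
#' @param cutoff pair cutoff, Angstrom.
#' @return energy in kcal/mol.
#' @export
vdw_energy <- function(structure, cutoff = 10) {
  pairwise_terms(with_exclusions(structure), cutoff)$vdw
}

#' Coulomb energy
#'
#' Sum over non-excluded pairs within the cutoff of k_e q_i q_j / r with
#' k_e = 332.0636 kcal*A/(mol*e^2).
#'
#' @inheritParams vdw_energy
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(structure, cutoff = 10) {
  pairwise_terms(with_exclusions(structure), cutoff)$coulomb
}

#' Full free-energy breakdown
#'
#' @param structure parameterized `ff_structure`.
#' @param solver_cfg a [solver_config()]; with `p0 = 0` and `C_dip = 0` the
#'   solvation term is identically zero (vacuum limit).
#' @param cutoff pairwise cutoff, Angstrom.
#' @return an `ff_energy`: list with F_solv, F_coulomb, F_vdw, F_E (exact
#'   sum of the three), plus solver convergence diagnostics.
#' @export
free_energy <- function(structure, solver_cfg = solver_config(),
                        cutoff = 10) {
  structure <- with_exclusions(structure)
  pt <- pairwise_terms(structure, cutoff)
  if (solver_cfg$p0 == 0 && solver_cfg$C_dip == 0) {
    solv <- list(F_solv = 0, converged = TRUE, residual = 0, N_w = 0)
  } else {
    solv <- solvation_free_energy(structure, solver_cfg)
  }
  structure(list(F_solv = solv$F_solv, F_coulomb = pt$coulomb,
                 F_vdw = pt$vdw,
                 F_E = solv$F_solv + pt$coulomb + pt$vdw,
                 converged = solv$converged, residual = solv$residual,
                 N_w = solv$N_w),
            class = "ff_energy")
}

#' @export
print.ff_energy <- function(x, ...) {
  cat(sprintf(paste0("<ff_energy> F_E = %.3f kcal/mol\n",
                     "  F_solv    %12.3f\n  F_coulomb %12.3f\n",
                     "  F_vdw     %12.3f\n"),
              x$F_E, x$F_solv, x$F_coulomb, x$F_vdw))
  if (!isTRUE(x$converged))
    cat(sprintf("  (solver not converged; residual %.2e)\n", x$residual))
  invisible(x)
}
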