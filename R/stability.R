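# Stability metrics over per-length fibril energy profiles:
#   amyloidogenicity  dG = F_a1 - F_native
#   nucleation        dN = F_a4 - 4 * F_a1
#   elongation        dF~ = sum_j (F^i_aj - F^c_aj) / j
# and the three-stage filter-and-rank procedure.

#' Per-length fibril energy profile
#'
#' @param label mutation label (e.g. "L12E"), or "control".
#' @param lengths fibril lengths j (must contain 1, and 4 when the
#'   nucleation metric is wanted).
#' @param energies free energies F_{a_j} in kcal/mol, one per length.
#' @param F_native free energy of the (mutated) native monomer, kcal/mol.
#' @return object of class `ff_stability_profile`.
#' @export
stability_profile <- function(label, lengths, energies, F_native = NA_real_) {
  stopifnot(length(lengths) == length(energies))
  if (anyDuplicated(lengths)) stop("duplicate fibril lengths")
  o <- order(lengths)
  structure(list(label = label, lengths = as.integer(lengths[o]),
                 energies = energies[o], F_native = F_native),
            class = "ff_stability_profile")
}

profile_energy <- function(profile, j) {
  i <- match(j, profile$lengths)
  if (is.na(i))
    stop("profile '", profile$label, "' has no energy for length ", j)
  profile$energies[i]
}

#' Amyloidogenicity free energy dG = F_a1 - F_native
#'
#' Positive values mean the native-to-amyloid transition costs energy
#' (endothermic); mutations with negative dG are eliminated by the filter.
#'
#' @param profile an `ff_stability_profile` with F_native set.
#' @return kcal/mol.
#' @export
delta_g <- function(profile) {
  if (is.na(profile$F_native))
    stop("profile '", profile$label, "' has no native energy")
  profile_energy(profile, 1) - profile$F_native
}

#' Nucleation free energy dN = F_a4 - 4 * F_a1
#'
#' Energy of joining four free amyloid monomers into a fibril; more
#' negative values mean stronger (more stable) nucleation.
#'
#' @param profile an `ff_stability_profile` containing lengths 1 and 4.
#' @return kcal/mol.
#' @export
delta_n <- function(profile) {
  profile_energy(profile, 4) - 4 * profile_energy(profile, 1)
}

#' Length-averaged elongation stability dF~
#'
#' Sum over the shared lengths of (F^i_aj - F^c_aj)/j; positive values mean
#' fibrils weaker than the control.
#'
#' @param profile mutation profile.
#' @param control control (wild-type) profile on the same length set.
#' @return kcal/mol.
#' @export
delta_f_tilde <- function(profile, control) {
  miss <- setdiff(profile$lengths, control$lengths)
  miss2 <- setdiff(control$lengths, profile$lengths)
  if (length(miss) || length(miss2))
    stop("profiles defined on different length sets; missing lengths: ",
         paste(union(miss, miss2), collapse = ", "))
  j <- profile$lengths
  sum((profile$energies - control$energies[match(j, control$lengths)]) / j)
}

#' Filter and rank mutation profiles
#'
#' Stage 1 drops mutations with dG < 0 (spontaneous amyloid formation);
#' stage 2 drops mutations whose dN is at or below the control's (stronger
#' or equal nucleation); stage 3 ranks the survivors by dF~ descending
#' (most fibril-destabilizing first, ties broken by label).
#'
#' @param profiles list of `ff_stability_profile`.
#' @param control the control profile (needs F_native, lengths 1 and 4).
#' @return data.frame report: label, dG, dN, dF_tilde, stage_dropped
#'   (NA = survivor), rank (NA unless ranked).
#' @export
filter_and_rank <- function(profiles, control) {
  dN_c <- delta_n(control)
  rows <- lapply(profiles, function(p) {
    dg <- delta_g(p); dn <- delta_n(p); df <- delta_f_tilde(p, control)
    stage <- NA_integer_
    if (dg < 0) stage <- 1L
    else if (dn <= dN_c) stage <- 2L
    data.frame(label = p$label, dG = dg, dN = dn, dF_tilde = df,
               stage_dropped = stage, rank = NA_integer_,
               stringsAsFactors = FALSE)
  })
  rep <- if (length(rows)) do.call(rbind, rows)
         else data.frame(label = character(), dG = numeric(),
                         dN = numeric(), dF_tilde = numeric(),
                         stage_dropped = integer(), rank = integer())
  surv <- which(is.na(rep$stage_dropped))
  if (length(surv)) {
    o <- surv[order(-rep$dF_tilde[surv], rep$label[surv])]
    rep$rank[o] <- seq_along(o)
  }
  rep <- rep[order(rep$label), ]
  rep <- rep[order(!is.na(rep$stage_dropped), rep$rank, na.last = TRUE), ]
  rownames(rep) <- NULL
  structure(rep, class = c("ff_stability_report", "data.frame"),
            control = c(dG = delta_g(control), dN = dN_c))
}

#' Read stability profiles from a TSV
#'
#' Expected columns: mutation, j, F (kcal/mol); optional F_native column
#' (constant per mutation).
#'
#' @param path TSV file.
#' @return named list of `ff_stability_profile`.
#' @export
read_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mutation", "j", "F") %in% names(tab)))
  out <- lapply(split(tab, tab$mutation), function(d) {
    stability_profile(d$mutation[1], d$j, d$F,
                      F_native = if ("F_native" %in% names(d))
                        d$F_native[1] else NA_real_)
  })
  out
}

#' Write a stability report as JSON
#' @param report an `ff_stability_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(control = as.list(attr(report, "control")),
                            mutations = as.data.frame(report)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
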