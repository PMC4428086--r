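# Rule-based destabilizing mutation proposal, ranking, and side-chain
# replacement.
#
# Disruption methods (closed vocabulary):
#   core:    mutate a buried hydrophobic residue into a charged one
#   surface: mutate an exposed polar residue into a hydrophobic one
#   turn:    mutate the turn centre residue / any turn Gly into proline
#   bridge:  mutate one salt-bridge member into Ala
#   strand:  mutate unclaimed small/hydrophobic strand residues into charged
#            residues; the most central strand aromatic may receive proline

METHOD_CORE <- "Making core charged"
METHOD_SURFACE <- "Making protein surface hydrophobic"
METHOD_TURN_GLY <- "Mutating GLY at a turn"
METHOD_TURN <- "Mutating an amino acid at a turn"
METHOD_STRAND_CHARGED <- "Making an amino acid on a beta strand charged"
METHOD_STRAND <- "Mutating an amino acid on a beta strand"
METHOD_BRIDGE <- "Breaking a salt bridge"

DISRUPTION_METHODS <- c(METHOD_CORE, METHOD_SURFACE, METHOD_TURN_GLY,
                        METHOD_TURN, METHOD_STRAND_CHARGED, METHOD_STRAND,
                        METHOD_BRIDGE)

STRAND_SITE_WT <- c("A", "V", "L", "I", "F", "G")

#' Read a substitution policy
#'
#' A policy maps disruption methods to target residues: a `defaults` section
#' keyed by method (per-wild-type entries plus a `default` fallback) and an
#' `overrides` section keyed by residue position. The bundled `amylin_2015`
#' policy carries the position-specific targets for Amylin.
#'
#' @param path YAML policy file, or the name of a bundled policy
#'   ("amylin_2015").
#' @return object of class `ff_policy`.
#' @export
read_policy <- function(path = "amylin_2015") {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", "policies", paste0(path, ".yaml"),
                           package = "fibrilforge")
    if (!nzchar(bundled)) stop("policy not found: ", path)
    path <- bundled
  }
  y <- yaml::read_yaml(path)
  overrides <- y$overrides
  if (!is.null(overrides)) names(overrides) <- as.character(names(overrides))
  structure(list(defaults = y$defaults, overrides = overrides,
                 provenance = y$provenance %||% path),
            class = "ff_policy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

policy_target <- function(policy, method_key, position, wt) {
  ov <- policy$overrides[[as.character(position)]]
  if (!is.null(ov)) return(ov)
  d <- policy$defaults[[method_key]]
  if (!is.null(d[[wt]])) return(d[[wt]])
  if (!is.null(d[["default"]])) return(d[["default"]])
  stop(sprintf(paste0("substitution policy has no target for method '%s', ",
                      "wild-type %s (position %d); add a defaults or ",
                      "overrides entry"), method_key, wt, position),
       call. = FALSE)
}

candidate_df <- function(position = integer(), wt = character(),
                         target = character(), method = character()) {
  data.frame(position = as.integer(position), wt = wt, target = target,
             method = method, rank = rep(NA_integer_, length(position)),
             stringsAsFactors = FALSE)
}

#' Propose destabilizing point mutations
#'
#' Applies the disruption rules to a region annotation: every hydrophobic
#' core residue gets a charged target, every hydrophilic surface residue a
#' hydrophobic target, each turn's centre residue and every turn glycine get
#' proline, one member of each salt bridge gets alanine, and strand sites
#' chosen by the strand heuristic get charged targets (with the most central
#' strand aromatic receiving proline). Targets are resolved through the
#' policy (position override first, then per-(method, wild-type) defaults).
#'
#' @param annotation an `ff_region_annotation` (single chain).
#' @param sequence the matching `ff_sequence`.
#' @param policy an `ff_policy` (default: bundled `amylin_2015`).
#' @param strand_rule enable the strand-site heuristic (default TRUE).
#' @return data.frame of candidates (position, wt, target, method, rank)
#'   ordered by position then method; duplicates on (position, target)
#'   merged keeping the first-generated method.
#' @export
propose_mutations <- function(annotation, sequence,
                              policy = read_policy("amylin_2015"),
                              strand_rule = TRUE) {
  res <- annotation$residues
  if (nrow(res) != length(sequence))
    stop("annotation and sequence disagree in length")
  aa <- res$aa
  pos <- res$resid
  rows <- list()
  add <- function(p, wt, target, method) {
    if (wt == target) return()
    rows[[length(rows) + 1L]] <<- candidate_df(p, wt, target, method)
  }
  # 1. hydrophobic core -> charged
  for (i in which(res$hydrophobic_core))
    add(pos[i], aa[i], policy_target(policy, "core_charged", pos[i], aa[i]),
        METHOD_CORE)
  # 2. hydrophilic surface -> hydrophobic
  for (i in which(res$hydrophilic_surface))
    add(pos[i], aa[i],
        policy_target(policy, "surface_hydrophobic", pos[i], aa[i]),
        METHOD_SURFACE)
  # 3. strand sites (beta-sheet disruption)
  if (strand_rule) {
    claimed <- res$hydrophobic_core | res$hydrophilic_surface
    strand_sites <- res$beta_sheet & !claimed & aa %in% STRAND_SITE_WT
    for (i in which(strand_sites))
      add(pos[i], aa[i],
          policy_target(policy, "strand_charged", pos[i], aa[i]),
          METHOD_STRAND_CHARGED)
    arom <- which(res$beta_sheet & aa %in% c("F", "W", "Y"))
    if (length(arom)) {
      centre <- (min(pos) + max(pos)) / 2
      i <- arom[which.min(abs(pos[arom] - centre))]
      add(pos[i], aa[i], "P", METHOD_STRAND)
    }
  }
  # 4. turns: centre residue and every Gly -> proline
  for (tr in annotation$turn_runs) {
    i <- which(pos == tr$centre)
    add(tr$centre, aa[i], "P", METHOD_TURN)
    for (g in tr$resids[aa[match(tr$resids, pos)] == "G"])
      add(g, "G", "P", METHOD_TURN_GLY)
  }
  # 5. salt bridges: one member (the acidic one) -> alanine
  if (nrow(annotation$salt_bridges))
    for (k in seq_len(nrow(annotation$salt_bridges))) {
      b <- annotation$salt_bridges[k, ]
      add(b$resid_a, aa_three_to_one(b$resname_a), "A", METHOD_BRIDGE)
    }
  out <- if (length(rows)) do.call(rbind, rows) else candidate_df()
  # merge duplicates on (position, target), keeping the first method
  out <- out[!duplicated(paste(out$position, out$target)), ]
  out <- out[order(out$position, out$method), ]
  rownames(out) <- NULL
  out
}

#' Default aggregation-propensity scorer
#'
#' Sum over a 5-residue window centred on the site of the product of
#' beta-sheet propensity (Chou-Fasman) and hydrophobicity (Kyte-Doolittle)
#' for the mutated sequence. Lower values mean lower aggregation propensity.
#'
#' @param candidate one-row candidate data.frame (position, wt, target).
#' @param sequence an `ff_sequence`.
#' @return numeric score.
#' @export
aggregation_window_score <- function(candidate, sequence) {
  s <- sequence$residues
  posns <- as.integer(names(s))
  i <- match(candidate$position, posns)
  if (is.na(i)) stop("candidate position not in sequence")
  s[i] <- candidate$target
  win <- s[max(1, i - 2):min(length(s), i + 2)]
  sum(BETA_PROPENSITY[win] * KYTE_DOOLITTLE[win])
}

#' Rank mutation candidates
#'
#' Ranks ascending by scorer value (lower aggregation propensity first);
#' ties broken by position. A scorer failure leaves that candidate with an
#' unset rank and a warning.
#'
#' @param candidates candidate data.frame from [propose_mutations()].
#' @param sequence an `ff_sequence`.
#' @param scorer function(candidate, sequence) -> numeric.
#' @return the candidates with the `rank` column filled, sorted by rank.
#' @export
rank_candidates <- function(candidates, sequence,
                            scorer = aggregation_window_score) {
  if (!nrow(candidates)) stop("no candidates to rank")
  score <- vapply(seq_len(nrow(candidates)), function(i) {
    tryCatch(scorer(candidates[i, ], sequence),
             error = function(e) {
               warning("scorer failed for ", candidates$wt[i],
                       candidates$position[i], candidates$target[i], ": ",
                       conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  ord <- order(score, candidates$position, na.last = TRUE)
  rank <- integer(nrow(candidates))
  rank[ord] <- seq_len(nrow(candidates))
  rank[is.na(score)] <- NA_integer_
  candidates$rank <- rank
  candidates$score <- score
  candidates[ord, ]
}

#' Experimentally reported Amylin mutations
#'
#' The four literature mutations (S20G, S20K, N21L, N14L) shipped for
#' comparison; these are never emitted by the rule engine.
#' @return data.frame with position, wt, target, source = "experimental".
#' @export
experimental_mutations <- function() {
  data.frame(position = c(20L, 20L, 21L, 14L),
             wt = c("S", "S", "N", "N"),
             target = c("G", "K", "L", "L"),
             source = "experimental", stringsAsFactors = FALSE)
}

#' Apply a point mutation to a structure
#'
#' Replaces the side chain at the given position in every chain (the
#' backbone N/CA/C/O atoms are untouched); the new side chain comes from the
#' ideal-geometry template aligned on the local backbone frame, with chi1
#' chosen from a small rotamer set to minimise steric overlap.
#'
#' @param structure an `ff_structure`; the residue at `position` must match
#'   the candidate's wild-type in every chain.
#' @param mutation one-row data.frame with position, wt, target (as produced
#'   by [propose_mutations()]), or a string like "A13R".
#' @return the mutated structure; if no rotamer is clash-free the structure
#'   carries `attr(, "clash") = TRUE` and a warning is issued (relaxation is
#'   expected downstream).
#' @export
apply_mutation <- function(structure, mutation) {
  if (is.character(mutation)) {
    m <- regmatches(mutation, regexec("^([A-Z])(\\d+)([A-Z])$", mutation))[[1]]
    if (length(m) != 4) stop("cannot parse mutation string: ", mutation)
    mutation <- data.frame(position = as.integer(m[3]), wt = m[2],
                           target = m[4], stringsAsFactors = FALSE)
  }
  pos <- mutation$position
  target3 <- aa_one_to_three(mutation$target)
  a <- structure$atoms
  clash_any <- FALSE
  for (ch in unique(a$chain)) {
    rows <- a$chain == ch & a$resid == pos
    if (!any(rows))
      stop("position ", pos, " not present in chain ", ch)
    wt_here <- aa_three_to_one(a$resname[rows][1])
    if (!identical(wt_here, mutation$wt))
      stop(sprintf("wild-type mismatch at %s%d: structure has %s, candidate %s",
                   ch, pos, wt_here, mutation$wt))
    bbn <- c("N", "CA", "C", "O", "OXT")
    keep <- !rows | a$name %in% bbn
    get <- function(nm) unlist(a[rows & a$name == nm, c("x", "y", "z")])
    n <- get("N"); ca <- get("CA"); cc <- get("C")
    # rotamer search over chi1
    others <- as.matrix(a[keep & !(rows & a$name %in% bbn), c("x", "y", "z")])
    best <- NULL; best_score <- Inf
    for (chi1 in c(-65, 60, 180)) {
      sc <- build_sidechain(target3, n, ca, cc, c(chi1, 180, 180, 180))
      score <- 0
      if (length(sc) && nrow(others)) {
        scm <- do.call(rbind, sc)
        d <- sqrt(outer(rowSums(scm^2), rowSums(others^2), `+`) -
                  2 * scm %*% t(others))
        score <- sum(pmax(0, 3.0 - d)^2)
      }
      if (score < best_score) { best_score <- score; best <- sc }
    }
    if (best_score > 1.0) clash_any <- TRUE
    # rebuild the residue's rows: backbone kept, new side chain appended
    a$resname[rows] <- target3
    drop_rows <- rows & !(a$name %in% bbn)
    newrows <- NULL
    if (length(best)) {
      scm <- do.call(rbind, best)
      newrows <- data.frame(serial = 0L, name = names(best),
                            element = element_of_atom(names(best)),
                            x = scm[, 1], y = scm[, 2], z = scm[, 3],
                            charge = NA_real_, radius = NA_real_,
                            sigma = NA_real_, eps = NA_real_,
                            resid = pos, resname = target3, chain = ch,
                            stringsAsFactors = FALSE)
    }
    # splice: keep everything except the old side chain; insert new side
    # chain right after the residue's backbone atoms
    idx_res_last <- max(which(rows & a$name %in% bbn))
    a <- a[!drop_rows, ]
    idx_res_last <- idx_res_last - sum(drop_rows & seq_along(rows) < idx_res_last)
    if (!is.null(newrows))
      a <- rbind(a[seq_len(idx_res_last), ], newrows,
                 a[-seq_len(idx_res_last), , drop = FALSE])
    rows <- a$chain == ch & a$resid == pos  # refresh for safety
  }
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  structure$atoms <- a
  structure$exclusions <- NULL  # topology changed
  # parameters must be reassigned for the new residue
  if (!anyNA(structure$atoms$charge[structure$atoms$resid != pos]))
    structure <- assign_parameters(structure)
  if (clash_any) {
    warning("no clash-free rotamer at position ", pos,
            "; flagging for downstream relaxation")
    attr(structure, "clash") <- TRUE
  }
  validate_structure(structure)
  structure
}

#' Export candidates as a TSV table
#' @param candidates candidate data.frame.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
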