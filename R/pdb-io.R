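# Fixed-column PDB reading and writing.
#
# The reader implements the subset of the format the pipeline needs: ATOM /
# HETATM / TER / MODEL / ENDMDL records, altloc resolution (highest occupancy
# kept), insertion-code folding into a sequential renumbering (mapping kept in
# the structure metadata attribute), first-model selection for multi-model
# files, and optional PQR-style whitespace-delimited charge/radius columns.

parse_float <- function(s, what, lineno, line) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("malformed %s field on line %d: '%s'", what, lineno,
                 trimws(line)), call. = FALSE)
  v
}

#' Read a PDB (or PQR) file
#'
#' @param path file path.
#' @param model 1-based model index for multi-model files (default: first).
#' @param skip_het drop HETATM records (default TRUE).
#' @param format "pdb" for fixed columns, "pqr" for whitespace-delimited
#'   records whose last two fields are partial charge (e) and radius (A).
#' @return an `ff_structure`; for PQR input, charge and radius columns are
#'   filled. The insertion-code renumbering map (if any) is stored in
#'   `attr(structure, "renumber_map")`.
#' @export
read_pdb <- function(path, model = 1L, skip_het = TRUE, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM")
  is_het <- startsWith(rec, "HETATM")
  if (!any(is_atom | is_het))
    stop("no ATOM records in ", path, call. = FALSE)

  # Model selection: lines between the model-th MODEL and its ENDMDL, or all
  # lines if the file has no MODEL records.
  model_starts <- which(startsWith(rec, "MODEL"))
  keep <- rep(TRUE, length(lines))
  if (length(model_starts)) {
    if (model > length(model_starts))
      stop("model ", model, " requested but file has ", length(model_starts))
    ends <- which(startsWith(rec, "ENDMDL"))
    from <- model_starts[model]
    to <- ends[ends > from][1]
    if (is.na(to)) to <- length(lines)
    keep <- seq_along(lines) >= from & seq_along(lines) <= to
  }
  sel <- (is_atom | (!skip_het & is_het)) & keep
  idx <- which(sel)
  if (!length(idx))
    stop("no atoms selected (only HETATM records with skip_het=TRUE?) in ",
         path, call. = FALSE)

  if (format == "pdb") {
    ln <- lines[idx]
    name <- trimws(substr(ln, 13, 16))
    altloc <- substr(ln, 17, 17)
    resname <- trimws(substr(ln, 18, 20))
    chain <- substr(ln, 22, 22)
    resseq <- trimws(substr(ln, 23, 26))
    icode <- substr(ln, 27, 27)
    x <- mapply(parse_float, substr(ln, 31, 38), "x coordinate", idx, ln)
    y <- mapply(parse_float, substr(ln, 39, 46), "y coordinate", idx, ln)
    z <- mapply(parse_float, substr(ln, 47, 54), "z coordinate", idx, ln)
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    element <- trimws(substr(ln, 77, 78))
    element[element == ""] <- element_of_atom(name[element == ""])
    atoms <- data.frame(name = name, element = element, x = x, y = y, z = z,
                        resid = suppressWarnings(as.integer(resseq)),
                        resname = resname, chain = chain,
                        stringsAsFactors = FALSE)
    if (anyNA(atoms$resid))
      stop("malformed residue number field on line ",
           idx[which(is.na(atoms$resid))[1]], call. = FALSE)

    # Altloc: keep the highest-occupancy location of each alternative set.
    if (any(altloc != " ")) {
      key <- paste(chain, resseq, icode, name)
      ord <- order(key, -occ)
      dupe <- duplicated(key[ord])
      keep_rows <- sort(ord[!dupe])
      atoms <- atoms[keep_rows, ]
      icode <- icode[keep_rows]
    }

    # Insertion codes folded into sequential renumbering per chain.
    renumber_map <- NULL
    if (any(icode != " ")) {
      old_key <- paste(atoms$chain, atoms$resid, icode)
      new_resid <- integer(nrow(atoms))
      maps <- list()
      for (ch in unique(atoms$chain)) {
        i <- atoms$chain == ch
        uk <- unique(old_key[i])
        new_resid[i] <- match(old_key[i], uk)
        maps[[ch]] <- data.frame(chain = ch, original = uk,
                                 renumbered = seq_along(uk))
      }
      renumber_map <- do.call(rbind, maps)
      atoms$resid <- new_resid
    }
    s <- ff_structure(atoms, metadata = paste0("read from ", basename(path)),
                      toy = TRUE)
    s$toy <- !all(vapply(split(s$atoms$name, paste(s$atoms$chain, s$atoms$resid)),
                         function(nm) "CA" %in% nm, logical(1)))
    attr(s, "renumber_map") <- renumber_map
    return(s)
  }

  # PQR: whitespace-delimited; last two fields are charge and radius.
  ln <- lines[idx]
  parts <- strsplit(trimws(ln), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 10))
    stop("malformed PQR record on line ", idx[which(nf < 10)[1]], call. = FALSE)
  get <- function(k) vapply(parts, `[[`, character(1), k)
  has_chain <- nf[1] == 11L  # with chain column; 10 fields means no chain
  name <- get(3); resname <- get(4)
  chain <- if (has_chain) get(5) else "A"
  resseq <- if (has_chain) get(6) else get(5)
  off <- if (has_chain) 0 else -1
  num <- function(k, what) mapply(parse_float, vapply(parts, `[[`, character(1), k),
                                  what, idx, ln)
  atoms <- data.frame(name = name, x = num(7 + off, "x coordinate"),
                      y = num(8 + off, "y coordinate"),
                      z = num(9 + off, "z coordinate"),
                      charge = num(10 + off, "charge"),
                      radius = num(11 + off, "radius"),
                      resid = as.integer(resseq), resname = resname,
                      chain = chain, stringsAsFactors = FALSE)
  ff_structure(atoms, metadata = paste0("read from ", basename(path)), toy = TRUE)
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column ATOM records, chains separated by TER, and a
#' terminal END. Coordinates are written to 3 decimals, so a written-then-read
#' structure round-trips exactly at that precision and a second write is
#' byte-identical.
#'
#' @param structure an `ff_structure` with at least one atom.
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (!nrow(a)) stop("refusing to write an empty structure", call. = FALSE)
  if (nrow(a) + length(unique(a$chain)) > 99999L)
    stop("more than 99,999 atom/TER records; use hybrid-36 numbering or ",
         "split the output into segments", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(a$chain)) {
    b <- a[a$chain == ch, ]
    for (i in seq_len(nrow(b))) {
      serial <- serial + 1L
      nm <- b$name[i]
      # PDB name field: element right-justified in cols 13-14 for short names.
      nmfmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nmfmt, " ", b$resname[i], ch, b$resid[i],
        b$x[i], b$y[i], b$z[i], 1, 0, b$element[i]), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %-3s %s%4d", serial,
                       b$resname[nrow(b)], ch, b$resid[nrow(b)]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a C-alpha trajectory
#'
#' @param path multi-model PDB file.
#' @param dt frame spacing in ps (times become 0, dt, 2*dt, ...).
#' @param label trajectory label.
#' @return an `ff_trajectory` (see [trajectory()]).
#' @export
read_trajectory <- function(path, dt = 1, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  nmodels <- max(1L, sum(startsWith(lines, "MODEL")))
  frames <- lapply(seq_len(nmodels), function(m) {
    s <- read_pdb(path, model = m)
    chain_atom_coords(s, structure_chains(s)[1], "CA")
  })
  trajectory(frames, times = (seq_len(nmodels) - 1) * dt, label = label)
}
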