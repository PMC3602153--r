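#' Parse a PDB-format structure into a DomainStructure
#'
#' Reads ATOM records of one model of a PDB file. For multi-model (NMR-style)
#' files only the requested model is retained; the default is the first
#' model. HETATM records (including waters) and residues outside the 20
#' standard amino acids are discarded. Alternate locations are resolved by
#' highest occupancy, ties broken alphabetically by altloc code.
#'
#' @param pdb_text PDB file content as a single string, a character vector of
#'   lines, or a path to a file.
#' @param model_index 1-based model to keep (default: first model).
#' @return A `DomainStructure`: a list with an `atoms` data frame (columns
#'   `serial`, `name`, `element`, `residue_index` (0-based, sequential within
#'   chain), `residue_name`, `aa`, `chain`, `resno` (author numbering), `x`,
#'   `y`, `z`) and the retained `model_index`.
#' @export
parse_structure <- function(pdb_text, model_index = 1L) {
  lines <- as_pdb_lines(pdb_text)

  # model selection by MODEL/ENDMDL bracketing, before any real parsing
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    if (model_index > length(model_starts)) {
      stop("model_index ", model_index, " requested but file has only ",
           length(model_starts), " model(s)")
    }
    ends <- grep("^ENDMDL", lines)
    from <- model_starts[model_index]
    to_candidates <- ends[ends > from]
    to <- if (length(to_candidates)) to_candidates[1] else length(lines)
    lines <- lines[seq(from, to)]
  }

  atom_idx <- grep("^ATOM ", lines)
  if (length(atom_idx) == 0) stop("no ATOM records found (empty structure)")

  # line-level validation so malformed records fail with their line number
  for (i in atom_idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords)) {
      stop("malformed ATOM record at line ", i, ": ", ln)
    }
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom

  at <- at[at$type == "ATOM" & at$resid %in% names(AA_ONE), , drop = FALSE]
  if (nrow(at) == 0) stop("no standard amino-acid residues in structure")

  # altloc resolution: highest occupancy, then alphabetical altloc code
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]

  # sequential 0-based residue indices within each chain
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  reskey <- paste(chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  residue_index <- integer(nrow(at))
  for (ch in unique(chain)) {
    sel <- chain == ch
    residue_index[sel] <- match(reskey[sel], unique(reskey[sel])) - 1L
  }

  element <- toupper(ifelse(is.na(at$elesy) | trimmod(at$elesy) == "",
                            element_from_name(at$elety), trimmod(at$elesy)))
  atoms <- data.frame(
    serial = at$eleno,
    name = trimmod(at$elety),
    element = element,
    residue_index = residue_index,
    residue_name = at$resid,
    aa = unname(AA_ONE[at$resid]),
    chain = chain,
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  new_domain_structure(atoms, model_index = model_index, validate = TRUE)
}

as_pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    return(readLines(pdb_text, warn = FALSE))
  }
  unlist(strsplit(pdb_text, "\n", fixed = TRUE))
}

# Internal constructor; validate = TRUE enforces the parse-time invariants.
new_domain_structure <- function(atoms, model_index = 1L, validate = FALSE) {
  stopifnot(all(c("name", "element", "residue_index", "residue_name",
                  "chain", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (!all(atoms$residue_name %in% names(AA_ONE))) {
    stop("non-standard residue names present")
  }
  if (is.null(atoms$aa)) atoms$aa <- unname(AA_ONE[atoms$residue_name])
  if (validate) {
    nres <- tapply(atoms$residue_index, atoms$chain,
                   function(ri) length(unique(ri)))
    if (!any(nres >= 3)) {
      stop("structure has no chain with at least 3 residues")
    }
  }
  structure(list(atoms = atoms, model_index = as.integer(model_index)),
            class = "DomainStructure")
}

#' @export
print.DomainStructure <- function(x, ...) {
  ch <- structure_chains(x)
  cat("DomainStructure:", nrow(x$atoms), "atoms,",
      length(ch), "chain(s) [",
      paste(sprintf("%s:%d res", names(ch), ch), collapse = ", "),
      "], model", x$model_index, "\n")
  invisible(x)
}

#' Chain residue counts of a structure
#' @param structure A `DomainStructure`.
#' @return Named integer vector: residues per chain.
#' @export
structure_chains <- function(structure) {
  vapply(split(structure$atoms$residue_index, structure$atoms$chain),
         function(ri) length(unique(ri)), integer(1))
}

#' One-letter sequence of a chain
#' @param structure A `DomainStructure`.
#' @param chain Chain identifier; default is the first chain.
#' @return Single string of 1-letter codes in residue order.
#' @export
chain_sequence <- function(structure, chain = NULL) {
  at <- structure$atoms
  chain <- chain %||% at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found")
  at <- at[!duplicated(at$residue_index), , drop = FALSE]
  paste(at$aa[order(at$residue_index)], collapse = "")
}

# Atoms of one chain, optionally one residue
chain_atoms <- function(structure, chain, residue_index = NULL) {
  at <- structure$atoms
  at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(residue_index)) {
    at <- at[at$residue_index %in% residue_index, , drop = FALSE]
  }
  at
}

#' Write a DomainStructure as PDB-format text
#'
#' Minimal ATOM/TER/END writer used for fixture output and round-tripping
#' through [parse_structure()].
#'
#' @param structure A `DomainStructure`.
#' @return Character scalar of PDB text.
#' @export
write_pdb <- function(structure) {
  at <- structure$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sel <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      serial <- serial + 1L
      nm <- sel$name[i]
      # PDB atom-name column convention: element right-justified in 13-14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, sel$residue_name[i], ch,
        sel$residue_index[i] + 1L,
        sel$x[i], sel$y[i], sel$z[i], 1.0, 0.0, sel$element[i]))
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
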