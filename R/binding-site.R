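#' Binding-site definition
#'
#' An ordered set of alignment columns (or, with the identity alignment,
#' 0-based residue indices of the domain chain) marking the core
#' peptide-contacting positions of the domain family.
#'
#' @param positions Integer vector of unique column/residue indices.
#' @param provenance `"derived"` (from complexes) or `"configured"`.
#' @return A `BindingSiteDefinition`.
#' @export
binding_site <- function(positions, provenance = c("configured", "derived")) {
  provenance <- match.arg(provenance)
  positions <- as.integer(positions)
  if (length(positions) < 1) stop("binding site must have at least 1 position")
  if (anyDuplicated(positions)) stop("binding-site positions must be unique")
  structure(list(positions = positions, provenance = provenance),
            class = "BindingSiteDefinition")
}

#' @export
print.BindingSiteDefinition <- function(x, ...) {
  cat("BindingSiteDefinition (", x$provenance, "): ",
      paste(x$positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Derive core binding-site positions from domain-peptide complexes
#'
#' A column is a core position when, in at least `min_structures` of the
#' supplied complexes, any heavy (non-hydrogen) atom of the domain residue
#' mapped to that column lies strictly closer than `contact_cutoff` to any
#' heavy atom of the peptide chain. Columns are returned in increasing
#' order. With a family-wide alignment and a sufficient set of complexes
#' this reproduces the ten-position core site used throughout the package.
#'
#' @param complexes List of lists with elements `structure`
#'   (`DomainStructure`), `domain_chain`, `peptide_chain`.
#' @param alignment Optional list (same length) of integer vectors mapping
#'   0-based domain residue index -> alignment column; `NULL` means the
#'   identity mapping for every complex.
#' @param contact_cutoff Heavy-atom distance cutoff in Angstroms (strict `<`).
#' @param min_structures Minimum number of complexes in which a column must
#'   contact; default is a majority of the supplied complexes.
#' @return A `BindingSiteDefinition` with provenance `"derived"`.
#' @export
derive_core_positions <- function(complexes, alignment = NULL,
                                  contact_cutoff = 4.5,
                                  min_structures = NULL) {
  stopifnot(length(complexes) >= 1)
  min_structures <- min_structures %||% (floor(length(complexes) / 2) + 1L)

  column_sets <- lapply(seq_along(complexes), function(k) {
    cx <- complexes[[k]]
    dom <- chain_atoms(cx$structure, cx$domain_chain)
    pep <- chain_atoms(cx$structure, cx$peptide_chain)
    dom <- dom[dom$element != "H", , drop = FALSE]
    pep <- pep[pep$element != "H", , drop = FALSE]
    if (nrow(dom) == 0 || nrow(pep) == 0) return(integer(0))
    d2 <- sqdist_xyz(as.matrix(dom[, c("x", "y", "z")]),
                     as.matrix(pep[, c("x", "y", "z")]))
    contact_res <- unique(dom$residue_index[
      apply(d2 < contact_cutoff^2, 1, any)])
    if (is.null(alignment)) contact_res
    else {
      map <- alignment[[k]]
      unique(map[as.character(contact_res)])
    }
  })

  counts <- table(unlist(column_sets))
  cols <- sort(as.integer(names(counts)[counts >= min_structures]))
  if (length(cols) == 0) {
    stop("no contacting columns found in >= ", min_structures, " complex(es)")
  }
  binding_site(cols, "derived")
}

#' Write / read a binding-site definition as TSV
#' @param site A `BindingSiteDefinition`.
#' @param path Output file.
#' @export
write_binding_site <- function(site, path) {
  utils::write.table(
    data.frame(column = site$positions, provenance = site$provenance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_site
#' @export
read_binding_site <- function(path) {
  df <- utils::read.delim(path)
  binding_site(df$column, unique(df$provenance))
}

# Map site columns to residue indices of one structure's domain chain.
# `alignment` maps 0-based residue index -> column; NULL = identity.
# A site column absent from the structure is a gap: unsupported domain.
resolve_site <- function(structure, site, chain = NULL, alignment = NULL) {
  at <- structure$atoms
  chain <- chain %||% at$chain[1]
  res <- sort(unique(at$residue_index[at$chain == chain]))
  if (is.null(alignment)) {
    cols <- res
  } else {
    cols <- unname(alignment[as.character(res)])
  }
  idx <- match(site$positions, cols)
  if (anyNA(idx)) {
    stop("unsupported domain: gap at binding-site column(s) ",
         paste(site$positions[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  res[idx]
}
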