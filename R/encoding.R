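#' Encode the JOY-style binary block (50 bits)
#'
#' Five bits per core position, in order: solvent accessible (relative
#' accessibility >= `acc_threshold`), side chain H-bonded to a main-chain
#' amide, to a main-chain carbonyl, to another side chain, and positive
#' backbone phi. Residues with undefined phi (chain start, missing backbone
#' atoms) encode the positive-phi bit as 0.
#'
#' @param structure A `DomainStructure`.
#' @param site A `BindingSiteDefinition`.
#' @param chain Domain chain; default first chain.
#' @param alignment Optional residue-index -> column map (see
#'   [resolve_site()]).
#' @param acc_threshold Relative-accessibility threshold for the accessible
#'   bit (JOY convention: 0.07).
#' @param sasa,hbonds,phi Optional precomputed results (per-structure reuse).
#' @param ... Passed to [compute_sasa()] / [detect_hbonds()].
#' @return Integer vector of length `5 * length(site$positions)`.
#' @export
encode_joy_block <- function(structure, site, chain = NULL, alignment = NULL,
                             acc_threshold = 0.07, sasa = NULL, hbonds = NULL,
                             phi = NULL, ...) {
  chain <- chain %||% structure$atoms$chain[1]
  res_idx <- resolve_site(structure, site, chain, alignment)
  sasa <- sasa %||% compute_sasa(structure, ...)
  flags <- hbond_flags(structure, hbonds)
  phi <- phi %||% compute_phi(structure, chain)

  chain_res <- sort(unique(structure$atoms$residue_index[
    structure$atoms$chain == chain]))
  bits <- integer(0)
  for (ri in res_idx) {
    sr <- sasa[sasa$chain == chain & sasa$residue_index == ri, , drop = FALSE]
    acc <- as.integer(sr$rel_acc[1] >= acc_threshold)
    fl <- flags[paste(chain, ri), ]
    p <- phi[match(ri, chain_res)]
    pos_phi <- as.integer(!is.na(p) && p > 0)
    bits <- c(bits, acc, unname(fl), pos_phi)
  }
  names(bits) <- paste0(
    rep(sprintf("p%02d", seq_along(res_idx)), each = 5), "_",
    rep(c("acc", "hb_amide", "hb_carbonyl", "hb_scsc", "pos_phi"),
        length(res_idx)))
  bits
}

#' Encode the per-position accessible-area block (10 values)
#'
#' @inheritParams encode_joy_block
#' @return Numeric vector (Angstrom^2), one value per site position, in
#'   site order.
#' @export
encode_area_block <- function(structure, site, chain = NULL, alignment = NULL,
                              sasa = NULL, ...) {
  chain <- chain %||% structure$atoms$chain[1]
  res_idx <- resolve_site(structure, site, chain, alignment)
  sasa <- sasa %||% compute_sasa(structure, ...)
  key <- paste(sasa$chain, sasa$residue_index)
  area <- sasa$area[match(paste(chain, res_idx), key)]
  names(area) <- sprintf("p%02d", seq_along(res_idx))
  area
}

# Per-atom partial charges. Formal residue charge split over canonical
# charged atoms; if none is present (pseudo-atom side chains) the charge
# sits on the side-chain atom farthest from CA.
atom_charges <- function(structure) {
  at <- structure$atoms
  q <- numeric(nrow(at))
  key <- paste(at$chain, at$residue_index)
  for (k in unique(key)) {
    rows <- which(key == k)
    res3 <- at$residue_name[rows[1]]
    total <- RESIDUE_CHARGE[AA_ONE[res3]]
    if (is.na(total)) next
    canon <- rows[at$name[rows] %in% CHARGED_ATOMS[[res3]]]
    if (length(canon) > 0) {
      q[canon] <- total / length(canon)
    } else {
      sc <- rows[!(at$name[rows] %in% BACKBONE_ATOMS)]
      if (length(sc) == 0) next
      ca <- rows[at$name[rows] == "CA"]
      if (length(ca) == 0) ca <- rows[1]
      d2 <- (at$x[sc] - at$x[ca])^2 + (at$y[sc] - at$y[ca])^2 +
        (at$z[sc] - at$z[ca])^2
      q[sc[which.max(d2)]] <- total
    }
  }
  q
}

# Coulomb potential with distance-dependent dielectric eps = 4r:
# V(p) = 332 * sum_j q_j / (4 d_pj^2)  [kcal/mol per unit charge]
coulomb_potential <- function(points_xyz, atoms_xyz, charges) {
  keep <- charges != 0
  if (!any(keep)) return(numeric(nrow(points_xyz)))
  d2 <- sqdist_xyz(points_xyz, atoms_xyz[keep, , drop = FALSE])
  d2[d2 < 1] <- 1
  as.numeric((332 / 4) * (1 / d2) %*% charges[keep])
}

#' Sample electrostatic or hydrophobicity values from the domain surface
#'
#' For each core position, the `n_samples` exposed Shrake-Rupley surface
#' points nearest to the residue's side-chain centroid are taken (ordered by
#' distance; deterministic). The electrostatic field is a Coulomb potential
#' with distance-dependent dielectric over a bundled formal-charge table;
#' hydrophobicity is the Kyte-Doolittle value of the residue owning each
#' point. A structure with fewer exposed points than requested pads with
#' zeros (logged).
#'
#' @inheritParams encode_joy_block
#' @param field `"electrostatic"` or `"hydrophobicity"`.
#' @param n_samples Surface samples per core position (default 9).
#' @param points Optional precomputed [surface_points()] result.
#' @return Numeric vector of length `length(site$positions) * n_samples`.
#' @export
sample_surface_values <- function(structure, site, field = c("electrostatic",
                                                             "hydrophobicity"),
                                  n_samples = 9, chain = NULL,
                                  alignment = NULL, points = NULL, ...) {
  field <- match.arg(field)
  chain <- chain %||% structure$atoms$chain[1]
  res_idx <- resolve_site(structure, site, chain, alignment)
  pts <- points %||% surface_points(structure, ...)

  at <- structure$atoms
  pxyz <- as.matrix(pts[, c("x", "y", "z")])
  values <- switch(field,
    electrostatic = coulomb_potential(
      pxyz, as.matrix(at[, c("x", "y", "z")]), atom_charges(structure)),
    hydrophobicity = unname(KD_HYDROPATHY[pts$aa]))

  out <- numeric(0)
  padded <- FALSE
  for (ri in res_idx) {
    rows <- at$chain == chain & at$residue_index == ri
    sc <- at[rows & !(at$name %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(sc) == 0) sc <- at[rows & at$name == "CA", , drop = FALSE]
    if (nrow(sc) == 0) sc <- at[rows, , drop = FALSE]
    centroid <- colMeans(sc[, c("x", "y", "z")])
    d2 <- colSums((t(pxyz) - centroid)^2)
    ord <- order(d2)[seq_len(min(n_samples, length(d2)))]
    v <- values[ord]
    if (length(v) < n_samples) {
      v <- c(v, numeric(n_samples - length(v)))
      padded <- TRUE
    }
    out <- c(out, v)
  }
  if (padded) message("sample_surface_values: fewer exposed surface points ",
                      "than requested; padded with zeros")
  names(out) <- paste0(
    rep(sprintf("p%02d", seq_along(res_idx)), each = n_samples), "_s",
    rep(seq_len(n_samples), length(res_idx)))
  out
}

# Rigid-motion canonicalization: center on the atom centroid and rotate
# into the principal-axes frame of all atoms, signs fixed by positive
# coordinate skewness (fallback: first atom coordinate positive) and a
# right-handed third axis.  Makes surface-based features exactly
# independent of the input frame (up to floating point) even though the
# sphere point grid is fixed in space.
canonicalize_structure <- function(structure) {
  at <- structure$atoms
  X <- as.matrix(at[, c("x", "y", "z")])
  X <- sweep(X, 2, colMeans(X))
  if (nrow(X) >= 3) {
    R <- svd(stats::cov(X))$u
    for (k in 1:2) {
      s <- sum((X %*% R[, k])^3)
      if (abs(s) < 1e-8) s <- (X %*% R[, k])[which.max(abs(X %*% R[, k]))]
      if (s < 0) R[, k] <- -R[, k]
    }
    R[, 3] <- vcross(R[, 1], R[, 2])
    X <- X %*% R
  }
  at$x <- X[, 1]; at$y <- X[, 2]; at$z <- X[, 3]
  structure$atoms <- at
  structure
}

#' Encode a domain structure into the 240-value feature vector
#'
#' Fixed block layout: 50 JOY-style binaries, 10 accessible areas, 90
#' electrostatic samples, 90 hydrophobicity samples (with the default
#' ten-position site and 9 samples per position). Optionally min-max scaled
#' with a fitted [fit_scaler()] object.
#'
#' @inheritParams sample_surface_values
#' @param scaler Optional `FeatureScaler`; when supplied the vector is
#'   scaled to the training [0,1] range.
#' @param probe_radius,n_points Shrake-Rupley parameters shared by all
#'   blocks.
#' @param domain_id Identifier stored as an attribute.
#' @return Named numeric vector of length `7 * length(site$positions) *
#'   ... = 240` for the default site, with attributes `domain_id` and
#'   `blocks` (index ranges of the four blocks).
#' @export
encode_domain <- function(structure, site, chain = NULL, alignment = NULL,
                          scaler = NULL, n_samples = 9, probe_radius = 1.4,
                          n_points = 960, domain_id = "domain") {
  chain <- chain %||% structure$atoms$chain[1]
  structure <- canonicalize_structure(structure)
  sasa <- compute_sasa(structure, probe_radius, n_points)
  pts <- surface_points(structure, probe_radius, n_points)
  hb <- detect_hbonds(structure)
  phi <- suppressMessages(compute_phi(structure, chain))

  joy <- encode_joy_block(structure, site, chain, alignment,
                          sasa = sasa, hbonds = hb, phi = phi)
  area <- encode_area_block(structure, site, chain, alignment, sasa = sasa)
  elec <- sample_surface_values(structure, site, "electrostatic", n_samples,
                                chain, alignment, points = pts)
  hyd <- sample_surface_values(structure, site, "hydrophobicity", n_samples,
                               chain, alignment, points = pts)

  v <- c(joy, area, elec, hyd)
  names(v) <- c(paste0("joy_", names(joy)), paste0("area_", names(area)),
                paste0("elec_", names(elec)), paste0("hyd_", names(hyd)))
  blocks <- list(joy = seq_along(joy),
                 area = length(joy) + seq_along(area),
                 electrostatic = length(joy) + length(area) + seq_along(elec),
                 hydrophobicity = length(joy) + length(area) + length(elec) +
                   seq_along(hyd))
  if (!is.null(scaler)) v <- apply_scaler(scaler, v)
  attr(v, "domain_id") <- domain_id
  attr(v, "blocks") <- blocks
  class(v) <- "StructureFeatureVector"
  v
}

#' Slice a structure feature vector into its four blocks
#' @param v A `StructureFeatureVector` from [encode_domain()].
#' @return Named list of numeric sub-vectors.
#' @export
feature_blocks <- function(v) {
  blocks <- attr(v, "blocks")
  stopifnot(!is.null(blocks))
  lapply(blocks, function(idx) unclass(v)[idx])
}

#' Sparse binary encoding of a C-terminal pentapeptide
#'
#' Each of the five residues becomes a 20-bit indicator over [AA_ALPHABET]
#' (alphabetical by one-letter code); blocks are concatenated N- to
#' C-terminal, positions labelled -4..0 with 0 the C-terminus.
#'
#' @param peptide 5-letter string over the 20 standard amino acids.
#' @return Integer vector of length 100 with exactly 5 bits set.
#' @export
encode_peptide <- function(peptide) {
  check_peptides(peptide, 5L)
  ch <- strsplit(peptide, "")[[1]]
  bits <- integer(100)
  idx <- match(ch, AA_ALPHABET)
  bits[(seq_len(5) - 1) * 20 + idx] <- 1L
  names(bits) <- paste0("pep_", rep(c("m4", "m3", "m2", "m1", "p0"),
                                    each = 20), "_",
                        rep(AA_ALPHABET, 5))
  bits
}

#' Decode a sparse peptide encoding back to its 5-letter string
#' @param bits Integer vector of length 100 from [encode_peptide()].
#' @return 5-letter string.
#' @export
decode_peptide <- function(bits) {
  stopifnot(length(bits) == 100)
  m <- matrix(bits, nrow = 20)
  if (!all(colSums(m) == 1)) stop("not a valid sparse peptide encoding")
  paste(AA_ALPHABET[apply(m, 2, which.max)], collapse = "")
}

#' Extract unique C-termini from a FASTA proteome
#'
#' @param fasta FASTA text (string) or path to a FASTA file.
#' @param length Tail length to extract (default 5).
#' @return List with `map` (data frame `id`, `peptide`, one row per
#'   sequence of sufficient length) and `peptides` (unique tails).
#'   Sequences shorter than `length` are skipped with a message.
#' @export
extract_ctermini <- function(fasta, length = 5L) {
  if (grepl("\n", fasta[1]) || startsWith(fasta[1], ">")) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(fasta, tmp)
    fasta <- tmp
  }
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  widths <- Biostrings::width(seqs)
  short <- widths < length
  if (any(short)) {
    message("extract_ctermini: skipped ", sum(short),
            " sequence(s) shorter than ", length)
  }
  keep <- which(!short)
  tails <- as.character(Biostrings::subseq(
    seqs[keep], start = widths[keep] - length + 1L))
  map <- data.frame(id = ids[keep], peptide = unname(tails),
                    stringsAsFactors = FALSE)
  list(map = map, peptides = unique(map$peptide))
}

#' Min-max feature scaler fitted on training vectors
#'
#' Per-dimension min and max over the training matrix; applying the scaler
#' maps training values into [0,1]. Constant dimensions (max == min) map
#' to 0. Values outside the training range are NOT clamped: an unseen
#' value of 20 after fitting on {0, 10} transforms to 2.0.
#'
#' @param X Numeric matrix, rows = training vectors.
#' @return A `FeatureScaler` (list with `min`, `max`).
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "FeatureScaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `FeatureScaler`.
#' @param x Numeric vector or matrix to transform.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "FeatureScaler"))
  rng <- scaler$max - scaler$min
  vec <- is.null(dim(x))
  if (vec) {
    atts <- attributes(x)
    x <- matrix(as.numeric(x), nrow = 1)
  }
  if (ncol(x) != length(scaler$min)) {
    stop("dimension mismatch: scaler has ", length(scaler$min),
         " dimensions, input has ", ncol(x))
  }
  out <- sweep(x, 2, scaler$min, "-")
  safe <- ifelse(rng == 0, 1, rng)
  out <- sweep(out, 2, safe, "/")
  out[, rng == 0] <- 0
  if (vec) {
    out <- out[1, ]
    nm <- atts$names
    attributes(out) <- atts[setdiff(names(atts), "names")]
    names(out) <- nm
  }
  out
}

#' Persist / restore a feature scaler as a key-value text file
#' @param scaler A `FeatureScaler`.
#' @param path File path.
#' @export
write_scaler <- function(scaler, path) {
  df <- data.frame(dimension = seq_along(scaler$min),
                   name = names(scaler$min) %||% "",
                   min = scaler$min, max = scaler$max)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  df <- utils::read.delim(path)
  structure(list(min = stats::setNames(df$min, df$name),
                 max = stats::setNames(df$max, df$name)),
            class = "FeatureScaler")
}
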