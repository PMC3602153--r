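#' Dihedral angle defined by four points
#'
#' Standard atan2 formula; result in degrees in (-180, 180], following the
#' IUPAC convention (trans = 180, right-handed helix phi negative).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

angle_deg <- function(a, b, c) {
  # angle at b
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Backbone phi angles of a chain
#'
#' phi(i) is the dihedral C(i-1)-N(i)-CA(i)-C(i). The first residue, and any
#' residue with a missing backbone atom, is reported as `NA` (flagged
#' undefined, with a message) rather than silently zero.
#'
#' @param structure A `DomainStructure`.
#' @param chain Chain id; default first chain.
#' @return Numeric vector, one value per residue (degrees, `NA` = undefined).
#' @export
compute_phi <- function(structure, chain = NULL) {
  at <- structure$atoms
  chain <- chain %||% at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found")
  res <- sort(unique(at$residue_index))
  get_atom <- function(ri, nm) {
    row <- at[at$residue_index == ri & at$name == nm, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  phi <- rep(NA_real_, length(res))
  n_missing <- 0L
  for (k in seq_along(res)[-1]) {
    cprev <- get_atom(res[k - 1], "C")
    n <- get_atom(res[k], "N")
    ca <- get_atom(res[k], "CA")
    cc <- get_atom(res[k], "C")
    if (is.null(cprev) || is.null(n) || is.null(ca) || is.null(cc)) {
      n_missing <- n_missing + 1L
      next
    }
    phi[k] <- dihedral_angle(cprev, n, ca, cc)
  }
  if (n_missing > 0) {
    message("compute_phi: ", n_missing,
            " residue(s) with incomplete backbone flagged undefined")
  }
  phi
}

#' Detect side-chain hydrogen bonds
#'
#' Geometric criteria: donor-acceptor distance at most `dist_cutoff` and,
#' since donor hydrogens are usually absent, an antecedent-donor-acceptor
#' angle of at least `min_angle` degrees. Every returned bond is classified
#' into exactly one of three kinds, according to which partner is a side
#' chain: `sc_mc_amide` (side-chain acceptor, main-chain N-H donor),
#' `sc_mc_carbonyl` (side-chain donor, main-chain carbonyl O acceptor) and
#' `sc_sc` (both side chains). Donor and acceptor must belong to different
#' residues.
#'
#' @param structure A `DomainStructure`.
#' @param dist_cutoff Donor-acceptor distance cutoff in Angstroms.
#' @param min_angle Minimum antecedent-donor-acceptor angle in degrees.
#' @return Data frame with donor/acceptor chain, residue index, atom name,
#'   `kind` and `distance`; zero rows when no bond meets the criteria.
#' @export
detect_hbonds <- function(structure, dist_cutoff = 3.5, min_angle = 90) {
  at <- structure$atoms

  pick <- function(table, mainchain_atom = NULL) {
    if (!is.null(mainchain_atom)) {
      return(which(at$name == mainchain_atom))
    }
    idx <- integer(0)
    for (res in names(table)) {
      idx <- c(idx, which(at$residue_name == res & at$name %in% table[[res]]))
    }
    sort(idx)
  }

  donors_sc <- pick(SC_DONORS)
  donors_mc <- pick(NULL, "N")
  acceptors_sc <- pick(SC_ACCEPTORS)
  acceptors_mc <- pick(NULL, "O")

  coords <- as.matrix(at[, c("x", "y", "z")])

  antecedent_of <- function(i) {
    same <- which(at$chain == at$chain[i] &
                    at$residue_index == at$residue_index[i])
    same <- setdiff(same, i)
    if (length(same) == 0) return(NULL)
    want <- ANTECEDENTS[at$name[i]]
    if (!is.na(want)) {
      hit <- same[at$name[same] == want]
      if (length(hit)) return(hit[1])
    }
    d2 <- colSums((t(coords[same, , drop = FALSE]) - coords[i, ])^2)
    same[which.min(d2)]
  }

  collect <- function(don, acc, kind) {
    if (length(don) == 0 || length(acc) == 0) return(NULL)
    d2 <- sqdist_xyz(coords[don, , drop = FALSE], coords[acc, , drop = FALSE])
    hits <- which(d2 <= dist_cutoff^2, arr.ind = TRUE)
    out <- NULL
    for (h in seq_len(nrow(hits))) {
      i <- don[hits[h, 1]]
      j <- acc[hits[h, 2]]
      if (i == j) next
      same_res <- at$chain[i] == at$chain[j] &&
        at$residue_index[i] == at$residue_index[j]
      if (same_res) next
      ant <- antecedent_of(i)
      if (!is.null(ant)) {
        ang <- angle_deg(coords[ant, ], coords[i, ], coords[j, ])
        if (ang < min_angle) next
      }
      out <- rbind(out, data.frame(
        donor_chain = at$chain[i], donor_residue = at$residue_index[i],
        donor_atom = at$name[i],
        acceptor_chain = at$chain[j], acceptor_residue = at$residue_index[j],
        acceptor_atom = at$name[j],
        kind = kind, distance = sqrt(d2[hits[h, 1], hits[h, 2]]),
        stringsAsFactors = FALSE))
    }
    out
  }

  res <- rbind(
    collect(donors_mc, acceptors_sc, "sc_mc_amide"),
    collect(donors_sc, acceptors_mc, "sc_mc_carbonyl"),
    collect(donors_sc, acceptors_sc, "sc_sc")
  )
  if (is.null(res)) {
    res <- data.frame(donor_chain = character(0), donor_residue = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_residue = integer(0), acceptor_atom = character(0),
                      kind = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res
}

# Per-residue hydrogen-bond involvement flags for the JOY-style encoding.
# A residue is flagged for the kind in which its SIDE CHAIN participates.
hbond_flags <- function(structure, hbonds = NULL, ...) {
  hb <- hbonds %||% detect_hbonds(structure, ...)
  at <- structure$atoms
  key <- unique(paste(at$chain, at$residue_index))
  flags <- matrix(0L, nrow = length(key), ncol = 3,
                  dimnames = list(key, c("sc_mc_amide", "sc_mc_carbonyl",
                                         "sc_sc")))
  if (nrow(hb) > 0) {
    dkey <- paste(hb$donor_chain, hb$donor_residue)
    akey <- paste(hb$acceptor_chain, hb$acceptor_residue)
    flags[akey[hb$kind == "sc_mc_amide"], "sc_mc_amide"] <- 1L
    flags[dkey[hb$kind == "sc_mc_carbonyl"], "sc_mc_carbonyl"] <- 1L
    flags[unique(c(dkey[hb$kind == "sc_sc"], akey[hb$kind == "sc_sc"])),
          "sc_sc"] <- 1L
  }
  flags
}
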