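#' Specification of the synthetic study conditions
#'
#' Fully determines (given the seed) every fixture the package can
#' generate: toy domain structures with an idealized backbone and
#' pseudo-atom side chains, interaction sets with a planted
#' position-specific binding preference, and a toy C-terminal proteome.
#' Domains fall into `n_archetypes` archetypes that differ in the charge
#' and hydrophobicity of their binding-site residues and in their planted
#' peptide preference (PWM), so that interaction classes are learnable
#' from the structure + peptide encoding.
#'
#' @param seed Integer master seed.
#' @param n_domains Number of toy domains.
#' @param n_archetypes Number of binding archetypes (max 4).
#' @param site_length Core binding-site length (default 10).
#' @param domain_length Residues per domain chain.
#' @param n_pos,n_neg Positive / negative interactions per domain.
#' @param proteome_size Sequences in the toy proteome.
#' @param consensus_fraction Fraction of proteome tails carrying a planted
#'   consensus (true binders).
#' @param conformation `"helix"` (phi -57, psi -47) or `"strand"`
#'   (phi -120, psi +120).
#' @param concentration Planted PWM probability of the consensus letter.
#' @param jitter Uniform coordinate noise amplitude in Angstroms.
#' @param peptide_offset Radial distance of the bound peptide chain from
#'   the binding-site centroid (Angstroms).
#' @param contact_distance Planted side-chain-to-peptide contact distance
#'   (must be < 4.5 for the core-position derivation to see it).
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_domains = 20L, n_archetypes = 2L,
                         site_length = 10L, domain_length = 30L,
                         n_pos = 30L, n_neg = 60L, proteome_size = 400L,
                         consensus_fraction = 0.1,
                         conformation = c("helix", "strand"),
                         concentration = 0.7, jitter = 0.15,
                         peptide_offset = 13.5, contact_distance = 4.0) {
  conformation <- match.arg(conformation)
  stopifnot(n_archetypes >= 1, n_archetypes <= 4,
            site_length >= 1, site_length <= domain_length)
  archetypes <- list(
    list(site_seq = "KRKSKRKTKR", consensus = "RETQV"),
    list(site_seq = "LDVLEILDVL", consensus = "EFYFV"),
    list(site_seq = "ENDQENDSEN", consensus = "GSTWL"),
    list(site_seq = "IVLFIVLMIV", consensus = "KPHRA")
  )[seq_len(n_archetypes)]
  archetypes <- lapply(archetypes, function(a) {
    a$site_seq <- paste(rep_len(strsplit(a$site_seq, "")[[1]],
                                site_length), collapse = "")
    a
  })
  site_start <- floor((domain_length - site_length) / 2)
  structure(list(
    seed = as.integer(seed), n_domains = as.integer(n_domains),
    n_archetypes = as.integer(n_archetypes),
    site_length = as.integer(site_length),
    domain_length = as.integer(domain_length),
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    proteome_size = as.integer(proteome_size),
    consensus_fraction = consensus_fraction,
    conformation = conformation, concentration = concentration,
    jitter = jitter, peptide_offset = peptide_offset,
    contact_distance = contact_distance,
    archetypes = archetypes,
    site_positions = site_start + seq_len(site_length) - 1L
  ), class = "FixtureSpec")
}

fixture_archetype <- function(spec, index) {
  ((index - 1L) %% spec$n_archetypes) + 1L
}

fixture_domain_ids <- function(spec) {
  sprintf("dom%02d", seq_len(spec$n_domains))
}

#' Planted position weight matrix of a fixture archetype
#'
#' @param spec A `FixtureSpec`.
#' @param archetype Archetype index.
#' @return A `PWM` putting `concentration` on each consensus letter and
#'   spreading the remainder uniformly.
#' @export
planted_pwm <- function(spec, archetype) {
  cons <- strsplit(spec$archetypes[[archetype]]$consensus, "")[[1]]
  m <- matrix((1 - spec$concentration) / 19, nrow = 20, ncol = length(cons),
              dimnames = list(AA_ALPHABET,
                              as.character(seq_along(cons) - length(cons))))
  for (j in seq_along(cons)) m[cons[j], j] <- spec$concentration
  structure(m, class = c("PWM", "matrix"),
            pseudocount = 0, n_sequences = NA_integer_)
}

# NeRF internal-to-cartesian placement: position of atom D given A, B, C,
# the C-D bond length, the B-C-D angle and the A-B-C-D torsion (degrees).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- (C - B) / vnorm(C - B)
  n <- vcross(B - A, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal backbone (N, CA, C, O + CB except Gly) for a sequence at fixed
# phi/psi; returns an atoms data frame for one chain.
build_chain <- function(sequence, chain_id, phi, psi, omega = 180) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  phi <- rep_len(phi, L)
  psi <- rep_len(psi, L)
  rows <- list()
  add <- function(name, element, ri, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = length(rows) + 1L, name = name, element = element,
      residue_index = ri, residue_name = unname(AA_THREE[aa[ri + 1]]),
      aa = aa[ri + 1], chain = chain_id, resno = ri + 1L,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  C <- CA + 1.525 * c(cos(th), sin(th), 0)
  for (i in seq_len(L)) {
    ri <- i - 1L
    if (i > 1) {
      N_new <- place_atom(Nprev, CAprev, Cprev, 1.329, 116.2, psi[i - 1])
      CA_new <- place_atom(CAprev, Cprev, N_new, 1.458, 121.7, omega)
      C_new <- place_atom(Cprev, N_new, CA_new, 1.525, 111.2, phi[i])
      N <- N_new; CA <- CA_new; C <- C_new
    }
    add("N", "N", ri, N)
    add("CA", "C", ri, CA)
    add("C", "C", ri, C)
    add("O", "O", ri, place_atom(N, CA, C, 1.231, 120.8, psi[i] - 180))
    if (aa[i] != "G") {
      add("CB", "C", ri, place_atom(C, N, CA, 1.530, 110.5, -122))
    }
    Nprev <- N; CAprev <- CA; Cprev <- C
  }
  do.call(rbind, rows)
}

#' Build one toy domain structure, optionally with a bound peptide chain
#'
#' The domain chain (`A`) is an idealized helix or strand with pseudo-atom
#' side chains; binding-site residues carry the archetype's site sequence.
#' When a peptide chain is requested, chain `B` (Gly + the archetype
#' consensus, extended conformation) is placed `peptide_offset` Angstroms
#' from the binding-site centroid, and each site residue receives an extra
#' side-chain pseudo-atom (`CG`) placed `contact_distance` (< 4.5) from
#' its nearest peptide heavy atom, so the planted site positions — and
#' only those — are in close contact with the peptide. All coordinates
#' receive seeded uniform jitter.
#'
#' @param spec A `FixtureSpec`.
#' @param index Domain index in `1..n_domains`.
#' @param with_peptide Include the contacting peptide chain.
#' @return List with `structure` (`DomainStructure`), `domain_id`,
#'   `archetype`, `site` (0-based residue indices of the planted core
#'   positions), `domain_chain`, `peptide_chain`.
#' @export
make_toy_domain <- function(spec, index, with_peptide = TRUE) {
  arch <- fixture_archetype(spec, index)
  site <- spec$site_positions
  site_seq <- strsplit(spec$archetypes[[arch]]$site_seq, "")[[1]]

  aa <- withr::with_seed(spec$seed + 100L * index, sample(
    c("A", "G", "S", "T", "N", "Q"), spec$domain_length, replace = TRUE))
  aa[site + 1L] <- site_seq
  angles <- switch(spec$conformation,
                   helix = c(phi = -57, psi = -47),
                   strand = c(phi = -120, psi = 120))
  dom <- build_chain(paste(aa, collapse = ""), "A",
                     angles["phi"], angles["psi"])

  atoms <- dom
  if (with_peptide) {
    pep_seq <- paste0("G", spec$archetypes[[arch]]$consensus)
    pep <- build_chain(pep_seq, "B", -120, 120)

    ca <- dom[dom$name == "CA", c("x", "y", "z")]
    site_ca <- dom[dom$name == "CA" & dom$residue_index %in% site,
                   c("x", "y", "z")]
    site_centroid <- colMeans(site_ca)
    pc <- stats::prcomp(ca, center = TRUE)
    radial <- pc$rotation[, 3]
    target <- site_centroid + spec$peptide_offset * radial

    pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
    shift <- target - colMeans(pep_xyz)
    pep$x <- pep$x + shift[1]
    pep$y <- pep$y + shift[2]
    pep$z <- pep$z + shift[3]

    # planted contacts: one CG pseudo-atom per site residue, placed
    # contact_distance from its nearest peptide heavy atom
    pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
    cg_rows <- list()
    for (ri in site) {
      cb <- dom[dom$residue_index == ri & dom$name == "CB", ]
      anchor <- if (nrow(cb) == 1) c(cb$x, cb$y, cb$z) else {
        carow <- dom[dom$residue_index == ri & dom$name == "CA", ]
        c(carow$x, carow$y, carow$z)
      }
      d2 <- colSums((t(pep_xyz) - anchor)^2)
      nearest <- pep_xyz[which.min(d2), ]
      u <- (nearest - anchor) / vnorm(nearest - anchor)
      cg <- nearest - spec$contact_distance * u
      cg_rows[[length(cg_rows) + 1]] <- data.frame(
        serial = 0L, name = "CG", element = "C", residue_index = ri,
        residue_name = unname(AA_THREE[aa[ri + 1]]), aa = aa[ri + 1],
        chain = "A", resno = ri + 1L, x = cg[1], y = cg[2], z = cg[3],
        stringsAsFactors = FALSE)
    }
    atoms <- rbind(dom, do.call(rbind, cg_rows), pep)
    atoms <- atoms[order(match(atoms$chain, c("A", "B")),
                         atoms$residue_index), , drop = FALSE]
  }

  if (spec$jitter > 0) {
    noise <- withr::with_seed(spec$seed + 100L * index + 1L,
                              matrix(stats::runif(3 * nrow(atoms),
                                                  -spec$jitter, spec$jitter),
                                     ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL

  list(structure = new_domain_structure(atoms),
       domain_id = fixture_domain_ids(spec)[index],
       archetype = arch, site = site,
       domain_chain = "A", peptide_chain = if (with_peptide) "B" else NULL)
}

# Draw n peptides from a PWM (column-independent sampling); unique unless
# the PWM is degenerate (one-hot columns admit a single peptide).
sample_pwm_peptides <- function(pwm, n, seed, max_tries = 1000L) {
  if (all(apply(unclass(pwm), 2, max) >= 1)) {
    return(rep(pwm_consensus(pwm), n))
  }
  out <- character(0)
  tries <- 0L
  withr::with_seed(seed, {
    while (length(out) < n && tries < max_tries) {
      batch <- replicate(n, paste(apply(unclass(pwm), 2, function(p)
        sample(rownames(pwm), 1, prob = p)), collapse = ""))
      out <- unique(c(out, batch))
      tries <- tries + 1L
    }
  })
  if (length(out) < n) stop("could not draw ", n, " unique PWM peptides")
  out[seq_len(n)]
}

#' Generate the planted interaction set
#'
#' Positives are drawn from each domain's archetype PWM; negatives are
#' uniform random pentapeptides rejected while their planted-PWM score
#' reaches the lowest positive score (so every negative scores below
#' every positive of its domain).
#'
#' @param spec A `FixtureSpec`.
#' @return List with `records` (`interaction_records`), `pwms` (planted
#'   PWM per archetype) and `domain_info` (domain id, archetype).
#' @export
make_interactions <- function(spec) {
  pwms <- lapply(seq_len(spec$n_archetypes), function(a)
    planted_pwm(spec, a))
  ids <- fixture_domain_ids(spec)
  recs <- list()
  smooth <- function(pwm) {
    m <- unclass(pwm) + 1e-6
    m <- sweep(m, 2, colSums(m), "/")
    structure(m, class = c("PWM", "matrix"), pseudocount = 1e-6,
              n_sequences = NA_integer_)
  }
  for (i in seq_len(spec$n_domains)) {
    arch <- fixture_archetype(spec, i)
    pwm <- smooth(pwms[[arch]])
    pos <- sample_pwm_peptides(pwms[[arch]], spec$n_pos,
                               spec$seed + 7000L + i)
    floor_score <- min(score_peptide(pwm, pos))
    neg <- character(0)
    tries <- 0L
    withr::with_seed(spec$seed + 8000L + i, {
      while (length(neg) < spec$n_neg) {
        tries <- tries + 1L
        if (tries > 1000L * spec$n_neg) {
          stop("negative rejection sampling stalled for domain ", ids[i])
        }
        cand <- paste(sample(AA_ALPHABET, 5, replace = TRUE), collapse = "")
        if (cand %in% pos || cand %in% neg) next
        if (score_peptide(pwm, cand) >= floor_score) next
        neg <- c(neg, cand)
      }
    })
    recs[[i]] <- interaction_records(
      ids[i], c(pos, neg), c(rep(1L, spec$n_pos), rep(-1L, spec$n_neg)),
      c(rep("experimental", spec$n_pos), rep("pwm_negative", spec$n_neg)))
  }
  list(records = validate_records(do.call(rbind, recs)),
       pwms = pwms,
       domain_info = data.frame(
         domain_id = ids,
         archetype = vapply(seq_len(spec$n_domains), fixture_archetype,
                            integer(1), spec = spec)))
}

#' Generate a toy C-terminal proteome as FASTA text
#'
#' A `consensus_fraction` of sequences end in a planted archetype
#' consensus (true binders, cycled over archetypes); the remainder are
#' background sequences whose tails are guaranteed not to match any
#' planted consensus.
#'
#' @param spec A `FixtureSpec`.
#' @return Single FASTA string with `proteome_size` records.
#' @export
make_toy_proteome <- function(spec) {
  n <- spec$proteome_size
  n_planted <- round(spec$consensus_fraction * n)
  consensi <- vapply(spec$archetypes, `[[`, character(1), "consensus")
  withr::with_seed(spec$seed + 9000L, {
    seqs <- vapply(seq_len(n), function(i) {
      len <- sample(30:60, 1)
      repeat {
        s <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
        if (!(substr(s, len - 4, len) %in% consensi)) break
      }
      s
    }, character(1))
    if (n_planted > 0) {
      planted <- sample(n, n_planted)
      for (k in seq_along(planted)) {
        i <- planted[k]
        cons <- consensi[((k - 1) %% length(consensi)) + 1]
        substr(seqs[i], nchar(seqs[i]) - 4, nchar(seqs[i])) <- cons
      }
    }
  })
  paste0(">prot", sprintf("%04d", seq_len(n)), "\n", seqs,
         collapse = "\n")
}

#' Build the complete synthetic study in one call
#'
#' Generates all domains, derives the core binding site from the
#' domain-peptide complexes, encodes every domain into its 240-value
#' feature vector, and generates the interaction set and toy proteome.
#' This is the entry point used by the package's end-to-end evaluation.
#'
#' @param spec A `FixtureSpec`.
#' @param n_points Shrake-Rupley point density used for encoding.
#' @return List: `spec`, `domains` (per-domain fixture lists), `site`
#'   (derived `BindingSiteDefinition`), `domain_vectors` (n_domains x 240
#'   matrix), `site_sequences` (binding-site sequence per domain),
#'   `interactions` (see [make_interactions()]), `proteome` (FASTA text),
#'   `ctermini` (see [extract_ctermini()]).
#' @export
make_fixture_set <- function(spec, n_points = 960) {
  domains <- lapply(seq_len(spec$n_domains), function(i)
    make_toy_domain(spec, i))
  complexes <- lapply(domains, function(d)
    list(structure = d$structure, domain_chain = d$domain_chain,
         peptide_chain = d$peptide_chain))
  site <- derive_core_positions(complexes)
  encoded <- lapply(domains, function(d)
    encode_domain(d$structure, site, chain = d$domain_chain,
                  n_points = n_points, domain_id = d$domain_id))
  vecs <- do.call(rbind, lapply(encoded, as.numeric))
  rownames(vecs) <- vapply(domains, `[[`, character(1), "domain_id")
  colnames(vecs) <- names(encoded[[1]])
  site_seqs <- vapply(domains, function(d) {
    s <- strsplit(chain_sequence(d$structure, d$domain_chain), "")[[1]]
    paste(s[site$positions + 1L], collapse = "")
  }, character(1))
  names(site_seqs) <- rownames(vecs)
  interactions <- make_interactions(spec)
  proteome <- make_toy_proteome(spec)
  list(spec = spec, domains = domains, site = site, domain_vectors = vecs,
       site_sequences = site_seqs, interactions = interactions,
       proteome = proteome,
       ctermini = suppressMessages(extract_ctermini(proteome)))
}

#' Write a fixture set to disk (PDB + FASTA + TSV)
#'
#' @param fixture Result of [make_fixture_set()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_set <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in fixture$domains) {
    writeLines(write_pdb(d$structure),
               file.path(dir, paste0(d$domain_id, ".pdb")))
  }
  writeLines(fixture$proteome, file.path(dir, "proteome.fasta"))
  write_interactions(fixture$interactions$records,
                     file.path(dir, "interactions.tsv"))
  write_binding_site(fixture$site, file.path(dir, "binding_site.tsv"))
  utils::write.table(
    data.frame(domain_id = rownames(fixture$domain_vectors),
               fixture$domain_vectors, check.names = FALSE),
    file.path(dir, "domain_features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
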