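#' Construct and validate a table of domain-peptide interaction records
#'
#' @param domain_id,peptide,label,source Equal-length vectors; `label` must
#'   be +1/-1 and `source` one of `experimental`, `pwm_negative`,
#'   `svm_negative`.
#' @return Data frame of class `interaction_records`.
#' @export
interaction_records <- function(domain_id, peptide, label,
                                source = "experimental") {
  rec <- data.frame(domain_id = as.character(domain_id),
                    peptide = as.character(peptide),
                    label = as.integer(label),
                    source = as.character(source),
                    stringsAsFactors = FALSE)
  validate_records(rec)
}

#' @rdname interaction_records
#' @param records A data frame with the four record columns.
#' @export
validate_records <- function(records) {
  stopifnot(all(c("domain_id", "peptide", "label", "source") %in%
                  names(records)))
  if (!all(records$label %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  if (!all(records$source %in% c("experimental", "pwm_negative",
                                 "svm_negative"))) {
    stop("unknown record source")
  }
  check_peptides(records$peptide)
  key <- paste(records$domain_id, records$peptide)
  lab_per_key <- tapply(records$label, key, function(l) length(unique(l)))
  if (any(lab_per_key > 1)) {
    bad <- names(lab_per_key)[lab_per_key > 1][1]
    stop("peptide labelled both +1 and -1 for the same domain: ", bad)
  }
  class(records) <- c("interaction_records", "data.frame")
  records
}

#' Read / write interaction tables as TSV
#' @param path File path.
#' @export
read_interactions <- function(path) {
  validate_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_interactions
#' @param records Interaction records.
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate artificial negatives from the low-scoring tail of a PWM scan
#'
#' Scores a C-terminal peptide pool with the domain's positive-binder PWM
#' and samples `n_negatives` peptides uniformly (seeded) from the bottom
#' `quantile` of scores, excluding the domain's known positives.
#'
#' @param pwm PWM built from the domain's positive binders (use a positive
#'   pseudocount).
#' @param peptide_pool Character vector of candidate peptides (typically
#'   proteome C-termini).
#' @param n_negatives Number of negatives to draw.
#' @param domain_id Domain the records are for.
#' @param quantile Fraction of the pool (by ascending score) eligible.
#' @param exclude Peptides never to return (known positives).
#' @param seed Integer seed.
#' @return `interaction_records` with label -1, source `pwm_negative`.
#' @export
generate_pwm_negatives <- function(pwm, peptide_pool, n_negatives, domain_id,
                                   quantile = 0.25, exclude = character(0),
                                   seed = 1L) {
  stopifnot(quantile > 0, quantile < 1)
  pool <- setdiff(unique(peptide_pool), exclude)
  if (length(pool) == 0) {
    stop("peptide pool exhausted after excluding ", length(exclude),
         " known positives (pool size ", length(unique(peptide_pool)), ")")
  }
  sc <- score_peptide(pwm, pool)
  cutoff <- stats::quantile(sc, quantile, names = FALSE)
  eligible <- pool[sc <= cutoff]
  if (length(eligible) < n_negatives) {
    stop("only ", length(eligible), " peptides in the bottom ", quantile,
         " quantile; ", n_negatives, " negatives requested")
  }
  chosen <- withr::with_seed(seed, sample(eligible, n_negatives))
  interaction_records(domain_id, chosen, -1L, "pwm_negative")
}

#' Is a peptide genomic with respect to a set of proteome tails?
#'
#' A peptide is genomic when its last four residues occur as the last four
#' residues of some C-terminal tail of the proteome.
#'
#' @param peptide Character vector of peptides (length >= 4 each).
#' @param proteome_tails Character vector of C-terminal tails (length >= 4).
#' @return Logical vector.
#' @export
is_genomic <- function(peptide, proteome_tails) {
  if (length(proteome_tails) == 0) return(rep(FALSE, length(peptide)))
  last4 <- function(x) substr(x, nchar(x) - 3L, nchar(x))
  last4(peptide) %in% unique(last4(proteome_tails))
}

#' Filter training domains by genomic-positive support
#'
#' Keeps a domain only if it has at least `min_genomic` genomic positive
#' peptides and at least one negative; domains failing either condition are
#' dropped with a message.
#'
#' @param records Interaction records.
#' @param proteome_tails C-terminal tails defining genomic peptides.
#' @param min_genomic Minimum genomic positives per domain (default 4).
#' @return Filtered `interaction_records`.
#' @export
filter_training_domains <- function(records, proteome_tails,
                                    min_genomic = 4L) {
  keep <- vapply(split(seq_len(nrow(records)), records$domain_id),
                 function(idx) {
    pos <- records$peptide[idx][records$label[idx] == 1]
    n_gen <- sum(is_genomic(pos, proteome_tails))
    n_neg <- sum(records$label[idx] == -1)
    n_gen >= min_genomic && n_neg >= 1
  }, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped) > 0) {
    message("filter_training_domains: dropped ", length(dropped),
            " domain(s): ", paste(dropped, collapse = ", "))
  }
  out <- records[records$domain_id %in% names(keep)[keep], , drop = FALSE]
  rownames(out) <- NULL
  validate_records(out)
}

#' Semi-supervised expansion of the negative training set
#'
#' Iteratively scans the proteome tails with the current model; any domain
#' with more predicted hits than `hit_threshold` contributes up to
#' `per_domain_cap` of its top-decision-value hits (that are not known
#' positives) as new negatives (source `svm_negative`), and the model is
#' retrained. Stops when every domain is at or below the threshold or after
#' `max_rounds` rounds (warning). Experimental records are never removed.
#'
#' @param records Initial interaction records.
#' @param domain_vectors Matrix of unscaled 240-value domain encodings,
#'   rownames = domain ids.
#' @param proteome_tails Unique C-terminal pentapeptides to scan.
#' @param per_domain_cap Max negatives added per domain per round.
#' @param hit_threshold Hit count above which a domain is over-predicting.
#' @param max_rounds Maximum expansion rounds.
#' @param gamma,C_minus,seed Passed to [pdz_train()].
#' @return List: `records` (augmented), `model` (final), `history` (data
#'   frame of per-round per-domain hit counts), `converged`.
#' @export
expand_negatives_semisupervised <- function(records, domain_vectors,
                                            proteome_tails,
                                            per_domain_cap = 10L,
                                            hit_threshold = 1000L,
                                            max_rounds = 5L,
                                            gamma = 1 / 340, C_minus = 1,
                                            seed = 1L) {
  history <- NULL
  model <- pdz_train(records, domain_vectors, gamma = gamma,
                     C_minus = C_minus, seed = seed)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    domains <- rownames(domain_vectors)
    domains <- intersect(domains, unique(records$domain_id))
    added <- 0L
    for (d in domains) {
      dv <- domain_decision_values(model, domain_vectors[d, ],
                                   proteome_tails)
      hits <- proteome_tails[dv >= 0]
      history <- rbind(history, data.frame(round = round, domain_id = d,
                                           hits = length(hits)))
      if (length(hits) <= hit_threshold) next
      known <- records$peptide[records$domain_id == d]
      cand <- setdiff(hits[order(dv[dv >= 0], decreasing = TRUE)], known)
      take <- utils::head(cand, per_domain_cap)
      if (length(take) == 0) next
      records <- validate_records(rbind(
        records, interaction_records(d, take, -1L, "svm_negative")))
      added <- added + length(take)
    }
    round_hits <- history$hits[history$round == round]
    if (all(round_hits <= hit_threshold)) {
      converged <- TRUE
      break
    }
    if (added == 0L) break
    model <- pdz_train(records, domain_vectors, gamma = gamma,
                       C_minus = C_minus, seed = seed)
  }
  if (!converged) {
    warning("semi-supervised expansion did not converge in ", max_rounds,
            " round(s); final mean hits/domain = ",
            round(mean(history$hits[history$round == max(history$round)]), 1))
  }
  list(records = records, model = model, history = history,
       converged = converged)
}
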