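#' Scan a C-terminal proteome with a trained model
#'
#' Every (domain, unique pentapeptide) pair is predicted once; hits
#' (decision value >= `min_decision`, default 0 i.e. the sign rule) are
#' then expanded back to all protein ids carrying that C-terminus.
#' Per-domain hit counts over unique peptides are reported as the
#' over-prediction diagnostic.
#'
#' @param model A `pdz_model`.
#' @param domain_vectors Matrix of unscaled 240-value domain encodings,
#'   rownames = domain ids.
#' @param ctermini Result of [extract_ctermini()] (list with `map` and
#'   `peptides`), or a character vector of unique pentapeptides.
#' @param min_decision Decision-value cutoff for a hit.
#' @return List with `hits` (data frame `domain_id`, `protein_id`,
#'   `peptide`, `decision_value`) and `counts` (named integer vector of
#'   unique-peptide hits per domain).
#' @export
scan_proteome <- function(model, domain_vectors, ctermini,
                          min_decision = 0) {
  if (is.character(ctermini)) {
    ctermini <- list(map = data.frame(id = ctermini, peptide = ctermini,
                                      stringsAsFactors = FALSE),
                     peptides = unique(ctermini))
  }
  peptides <- sort(ctermini$peptides)
  domains <- rownames(domain_vectors)
  counts <- stats::setNames(integer(length(domains)), domains)
  hits <- NULL
  for (d in domains) {
    dv <- domain_decision_values(model, domain_vectors[d, ], peptides)
    hit_peps <- peptides[dv >= min_decision]
    counts[d] <- length(hit_peps)
    if (length(hit_peps) == 0) next
    expanded <- ctermini$map[ctermini$map$peptide %in% hit_peps, ,
                             drop = FALSE]
    hits <- rbind(hits, data.frame(
      domain_id = d, protein_id = expanded$id, peptide = expanded$peptide,
      decision_value = unname(dv[expanded$peptide]),
      stringsAsFactors = FALSE))
  }
  if (is.null(hits)) {
    hits <- data.frame(domain_id = character(0), protein_id = character(0),
                       peptide = character(0), decision_value = numeric(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(hits = hits, counts = counts)
}

#' Summarize one domain's predicted binders as a PWM
#'
#' Builds a position weight matrix over the five ligand positions
#' (numbered -4..0, with 0 the C-terminus) from the unique peptides
#' predicted for a domain. Refuses to summarize fewer than `min_peptides`
#' peptides (logo construction convention: four or more).
#'
#' @param hits Character vector of hit peptides, or the `hits` data frame
#'   of [scan_proteome()] filtered to one domain.
#' @param pseudocount Pseudocount for [build_pwm()].
#' @param min_peptides Minimum number of unique peptides required.
#' @return A `PWM`.
#' @export
predicted_pwm <- function(hits, pseudocount = 0, min_peptides = 4L) {
  peps <- if (is.data.frame(hits)) unique(hits$peptide) else unique(hits)
  if (length(peps) < min_peptides) {
    stop("only ", length(peps), " unique predicted peptide(s); at least ",
         min_peptides, " required to summarize a binding specificity")
  }
  build_pwm(peps, pseudocount)
}

#' Render a PWM as an information-content sequence logo
#'
#' Letter heights are Schneider-Stephens information contributions:
#' `p * (log2(20) - H(column))`. Rendering is a reporting convenience and
#' requires ggplot2.
#'
#' @param pwm A `PWM`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_logo <- function(pwm, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_logo requires the ggplot2 package")
  }
  m <- unclass(pwm)
  ic <- apply(m, 2, function(p) {
    p_nz <- p[p > 0]
    log2(nrow(m)) + sum(p_nz * log2(p_nz))
  })
  df <- NULL
  for (j in seq_len(ncol(m))) {
    h <- m[, j] * ic[j]
    keep <- which(h > 1e-3)
    if (length(keep) == 0) next
    ord <- keep[order(h[keep])]
    tops <- cumsum(h[ord])
    df <- rbind(df, data.frame(
      pos = as.numeric(colnames(m)[j]), letter = rownames(m)[ord],
      height = h[ord], y = tops - h[ord] / 2))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$y,
                                   label = .data$letter,
                                   size = .data$height,
                                   colour = .data$letter)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 10)) +
    ggplot2::scale_x_continuous(breaks = as.numeric(colnames(m))) +
    ggplot2::labs(x = "peptide position", y = "information (bits)",
                  title = title) +
    ggplot2::theme_minimal()
}
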