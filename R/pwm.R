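#' Build a position weight matrix from aligned pentapeptides
#'
#' Column j probability of amino acid a is
#' `(count(a, j) + pseudocount) / (n + 20 * pseudocount)`.
#'
#' @param peptides Character vector of equal-length peptides (usually 5).
#' @param pseudocount Non-negative pseudocount added per cell.
#' @return A `PWM`: 20 x L probability matrix (rows in [AA_ALPHABET] order,
#'   columns labelled -(L-1)..0 with 0 the C-terminus) with attributes
#'   `pseudocount` and `n_sequences`.
#' @export
build_pwm <- function(peptides, pseudocount = 0) {
  if (length(peptides) == 0) stop("cannot build a PWM from zero peptides")
  L <- nchar(peptides[1])
  check_peptides(peptides, L)
  n <- length(peptides)
  chars <- do.call(rbind, strsplit(peptides, ""))
  m <- vapply(seq_len(L), function(j) {
    counts <- table(factor(chars[, j], levels = AA_ALPHABET))
    (as.numeric(counts) + pseudocount) / (n + 20 * pseudocount)
  }, numeric(20))
  dimnames(m) <- list(AA_ALPHABET, as.character(seq_len(L) - L))
  structure(m, class = c("PWM", "matrix"), pseudocount = pseudocount,
            n_sequences = n)
}

#' Log-odds PWM score of peptides
#'
#' Sum over positions of `log2(p(a, j) / background)`; the uniform
#' background is 0.05 per residue. Higher is a better match; the consensus
#' peptide achieves the maximum over all peptides of that length.
#'
#' @param pwm A `PWM`.
#' @param peptides Character vector of peptides (same length as PWM columns).
#' @param background Per-letter background probability.
#' @return Numeric vector of scores (bits).
#' @export
score_peptide <- function(pwm, peptides, background = 0.05) {
  L <- ncol(pwm)
  check_peptides(peptides, L)
  chars <- do.call(rbind, strsplit(peptides, ""))
  row_idx <- matrix(match(chars, rownames(pwm)), nrow = length(peptides))
  probs <- vapply(seq_len(L), function(j)
    unclass(pwm)[cbind(row_idx[, j], j)], numeric(length(peptides)))
  probs <- matrix(probs, nrow = length(peptides))
  if (any(probs == 0)) {
    stop("zero PWM probability encountered; rebuild the PWM with a ",
         "positive pseudocount")
  }
  rowSums(log2(probs / background))
}

#' Consensus peptide of a PWM (column-wise argmax)
#' @param pwm A `PWM`.
#' @return Single peptide string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(unclass(pwm), 2, which.max)], collapse = "")
}

#' Normalized Euclidean similarity between two PWMs
#'
#' `1 - D / D_max` where D is the Euclidean (Frobenius) distance between
#' the probability matrices and `D_max = sqrt(2 * ncol)` is the largest
#' distance achievable by column-stochastic matrices of that shape (one-hot
#' columns with disjoint letters). Identical matrices score 1; fully
#' disjoint one-hot matrices score 0.
#'
#' @param pwm_a,pwm_b PWMs of identical shape.
#' @return Similarity in [0, 1].
#' @export
pwm_similarity <- function(pwm_a, pwm_b) {
  if (!all(dim(pwm_a) == dim(pwm_b))) {
    stop("PWM shape mismatch: ", paste(dim(pwm_a), collapse = "x"), " vs ",
         paste(dim(pwm_b), collapse = "x"))
  }
  d <- sqrt(sum((unclass(pwm_a) - unclass(pwm_b))^2))
  1 - d / sqrt(2 * ncol(pwm_a))
}

#' Write / read a PWM as 20 x L TSV
#' @param pwm A `PWM`.
#' @param path File path.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(aa = rownames(pwm), unclass(pwm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$aa
  m <- m[AA_ALPHABET, , drop = FALSE]
  structure(m, class = c("PWM", "matrix"),
            pseudocount = NA_real_, n_sequences = NA_integer_)
}
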