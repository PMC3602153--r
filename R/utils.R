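`%||%` <- function(a, b) if (is.null(a)) b else a

# Element symbol from a PDB atom name ("OG1" -> "O", "SE" kept, "1HB" -> "H").
element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", trimmod(name))
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG"), two, one)
}

trimmod <- function(x) gsub("^\\s+|\\s+$", "", x)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

# Squared Euclidean distances between rows of A (n x 3) and B (m x 3).
sqdist_xyz <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Validate a vector of pentapeptides against the 20-letter alphabet.
check_peptides <- function(peptides, length = 5L) {
  if (!is.character(peptides)) stop("peptides must be character strings")
  bad_len <- nchar(peptides) != length
  if (any(bad_len)) {
    stop("peptide(s) not of length ", length, ": ",
         paste(utils::head(peptides[bad_len], 3), collapse = ", "))
  }
  letters_ok <- vapply(strsplit(peptides, ""), function(ch)
    all(ch %in% AA_ALPHABET), logical(1))
  if (!all(letters_ok)) {
    stop("peptide(s) contain non-standard letters: ",
         paste(utils::head(peptides[!letters_ok], 3), collapse = ", "))
  }
  invisible(peptides)
}
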