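# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# The default synthetic study: 20 domains, 2 archetypes, 30 pos + 60 neg
# per domain, 400-sequence proteome.
default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- suppressMessages(
      make_fixture_set(fixture_spec(seed = 1)))
  }
  .fixture_cache$default
}

# A small, fast variant for unit tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- suppressMessages(make_fixture_set(
      fixture_spec(seed = 7, n_domains = 4, n_pos = 10, n_neg = 20,
                   proteome_size = 60)))
  }
  .fixture_cache$small
}

# Interaction records plus random (structure-free) domain encodings --
# enough for SVM and CV mechanics where real geometry is irrelevant.
synthetic_learning_problem <- function(seed = 3, n_domains = 6,
                                       n_pos = 15, n_neg = 30) {
  spec <- fixture_spec(seed = seed, n_domains = n_domains, n_pos = n_pos,
                       n_neg = n_neg)
  ints <- make_interactions(spec)
  ids <- unique(ints$records$domain_id)
  arch <- ints$domain_info$archetype
  vecs <- withr::with_seed(seed, {
    base <- matrix(stats::runif(length(ids) * 240), nrow = length(ids))
    base[, 1:20] <- base[, 1:20] + 2 * arch  # archetype-separating block
    base
  })
  rownames(vecs) <- ids
  list(records = ints$records, domain_vectors = vecs, pwms = ints$pwms,
       domain_info = ints$domain_info, spec = spec)
}

# Minimal hand-built structure: Gly-Ser with the Ser OG hydrogen bonded
# to the Gly backbone carbonyl (2.9-3.1 A) and everything exposed.
gly_ser_hbond_structure <- function(og_xyz = c(5.0, 1.9, 0)) {
  at <- data.frame(
    name = c("N", "CA", "C", "O", "N", "CA", "CB", "OG", "C", "O"),
    element = c("N", "C", "C", "O", "N", "C", "C", "O", "C", "O"),
    residue_index = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L),
    residue_name = c(rep("GLY", 4), rep("SER", 6)),
    chain = "A",
    x = c(0, 1.4, 2.0, 2.0, 6, 7.4, 7.9, og_xyz[1], 8.5, 8.5),
    y = c(0, 0, 1.2, 2.43, 0, 0, 1.4, og_xyz[2], -1.2, -2.4),
    z = c(rep(0, 7), og_xyz[3], 0, 0),
    stringsAsFactors = FALSE)
  pdzpred:::new_domain_structure(at)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    th <- stats::runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                   0, -sin(th[1]), cos(th[1])), 3)
    Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                   sin(th[2]), 0, cos(th[2])), 3)
    Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3)
    Rx %*% Ry %*% Rz
  })
}

transform_structure <- function(structure, R, shift = c(0, 0, 0)) {
  X <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% R
  structure$atoms$x <- X[, 1] + shift[1]
  structure$atoms$y <- X[, 2] + shift[2]
  structure$atoms$z <- X[, 3] + shift[3]
  structure
}

# balanced pool whose PWM is exactly uniform: each letter once per column
AA_ALPHABET_pentapeptides <- function() {
  vapply(pdzpred::AA_ALPHABET, function(a)
    paste(rep(a, 5), collapse = ""), character(1), USE.NAMES = FALSE)
}

random_peptides <- function(n, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(pdzpred::AA_ALPHABET, 5, replace = TRUE), collapse = ""),
    character(1)))
}
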