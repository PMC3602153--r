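#' Classification metrics at the sign threshold
#'
#' Sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP). Ratios with a zero denominator are reported as
#' `NA` (undefined), never as 0.
#'
#' @param labels True labels (+1/-1).
#' @param predictions Predicted labels (+1/-1).
#' @return List with `sensitivity`, `specificity`, `precision`.
#' @export
compute_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == -1)
  tn <- sum(labels == -1 & predictions == -1)
  fp <- sum(labels == -1 & predictions == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp))
}

#' Areas under the ROC and precision-recall curves
#'
#' ROC AUC by the trapezoidal rule on the tie-grouped ROC curve (equal
#' decision values are collapsed into one curve vertex, equivalent to
#' midrank tie handling). PR AUC by trapezoidal interpolation over the
#' tie-grouped (recall, precision) points, anchored at recall 0 with the
#' precision of the highest-scoring group.
#'
#' @param labels True labels (+1/-1); both classes must be present.
#' @param decision_values Numeric scores, larger = more positive.
#' @return List with `roc_auc` and `pr_auc`.
#' @export
roc_pr_auc <- function(labels, decision_values) {
  stopifnot(length(labels) == length(decision_values))
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute AUCs")
  }
  ord <- order(decision_values, decreasing = TRUE)
  s <- decision_values[ord]
  y <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(as.numeric(y), grp, sum)
  fp_g <- tapply(as.numeric(!y), grp, sum)
  tp <- cumsum(tp_g)
  fp <- cumsum(fp_g)

  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  r <- c(0, recall)
  p <- c(precision[1], precision)
  pr_auc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)

  list(roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Binding-site sequence similarity (fraction identity)
#'
#' @param seq_a,seq_b Equal-length binding-site sequences (site length,
#'   default 10 in this package).
#' @return Fraction of identical positions, in [0, 1].
#' @export
domain_similarity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("binding-site sequences differ in length")
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  mean(a == b)
}

# n_draws independent holdout sets of ceil(frac * length(ids)) ids.
draw_holdouts <- function(ids, frac, n_draws, seed) {
  k <- max(1L, ceiling(frac * length(ids)))
  withr::with_seed(seed, lapply(seq_len(n_draws), function(i)
    sample(ids, k)))
}

fold_metrics <- function(train_rec, test_rec, domain_vectors, gamma,
                         C_minus, seed) {
  model <- pdz_train(train_rec, domain_vectors, gamma = gamma,
                     C_minus = C_minus, seed = seed)
  pred <- predict(model, test_rec, domain_vectors, check_scale = FALSE)
  m <- compute_metrics(test_rec$label, pred$label)
  auc <- roc_pr_auc(test_rec$label, pred$decision_value)
  c(sensitivity = m$sensitivity, specificity = m$specificity,
    precision = m$precision, roc_auc = auc$roc_auc, pr_auc = auc$pr_auc)
}

#' Cross-validation under the package's partition schemes
#'
#' `tenfold` partitions interactions into `folds` random sets, holding out
#' each in turn. `leave_domains` holds out `domain_frac` (default 12%) of
#' the domains with ALL their interactions, `leave_peptides` does likewise
#' for `peptide_frac` (default 8%) of the peptides, and `leave_both`
#' applies both holdouts simultaneously; these three repeat `repeats`
#' (default 10) independent seeded draws. Scalers (and any grid search)
#' are refit inside each training fold only.
#'
#' @param records Interaction records.
#' @param domain_vectors Domain encoding matrix (unscaled).
#' @param scheme One of `tenfold`, `leave_domains`, `leave_peptides`,
#'   `leave_both`.
#' @param folds Folds for the tenfold scheme.
#' @param domain_frac,peptide_frac Holdout fractions.
#' @param repeats Holdout draws for the leave-out schemes.
#' @param gamma,C_minus SVM hyperparameters used in every fold.
#' @param seed Integer seed.
#' @return A `pdz_cv` object: list with `results` (one row per run:
#'   sensitivity, specificity, precision, ROC and PR AUC), `folds` (held
#'   out record indices per run), `holdouts` (held-out domain/peptide
#'   sets for the entity-wise schemes), `scheme`, `seed`. Single-class
#'   test folds are skipped with a message and recorded as `NA`.
#' @export
run_cv <- function(records, domain_vectors,
                   scheme = c("tenfold", "leave_domains", "leave_peptides",
                              "leave_both"),
                   folds = 10L, domain_frac = 0.12, peptide_frac = 0.08,
                   repeats = 10L, gamma = 1 / 340, C_minus = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  records <- validate_records(records)
  n <- nrow(records)

  holdouts <- NULL
  test_sets <- switch(scheme,
    tenfold = {
      fold <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
      lapply(seq_len(folds), function(f) which(fold == f))
    },
    leave_domains = {
      hd <- draw_holdouts(unique(records$domain_id), domain_frac,
                          repeats, seed)
      holdouts <- lapply(hd, function(h) list(domains = h))
      lapply(hd, function(h) which(records$domain_id %in% h))
    },
    leave_peptides = {
      hp <- draw_holdouts(unique(records$peptide), peptide_frac,
                          repeats, seed)
      holdouts <- lapply(hp, function(h) list(peptides = h))
      lapply(hp, function(h) which(records$peptide %in% h))
    },
    leave_both = {
      hd <- draw_holdouts(unique(records$domain_id), domain_frac,
                          repeats, seed)
      hp <- draw_holdouts(unique(records$peptide), peptide_frac,
                          repeats, seed + 1L)
      holdouts <- lapply(seq_len(repeats), function(r)
        list(domains = hd[[r]], peptides = hp[[r]]))
      lapply(seq_len(repeats), function(r)
        which(records$domain_id %in% hd[[r]] |
                records$peptide %in% hp[[r]]))
    })

  res <- NULL
  for (r in seq_along(test_sets)) {
    test <- test_sets[[r]]
    train <- setdiff(seq_len(n), test)
    row <- c(sensitivity = NA_real_, specificity = NA_real_,
             precision = NA_real_, roc_auc = NA_real_, pr_auc = NA_real_)
    if (length(unique(records$label[test])) < 2 ||
        length(unique(records$label[train])) < 2) {
      message("run_cv: fold ", r, " has a single class; skipped")
    } else {
      row <- fold_metrics(records[train, , drop = FALSE],
                          records[test, , drop = FALSE],
                          domain_vectors, gamma, C_minus, seed)
    }
    res <- rbind(res, data.frame(run = r, t(row)))
  }
  structure(list(results = res, folds = test_sets, holdouts = holdouts,
                 scheme = scheme, seed = seed),
            class = "pdz_cv")
}

#' @export
print.pdz_cv <- function(x, ...) {
  cat("pdz_cv (", x$scheme, "): ", nrow(x$results), " runs; mean ROC AUC ",
      round(mean(x$results$roc_auc, na.rm = TRUE), 3), ", mean PR AUC ",
      round(mean(x$results$pr_auc, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Leave-domains-out CV with similarity-filtered training sets
#'
#' For each run, 12% of domains (and all their interactions) are held out;
#' a remaining domain is retained for training only when its binding-site
#' sequence similarity ([domain_similarity()]) to EVERY test domain is
#' below the threshold. Training sets are capped at `max_train`
#' interactions by seeded random subsampling. `folds` holdout draws are
#' executed per repeat for `repeats` repeats (default 10 x 10 = 100 runs
#' per threshold). A threshold >= 1 + epsilon filters nothing and
#' reproduces the plain leave-domains fold composition for the same seed.
#'
#' @param records Interaction records.
#' @param domain_vectors Domain encoding matrix.
#' @param site_sequences Named character vector: binding-site sequence per
#'   domain id.
#' @param thresholds Numeric similarity thresholds to evaluate.
#' @param folds,repeats Holdout draws per repeat, and repeats.
#' @param domain_frac Fraction of domains held out per run.
#' @param max_train Cap on training interactions (spec of the study: 500).
#' @param gamma,C_minus,seed As in [run_cv()].
#' @return List with `results` (long data frame: threshold, run, AUCs;
#'   runs with an empty training set are recorded as `NA`, i.e. missing)
#'   and `folds` (held-out domains per run).
#' @export
similarity_filtered_cv <- function(records, domain_vectors, site_sequences,
                                   thresholds, folds = 10L, repeats = 10L,
                                   domain_frac = 0.12, max_train = 500L,
                                   gamma = 1 / 340, C_minus = 1, seed = 1L) {
  records <- validate_records(records)
  domains <- unique(records$domain_id)
  stopifnot(all(domains %in% names(site_sequences)))
  n_runs <- folds * repeats
  holdouts <- draw_holdouts(domains, domain_frac, n_runs, seed)

  sim <- function(a, b) domain_similarity(site_sequences[[a]],
                                          site_sequences[[b]])
  res <- NULL
  for (th in thresholds) {
    for (r in seq_len(n_runs)) {
      test_dom <- holdouts[[r]]
      train_dom <- setdiff(domains, test_dom)
      ok <- vapply(train_dom, function(d)
        all(vapply(test_dom, function(t) sim(d, t) < th, logical(1))),
        logical(1))
      train_dom <- train_dom[ok]
      test <- which(records$domain_id %in% test_dom)
      train <- which(records$domain_id %in% train_dom)
      if (length(train) > max_train) {
        train <- withr::with_seed(seed + 1000L * r,
                                  sample(train, max_train))
      }
      row <- data.frame(threshold = th, run = r, n_train = length(train),
                        roc_auc = NA_real_, pr_auc = NA_real_)
      if (length(train) > 0 &&
          length(unique(records$label[train])) == 2 &&
          length(unique(records$label[test])) == 2) {
        m <- fold_metrics(records[train, , drop = FALSE],
                          records[test, , drop = FALSE],
                          domain_vectors, gamma, C_minus, seed)
        row$roc_auc <- m["roc_auc"]
        row$pr_auc <- m["pr_auc"]
      }
      res <- rbind(res, row)
    }
  }
  rownames(res) <- NULL
  list(results = res, folds = holdouts)
}

#' Export CV results in long, box-plot-ready form
#'
#' @param cv A `pdz_cv` or the result of [similarity_filtered_cv()].
#' @param path Optional TSV path to write.
#' @return Long data frame (one row per run and metric).
#' @export
cv_long <- function(cv, path = NULL) {
  df <- if (inherits(cv, "pdz_cv")) cv$results else cv$results
  long <- stats::reshape(
    df, direction = "long",
    varying = c("roc_auc", "pr_auc"), v.names = "auc",
    times = c("roc_auc", "pr_auc"), timevar = "metric")
  rownames(long) <- NULL
  long$id <- NULL
  if (!is.null(path)) {
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  long
}
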