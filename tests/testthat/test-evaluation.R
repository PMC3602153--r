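test_that("metrics instantiate the printed formulas and flag undefined ratios", {
  # TP=3, FN=1, TN=4, FP=2
  labels <- c(1, 1, 1, 1, -1, -1, -1, -1, -1, -1)
  preds <- c(1, 1, 1, -1, 1, 1, -1, -1, -1, -1)
  m <- compute_metrics(labels, preds)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$precision, 3 / 5)

  perfect <- compute_metrics(labels, labels)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  precision = 1))

  all_neg <- compute_metrics(labels, rep(-1, 10))
  expect_true(is.na(all_neg$precision))  # undefined, not zero
  expect_error(compute_metrics(labels, preds[-1]), "length")
})

test_that("ROC AUC equals the Mann-Whitney statistic on random instances", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- sample(20:120, 1)
      labels <- sample(c(-1, 1), n, replace = TRUE,
                       prob = c(0.6, 0.4))
      if (length(unique(labels)) < 2) next
      # mix continuous and heavily tied score sets
      scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
      n_pos <- sum(labels == 1)
      n_neg <- sum(labels == -1)
      u <- sum(rank(scores)[labels == 1]) - n_pos * (n_pos + 1) / 2
      expect_equal(roc_pr_auc(labels, scores)$roc_auc,
                   u / (n_pos * n_neg), tolerance = 1e-9)
    }
    # one large instance
    labels <- sample(c(-1, 1), 1000, replace = TRUE)
    scores <- rnorm(1000)
    n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
    u <- sum(rank(scores)[labels == 1]) - n_pos * (n_pos + 1) / 2
    expect_equal(roc_pr_auc(labels, scores)$roc_auc, u / (n_pos * n_neg),
                 tolerance = 1e-9)
  })
})

test_that("random scores give ROC 0.5 and PR equal to the positive fraction", {
  withr::with_seed(19, {
    labels <- sample(c(-1, 1), 10000, replace = TRUE, prob = c(0.7, 0.3))
    scores <- rnorm(10000)
    auc <- roc_pr_auc(labels, scores)
    expect_equal(auc$roc_auc, 0.5, tolerance = 0.02)
    expect_equal(auc$pr_auc, mean(labels == 1), tolerance = 0.02)
  })
  # scores equal to labels: perfect ranking
  labels <- c(rep(1, 5), rep(-1, 5))
  expect_equal(roc_pr_auc(labels, labels)$roc_auc, 1.0)
  expect_error(roc_pr_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("binding-site sequence similarity is fraction identity", {
  expect_equal(domain_similarity("LGIRESFGHA", "LGIRESFGHA"), 1.0)
  expect_equal(domain_similarity("LGIRESFGHA", "LGIREAAAAC"), 0.5)
  expect_equal(domain_similarity("AAAAA", "CCCCC"), 0)
  # invariant under a common position permutation
  a <- "LGIRESFGHA"; b <- "LGIREAAAAC"
  perm <- withr::with_seed(3, sample(10))
  ap <- paste(strsplit(a, "")[[1]][perm], collapse = "")
  bp <- paste(strsplit(b, "")[[1]][perm], collapse = "")
  expect_equal(domain_similarity(ap, bp), domain_similarity(a, b))
  expect_error(domain_similarity("AAA", "AAAA"), "length")
})

test_that("tenfold CV partitions interactions into disjoint, covering folds", {
  prob <- synthetic_learning_problem(seed = 3, n_domains = 4)
  cv <- run_cv(prob$records, prob$domain_vectors, "tenfold", folds = 5,
               seed = 2)
  expect_equal(nrow(cv$results), 5)
  held <- unlist(cv$folds)
  expect_setequal(held, seq_len(nrow(prob$records)))
  expect_equal(anyDuplicated(held), 0)
  expect_true(all(cv$results$roc_auc > 0.8))  # planted signal is learnable
})

test_that("leave-domain folds share no domain between train and test", {
  prob <- synthetic_learning_problem(seed = 3, n_domains = 8)
  cv <- run_cv(prob$records, prob$domain_vectors, "leave_domains",
               domain_frac = 0.25, repeats = 4, seed = 2)
  for (f in cv$folds) {
    test_dom <- unique(prob$records$domain_id[f])
    train_dom <- unique(prob$records$domain_id[-f])
    expect_length(intersect(test_dom, train_dom), 0)
    expect_equal(length(test_dom), 2)   # 25% of 8 domains
    # all interactions of a held-out domain are held out together
    expect_setequal(f, which(prob$records$domain_id %in% test_dom))
  }
})

test_that("leave-peptide and leave-both folds hold out whole entities", {
  prob <- synthetic_learning_problem(seed = 4, n_domains = 6)
  cvp <- run_cv(prob$records, prob$domain_vectors, "leave_peptides",
                peptide_frac = 0.08, repeats = 3, seed = 5)
  for (r in seq_along(cvp$folds)) {
    held <- cvp$holdouts[[r]]$peptides
    train <- setdiff(seq_len(nrow(prob$records)), cvp$folds[[r]])
    expect_length(intersect(held, prob$records$peptide[train]), 0)
    expect_setequal(cvp$folds[[r]],
                    which(prob$records$peptide %in% held))
  }
  cvb <- run_cv(prob$records, prob$domain_vectors, "leave_both",
                domain_frac = 0.2, peptide_frac = 0.08, repeats = 3,
                seed = 5)
  for (r in seq_along(cvb$folds)) {
    held <- cvb$holdouts[[r]]
    train <- setdiff(seq_len(nrow(prob$records)), cvb$folds[[r]])
    expect_length(intersect(held$domains,
                            prob$records$domain_id[train]), 0)
    expect_length(intersect(held$peptides,
                            prob$records$peptide[train]), 0)
  }
})

test_that("similarity filtering at threshold > 1 reproduces plain leave-domain folds", {
  prob <- synthetic_learning_problem(seed = 6, n_domains = 6)
  sims <- stats::setNames(
    c("AAAAAAAAAA", "AAAAAAAAAC", "CCCCCCCCCC", "CCCCCCCCCA",
      "GGGGGGGGGG", "GGGGGGGGGA"),
    unique(prob$records$domain_id))
  plain <- run_cv(prob$records, prob$domain_vectors, "leave_domains",
                  repeats = 4, seed = 9)
  filt <- similarity_filtered_cv(prob$records, prob$domain_vectors, sims,
                                 thresholds = 1.01, folds = 4, repeats = 1,
                                 max_train = Inf, seed = 9)
  held_plain <- lapply(plain$folds, function(f)
    sort(unique(prob$records$domain_id[f])))
  held_filt <- lapply(filt$folds, sort)
  expect_equal(held_filt, held_plain)
  # nothing filtered, so every record outside the holdout is trained on
  expect_equal(filt$results$n_train,
               vapply(plain$folds, function(f) nrow(prob$records) -
                        length(f), numeric(1)))
})

test_that("similarity filtering removes near-duplicate training domains and caps size", {
  prob <- synthetic_learning_problem(seed = 6, n_domains = 6)
  doms <- unique(prob$records$domain_id)
  # two similarity clusters of three domains each
  sims <- stats::setNames(
    c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAAACC",
      "GGGGGGGGGG", "GGGGGGGGGA", "GGGGGGGGAA"), doms)
  filt <- similarity_filtered_cv(prob$records, prob$domain_vectors, sims,
                                 thresholds = c(0.5, 0), folds = 3,
                                 repeats = 1, max_train = 50, seed = 9)
  res <- filt$results
  expect_true(all(res$n_train <= 50))
  # at or below the minimum pairwise similarity nothing can be trained
  low <- res[res$threshold == 0, ]
  expect_true(all(low$n_train == 0))
  expect_true(all(is.na(low$roc_auc)))
  mid <- res[res$threshold == 0.5, ]
  expect_true(any(mid$n_train > 0))
})

test_that("CV results export to long box-plot-ready format", {
  prob <- synthetic_learning_problem(seed = 3, n_domains = 4)
  cv <- run_cv(prob$records, prob$domain_vectors, "tenfold", folds = 3,
               seed = 2)
  long <- cv_long(cv)
  expect_setequal(unique(long$metric), c("roc_auc", "pr_auc"))
  expect_equal(nrow(long), 2 * nrow(cv$results))
  path <- withr::local_tempfile(fileext = ".tsv")
  cv_long(cv, path)
  expect_true(file.exists(path))
})
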