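#' Concatenate a domain encoding and a peptide encoding
#'
#' @param domain_vec Numeric vector of length 240 ([encode_domain()]).
#' @param pep_vec Integer vector of length 100 ([encode_peptide()]).
#' @return Numeric vector of length 340, domain block first.
#' @export
assemble_pair_vector <- function(domain_vec, pep_vec) {
  if (length(domain_vec) != 240) {
    stop("domain vector has length ", length(domain_vec), ", expected 240")
  }
  if (length(pep_vec) != 100) {
    stop("peptide vector has length ", length(pep_vec), ", expected 100")
  }
  c(unclass(domain_vec), as.numeric(pep_vec))
}

#' Radial basis function kernel
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`, in (0, 1].
#'
#' @param x_i,x_j Equal-length numeric vectors.
#' @param gamma Non-negative kernel width.
#' @return Kernel value.
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  stopifnot(length(x_i) == length(x_j), gamma >= 0)
  if (anyNA(x_i) || anyNA(x_j) || !all(is.finite(c(x_i, x_j)))) {
    stop("non-finite values in kernel input")
  }
  exp(-gamma * sum((x_i - x_j)^2))
}

# RBF kernel matrix between rows of A and rows of B.
kernel_matrix <- function(A, B, gamma) {
  exp(-gamma * sqdist_xyz(as.matrix(A), as.matrix(B)))
}

# Build the raw (unscaled) 340-column design matrix for records.
assemble_design <- function(records, domain_vectors) {
  missing <- setdiff(unique(records$domain_id), rownames(domain_vectors))
  if (length(missing) > 0) {
    stop("no domain encoding for: ", paste(missing, collapse = ", "))
  }
  peps <- unique(records$peptide)
  P <- t(vapply(peps, encode_peptide, integer(100)))
  X <- cbind(domain_vectors[records$domain_id, , drop = FALSE],
             P[match(records$peptide, peps), , drop = FALSE])
  rownames(X) <- NULL
  X
}

#' Train the cost-weighted RBF support vector classifier
#'
#' Solves the soft-margin dual with per-class box constraints, using
#' weighted costs `C+ = (n+/n-) * C-` exactly as printed in the method
#' (this down-weights the larger class only when positives are the
#' minority; set `invert_class_weights = TRUE` for the conventional
#' `n-/n+` form). Features are min-max scaled with a scaler fitted on
#' these training records only. The dual is solved by libsvm (e1071); the
#' fitted model stores support vectors, dual coefficients `alpha_i * y_i`
#' (oriented so positive decision values mean class +1), bias, kernel and
#' cost parameters, and the scaler.
#'
#' @param records Interaction records (both classes present).
#' @param domain_vectors Matrix of unscaled 240-value domain encodings with
#'   rownames = domain ids.
#' @param gamma RBF kernel width.
#' @param C_minus Cost parameter for the negative class.
#' @param seed Integer seed (stored; training itself is deterministic).
#' @param invert_class_weights Use `C+ = (n-/n+) C-` instead.
#' @return A `pdz_model`.
#' @export
pdz_train <- function(records, domain_vectors, gamma = 1 / 340, C_minus = 1,
                      seed = 1L, invert_class_weights = FALSE) {
  records <- validate_records(records)
  n_pos <- sum(records$label == 1)
  n_neg <- sum(records$label == -1)
  if (n_pos == 0 || n_neg == 0) {
    stop("training requires both classes (got ", n_pos, " positive, ",
         n_neg, " negative)")
  }
  X <- assemble_design(records, domain_vectors)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  y <- factor(records$label, levels = c("-1", "1"))
  w_pos <- if (invert_class_weights) n_neg / n_pos else n_pos / n_neg
  fit <- withr::with_seed(seed, e1071::svm(
    Xs, y, scale = FALSE, type = "C-classification", kernel = "radial",
    gamma = gamma, cost = C_minus,
    class.weights = c("-1" = 1, "1" = w_pos)))

  # orient so that positive decision values mean class +1
  dv <- attr(stats::predict(fit, Xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  orient <- if (colnames(dv)[1] == "1/-1") 1 else -1

  model <- structure(list(
    sv = fit$SV,
    alpha_y = orient * as.numeric(fit$coefs),
    b = -orient * fit$rho,
    gamma = gamma,
    cost_neg = C_minus,
    cost_pos = w_pos * C_minus,
    scaler = scaler,
    n_pos = n_pos, n_neg = n_neg, seed = seed,
    libsvm = fit
  ), class = "pdz_model")
  model
}

#' @export
print.pdz_model <- function(x, ...) {
  cat("pdz_model: ", nrow(x$sv), " support vectors, gamma = ",
      signif(x$gamma, 4), ", C- = ", signif(x$cost_neg, 4), ", C+ = ",
      signif(x$cost_pos, 4), " (n+ = ", x$n_pos, ", n- = ", x$n_neg, ")\n",
      sep = "")
  invisible(x)
}

# Decision values for raw (unscaled) pair vectors via the model's own
# kernel expansion: f(x) = sum_i alpha_i y_i K(x_i, x) + b.
model_decision_values <- function(model, X_raw, check_scale = TRUE) {
  Xs <- apply_scaler(model$scaler, X_raw)
  if (check_scale && (min(Xs) < -0.5 || max(Xs) > 1.5)) {
    warning("input features far outside the training [0,1] range; ",
            "was the input assembled with the model's scaler inputs?")
  }
  as.numeric(kernel_matrix(Xs, model$sv, model$gamma) %*% model$alpha_y +
               model$b)
}

# Decision values of one domain vector against many peptides.
domain_decision_values <- function(model, domain_vec, peptides) {
  P <- t(vapply(peptides, encode_peptide, integer(100)))
  X <- cbind(matrix(rep(as.numeric(domain_vec), each = length(peptides)),
                    nrow = length(peptides)), P)
  stats::setNames(model_decision_values(model, X), peptides)
}

#' Predict interaction labels for domain-peptide pairs
#'
#' Decision values are computed with the package's own kernel expansion
#' over the stored support vectors; the label is +1 when the decision
#' value is >= 0 (sgn(0) = +1), -1 otherwise.
#'
#' @param object A `pdz_model`.
#' @param pairs Data frame with columns `domain_id` and `peptide`, or a raw
#'   numeric matrix of 340-column pair vectors.
#' @param domain_vectors Domain encoding matrix (required for the data
#'   frame form).
#' @param check_scale Warn when inputs fall far outside the training
#'   feature range.
#' @param ... Unused.
#' @return Data frame with `domain_id`, `peptide` (when available),
#'   `decision_value` and `label`.
#' @export
predict.pdz_model <- function(object, pairs, domain_vectors = NULL,
                              check_scale = TRUE, ...) {
  if (is.matrix(pairs)) {
    dv <- model_decision_values(object, pairs, check_scale)
    return(data.frame(decision_value = dv,
                      label = ifelse(dv >= 0, 1L, -1L)))
  }
  stopifnot(is.data.frame(pairs), !is.null(domain_vectors))
  X <- assemble_design(pairs, domain_vectors)
  dv <- model_decision_values(object, X, check_scale)
  data.frame(domain_id = pairs$domain_id, peptide = pairs$peptide,
             decision_value = dv, label = ifelse(dv >= 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Grid search for kernel width and cost
#'
#' Evaluates every (gamma, C-) pair by seeded `inner_folds`-fold cross
#' validation on the training records, scoring mean ROC AUC, and returns
#' the maximizer; ties are broken by smaller C-, then smaller gamma. Folds
#' whose test set contains a single class are skipped with a warning.
#'
#' @param records Interaction records.
#' @param domain_vectors Domain encoding matrix.
#' @param gamma_grid,C_grid Numeric grids (defaults: powers of two,
#'   2^-15..2^3 and 2^-5..2^15).
#' @param inner_folds Number of inner CV folds.
#' @param seed Integer seed controlling fold assignment.
#' @return List with `gamma`, `C_minus` and the full score `table`.
#' @export
grid_search <- function(records, domain_vectors,
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        C_grid = 2^seq(-5, 15, by = 2),
                        inner_folds = 5L, seed = 1L) {
  stopifnot(length(gamma_grid) > 0, length(C_grid) > 0)
  n <- nrow(records)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(inner_folds), n)))
  grid <- expand.grid(gamma = gamma_grid, C_minus = C_grid)
  grid$mean_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- c()
    for (f in seq_len(inner_folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(records$label[test])) < 2 ||
          length(unique(records$label[train])) < 2) {
        warning("grid_search: single-class fold ", f, " skipped")
        next
      }
      m <- pdz_train(records[train, , drop = FALSE], domain_vectors,
                     gamma = grid$gamma[g], C_minus = grid$C_minus[g],
                     seed = seed)
      pred <- predict(m, records[test, , drop = FALSE], domain_vectors)
      aucs <- c(aucs, roc_pr_auc(records$label[test],
                                 pred$decision_value)$roc_auc)
    }
    grid$mean_auc[g] <- if (length(aucs)) mean(aucs) else NA_real_
  }
  ord <- order(-grid$mean_auc, grid$C_minus, grid$gamma)
  best <- grid[ord[1], ]
  list(gamma = best$gamma, C_minus = best$C_minus, table = grid)
}

#' Persist a trained model as portable JSON text
#'
#' Stores support vectors, oriented dual coefficients, bias, kernel/cost
#' parameters and the feature scaler. A loaded model predicts through the
#' package's kernel expansion, identically to the original.
#'
#' @param model A `pdz_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  obj <- model[c("sv", "alpha_y", "b", "gamma", "cost_neg", "cost_pos",
                 "n_pos", "n_neg", "seed")]
  obj$sv <- unname(as.matrix(obj$sv))
  obj$scaler_min <- unname(model$scaler$min)
  obj$scaler_max <- unname(model$scaler$max)
  obj$feature_names <- names(model$scaler$min)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(list(
    min = stats::setNames(obj$scaler_min, obj$feature_names),
    max = stats::setNames(obj$scaler_max, obj$feature_names)),
    class = "FeatureScaler")
  structure(list(sv = as.matrix(obj$sv), alpha_y = obj$alpha_y, b = obj$b,
                 gamma = obj$gamma, cost_neg = obj$cost_neg,
                 cost_pos = obj$cost_pos, scaler = scaler,
                 n_pos = obj$n_pos, n_neg = obj$n_neg, seed = obj$seed,
                 libsvm = NULL),
            class = "pdz_model")
}
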