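# Connectome-based prediction protocol: per-fold correlation feature
# selection, epsilon-SVR with fixed default hyperparameters, repeated
# k-fold cross-validation, permutation significance, split-half age-group
# transfer, FDR predictive-pattern discovery.

#' Prediction protocol configuration
#'
#' The SVR hyperparameters are pinned to the canonical libsvm/e1071
#' defaults (radial-basis kernel, cost 1, epsilon 0.1, gamma = 1 / number
#' of selected features, training-fold standardization of X and y); the
#' protocol defaults are 10 folds, 1000 repeats and 1000 permutations,
#' all scalable down.
#'
#' @param k_folds Folds per cross-validation repeat (default 10).
#' @param n_repeats Independent CV repetitions (default 1000).
#' @param selection_alpha Per-fold feature-selection threshold (default 0.05).
#' @param n_permutations Permutations for the significance test (default 1000).
#' @param seed Master seed; every partition/permutation derives from it.
#' @param cost,epsilon SVR cost and epsilon-tube (defaults 1, 0.1).
#' @return A list of class `wmcov_prediction_config`.
#' @export
prediction_config <- function(k_folds = 10L, n_repeats = 1000L,
                              selection_alpha = 0.05,
                              n_permutations = 1000L, seed = 1L,
                              cost = 1, epsilon = 0.1) {
  stopifnot(k_folds >= 2L, n_repeats >= 1L,
            selection_alpha > 0, selection_alpha < 1)
  structure(list(k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 selection_alpha = selection_alpha,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 svr = list(kernel = "radial", cost = cost, epsilon = epsilon,
                            gamma = "1/n_features")),
            class = "wmcov_prediction_config")
}

#' Correlation-based feature selection
#'
#' Selects the edges whose Pearson correlation with the training scores is
#' significant at `alpha` (two-sided t-test, df = n_train - 2). Constant
#' columns are excluded with a warning rather than an error. May return an
#' empty set.
#'
#' @param edge_matrix n_train x E numeric matrix.
#' @param scores Length-n_train numeric vector.
#' @param alpha Threshold on the two-sided p (default 0.05).
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_features <- function(edge_matrix, scores, alpha = 0.05) {
  stopifnot(is.matrix(edge_matrix), length(scores) == nrow(edge_matrix))
  n <- nrow(edge_matrix)
  if (n < 10L) stop_wmcov("need at least 10 training subjects, got %d", n)
  sds <- apply(edge_matrix, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    warning(sprintf("%d constant edge column(s) excluded from selection",
                    sum(const)), call. = FALSE)
  p <- rep(1, ncol(edge_matrix))
  if (any(!const)) {
    r <- suppressWarnings(as.vector(stats::cor(edge_matrix[, !const, drop = FALSE],
                                               scores)))
    df <- n - 2L
    tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p[!const] <- 2 * stats::pt(tstat, df = df, lower.tail = FALSE)
  }
  which(p < alpha & !const)
}

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an epsilon-SVR on a training fold and predict a test fold
#'
#' Standardizes features and target with training-fold statistics, fits a
#' radial-basis epsilon-SVR at the fixed default hyperparameters
#' (cost = 1, epsilon = 0.1, gamma = 1/ncol(X)), and maps test predictions
#' back to the original score scale. With zero columns in `X_train`
#' (empty feature selection) the training mean is predicted, mirroring the
#' documented fallback.
#'
#' @param X_train,X_test Numeric matrices with matching columns.
#' @param y_train Numeric training scores.
#' @param config A [prediction_config()].
#' @return Numeric predictions for the rows of `X_test`.
#' @export
fit_predict_svr <- function(X_train, y_train, X_test,
                            config = prediction_config()) {
  stopifnot(is.matrix(X_train), is.matrix(X_test),
            ncol(X_train) == ncol(X_test), nrow(X_train) == length(y_train))
  n_test <- nrow(X_test)
  if (ncol(X_train) == 0L) return(rep(mean(y_train), n_test))
  mu_y <- mean(y_train); sd_y <- stats::sd(y_train)
  if (sd_y == 0) return(rep(mu_y, n_test))

  mu_x <- colMeans(X_train)
  sd_x <- apply(X_train, 2, stats::sd)
  sd_x[sd_x == 0] <- 1
  Xtr <- sweep(sweep(X_train, 2, mu_x), 2, sd_x, "/")
  Xte <- sweep(sweep(X_test, 2, mu_x), 2, sd_x, "/")
  ys <- (y_train - mu_y) / sd_y

  gamma <- 1 / ncol(X_train)
  K <- .rbf_kernel(Xtr, Xtr, gamma)
  fit <- svr_smo(K, ys, C = config$svr$cost, eps = config$svr$epsilon)
  Ktest <- .rbf_kernel(Xte, Xtr, gamma)
  pred_s <- as.vector(Ktest %*% fit$beta) + fit$b
  pred_s * sd_y + mu_y
}

#' Permutation p-value for predicted-vs-observed correlation
#'
#' Two-sided: `p = (1 + #{|r_perm| >= |r_obs|}) / (n_permutations + 1)`,
#' permuting the observed-score vector.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 10).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return Scalar p in (0, 1].
#' @export
permutation_pvalue <- function(observed, predicted, n_permutations = 1000L,
                               seed = 1L) {
  n <- length(observed)
  stopifnot(length(predicted) == n, n >= 10L)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop_wmcov("constant vector; correlation (and its permutation test) undefined")
  r_obs <- abs(stats::cor(observed, predicted))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    r_b <- abs(stats::cor(observed[sample.int(n)], predicted))
    if (r_b >= r_obs - 1e-15) hits <- hits + 1L
  }
  (1 + hits) / (n_permutations + 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# pooled out-of-fold predictions for a given fold assignment
.cv_fixed_folds <- function(X, y, fold, config) {
  pred <- numeric(nrow(X))
  n_sel <- integer(config$k_folds)
  for (k in seq_len(config$k_folds)) {
    te <- fold == k
    sel <- suppressWarnings(
      select_features(X[!te, , drop = FALSE], y[!te], config$selection_alpha))
    n_sel[k] <- length(sel)
    pred[te] <- fit_predict_svr(X[!te, sel, drop = FALSE], y[!te],
                                X[te, sel, drop = FALSE], config)
  }
  list(pred = pred, fold = fold, n_selected = n_sel)
}

# one repeat of k-fold CV with a fresh random partition
.cv_one_repeat <- function(X, y, config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(config$k_folds), length.out = nrow(X)))
  .cv_fixed_folds(X, y, fold, config)
}

# Protocol-level permutation test: the whole pipeline (per-fold feature
# selection + SVR fit) is re-run on each permuted score vector, holding
# the first repeat's fold partition fixed. Shuffling scores against FIXED
# cross-validated predictions is anticonservative -- the predictions
# depend on the scores through the training folds, so the real null
# distribution of r is wider than the naive permutation null.
.cv_permutation_p <- function(X, y, fold, r_obs, config, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  B <- config$n_permutations
  hits <- 0L
  for (b in seq_len(B)) {
    yb <- y[sample.int(length(y))]
    rb <- stats::cor(.cv_fixed_folds(X, yb, fold, config)$pred, yb)
    if (is.na(rb)) rb <- 0
    if (abs(rb) >= abs(r_obs) - 1e-15) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

#' Repeated k-fold cross-validated prediction
#'
#' For each repeat, a fresh random fold partition; inside each fold,
#' feature selection and standardization use the training folds only
#' (the held-out fold never touches selection or fitting). Per repeat the
#' pooled out-of-fold predictions give one r and one MAE; the summary is
#' their mean and sd over repeats. The permutation p-value re-runs the
#' entire selection + SVR pipeline on each permuted score vector (first
#' repeat's fold partition held fixed): shuffling scores against fixed
#' cross-validated predictions is anticonservative, because the
#' predictions depend on the scores through the training folds.
#'
#' @param edge_table N x E matrix of subject edge vectors.
#' @param scores Length-N scores (`NA` allowed; complete-case).
#' @param config A [prediction_config()].
#' @return Object of class `wmcov_performance`: `r_mean`, `r_sd`,
#'   `mae_mean`, `mae_sd`, `permutation_p`, `n_subjects_used`, `per_repeat`
#'   (data.frame), `mean_n_selected`, and `first_repeat` (pooled
#'   predictions, fold assignment and complete-case indices of the first
#'   repetition, e.g. for leakage audits).
#' @export
repeated_cv <- function(edge_table, scores, config = prediction_config()) {
  stopifnot(is.matrix(edge_table), length(scores) == nrow(edge_table))
  ok <- !is.na(scores)
  X <- edge_table[ok, , drop = FALSE]
  y <- scores[ok]
  if (length(y) < 30L)
    stop_wmcov("only %d complete cases; need at least 30", length(y))
  reps <- lapply(seq_len(config$n_repeats), function(rep_i)
    .cv_one_repeat(X, y, config, derive_seed(config$seed, rep_i)))
  r_vec <- vapply(reps, function(z) stats::cor(z$pred, y), 1)
  mae_vec <- vapply(reps, function(z) mean(abs(z$pred - y)), 1)
  perm_p <- .cv_permutation_p(X, y, reps[[1]]$fold, r_vec[1], config,
                              derive_seed(config$seed, 0L))
  structure(list(r_mean = mean(r_vec), r_sd = stats::sd(r_vec),
                 mae_mean = mean(mae_vec), mae_sd = stats::sd(mae_vec),
                 permutation_p = perm_p, n_subjects_used = length(y),
                 per_repeat = data.frame(repeat_id = seq_along(r_vec),
                                         r = r_vec, mae = mae_vec),
                 mean_n_selected = mean(unlist(lapply(reps, `[[`, "n_selected"))),
                 first_repeat = list(pred = reps[[1]]$pred,
                                     fold = reps[[1]]$fold,
                                     complete_cases = which(ok)),
                 config = config),
            class = "wmcov_performance")
}

#' Split-half age-group transfer
#'
#' Splits subjects at the mean age (subjects at or below the mean form the
#' younger group), trains the full pipeline (selection + SVR) on one group
#' and tests once on the other, in both directions.
#'
#' @param edge_table N x E matrix.
#' @param scores Length-N scores (`NA` allowed).
#' @param ages Length-N ages.
#' @param config A [prediction_config()].
#' @return List with `young_to_old` and `old_to_young`, each holding
#'   `r`, `mae`, `permutation_p`, `n_train`, `n_test`.
#' @export
split_half_transfer <- function(edge_table, scores, ages,
                                config = prediction_config()) {
  stopifnot(nrow(edge_table) == length(scores), length(ages) == length(scores))
  ok <- !is.na(scores)
  X <- edge_table[ok, , drop = FALSE]; y <- scores[ok]; a <- ages[ok]
  young <- a <= mean(a)   # age ties go to the younger group
  if (sum(young) < 15L || sum(!young) < 15L)
    stop_wmcov("each age group needs >= 15 complete cases (got %d / %d)",
               sum(young), sum(!young))
  run_dir <- function(tr, stream) {
    sel <- suppressWarnings(
      select_features(X[tr, , drop = FALSE], y[tr], config$selection_alpha))
    pred <- fit_predict_svr(X[tr, sel, drop = FALSE], y[tr],
                            X[!tr, sel, drop = FALSE], config)
    list(r = stats::cor(pred, y[!tr]), mae = mean(abs(pred - y[!tr])),
         permutation_p = permutation_pvalue(y[!tr], pred,
                                            config$n_permutations,
                                            derive_seed(config$seed, stream)),
         n_train = sum(tr), n_test = sum(!tr), n_selected = length(sel))
  }
  list(young_to_old = run_dir(young, 101L),
       old_to_young = run_dir(!young, 102L))
}

#' Predictive pattern discovery
#'
#' Correlates every edge with the score over all complete cases, corrects
#' the E p-values with Benjamini-Hochberg FDR, and writes the signed
#' significance (+1 positive, -1 negative, 0 otherwise) into matrix form.
#'
#' @param edge_table N x E matrix (columns in [edge_index()] order).
#' @param scores Length-N scores (`NA` allowed).
#' @param alpha FDR-corrected threshold (default 0.05).
#' @param n_regions Region count R; inferred from E when `NULL`.
#' @return Object of class `wmcov_pattern`: `pattern` (R x R of -1/0/+1),
#'   `r`, `p_fdr` (R x R), `edge_table` data.frame.
#' @export
predictive_pattern <- function(edge_table, scores, alpha = 0.05,
                               n_regions = NULL) {
  stopifnot(is.matrix(edge_table), length(scores) == nrow(edge_table))
  ok <- !is.na(scores)
  X <- edge_table[ok, , drop = FALSE]; y <- scores[ok]
  if (length(y) < 30L)
    stop_wmcov("only %d complete cases; need at least 30", length(y))
  E <- ncol(X)
  if (is.null(n_regions)) {
    R <- (1 + sqrt(1 + 8 * E)) / 2
    if (R != round(R))
      stop_wmcov("%d edges is not R(R-1)/2 for integer R; pass n_regions", E)
    R <- as.integer(R)
  } else R <- as.integer(n_regions)
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, E); p <- rep(1, E)
  nz <- sds > 0
  if (any(nz)) {
    r[nz] <- as.vector(stats::cor(X[, nz, drop = FALSE], y))
    df <- length(y) - 2L
    tstat <- abs(r[nz]) * sqrt(df / pmax(1 - r[nz]^2, .Machine$double.eps))
    p[nz] <- 2 * stats::pt(tstat, df = df, lower.tail = FALSE)
  }
  p_fdr <- stats::p.adjust(p, method = "BH")
  sig <- as.integer(p_fdr < alpha) * sign(r)
  structure(list(pattern = devectorize_edges(sig, R),
                 r = devectorize_edges(r, R),
                 p_fdr = devectorize_edges(p_fdr, R) +
                   diag(R),  # diagonal p = 1, not 0
                 edge_table = data.frame(edge_index(R), r = r, p_raw = p,
                                         p_fdr = p_fdr, sign = sig),
                 alpha = alpha, n_subjects_used = length(y)),
            class = "wmcov_pattern")
}

#' @export
print.wmcov_performance <- function(x, ...) {
  cat(sprintf("prediction performance over %d repeat(s), N = %d:\n",
              nrow(x$per_repeat), x$n_subjects_used))
  cat(sprintf("  r   = %.3f +/- %.3f   (permutation p = %.4g)\n",
              x$r_mean, x$r_sd, x$permutation_p))
  cat(sprintf("  MAE = %.3f +/- %.3f\n", x$mae_mean, x$mae_sd))
  invisible(x)
}

#' @export
print.wmcov_pattern <- function(x, ...) {
  cat(sprintf("predictive pattern: %d significant edge(s) of %d (FDR alpha=%g)\n",
              sum(x$edge_table$sign != 0), nrow(x$edge_table), x$alpha))
  invisible(x)
}
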