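# Weighted network construction and node-strength analysis.

#' Threshold a connectivity matrix to a weighted positive network
#'
#' Keeps an edge iff its correlation is positive AND significant under a
#' two-sided t-test with df = C - 2, where C is the number of wavelet
#' channels each edge correlation was computed over. Everything else
#' (including the diagonal) is zeroed.
#'
#' @param cm `wmcov_connectivity` with `metric = "wavelet_pearson"`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `wmcov_network`: `weights`, `retained_mask`,
#'   `alpha`, `df`, `p_values`.
#' @export
threshold_positive <- function(cm, alpha = 0.05) {
  stopifnot(inherits(cm, "wmcov_connectivity"))
  if (!identical(cm$metric, "wavelet_pearson"))
    stop_wmcov("positive-significant thresholding is defined for wavelet_pearson matrices")
  C <- cm$n_samples_per_entry
  if (is.null(C) || C < 4L)
    stop_wmcov("n_samples_per_entry missing or < 4; cannot form edge p-values")
  r <- cm$values
  df <- C - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  keep <- (r > 0) & (p < alpha)
  diag(keep) <- FALSE
  w <- ifelse(keep, r, 0)
  structure(list(weights = w, retained_mask = keep, alpha = alpha, df = df,
                 p_values = p),
            class = "wmcov_network")
}

#' Node strength
#'
#' Strength of region r = sum of retained edge weights incident to r
#' (row sums of the thresholded weight matrix).
#'
#' @param net A `wmcov_network` from [threshold_positive()].
#' @return Named numeric vector of length R.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "wmcov_network"))
  rowSums(net$weights)
}

#' Correlate node strengths with a cognitive score across subjects
#'
#' Pearson correlation per region between the column of the N x R subject
#' strength table and the score, complete cases only, with Benjamini-
#' Hochberg FDR correction across the R regions.
#'
#' @param strengths N x R matrix (subjects x regions).
#' @param scores Length-N numeric, `NA` allowed (complete-case analysis).
#' @param alpha Significance level on the FDR-corrected p (default 0.05).
#' @return data.frame: region, r, p_raw, p_fdr, significant.
#' @export
strength_score_correlation <- function(strengths, scores, alpha = 0.05) {
  stopifnot(is.matrix(strengths), length(scores) == nrow(strengths))
  ok <- !is.na(scores)
  if (sum(ok) < 10L)
    stop_wmcov("only %d complete cases; need at least 10", sum(ok))
  S <- strengths[ok, , drop = FALSE]
  y <- scores[ok]
  res <- t(vapply(seq_len(ncol(S)), function(r) {
    ct <- stats::cor.test(S[, r], y)
    c(ct$estimate, ct$p.value)
  }, numeric(2)))
  p_fdr <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(region = colnames(strengths) %||% seq_len(ncol(S)),
             r = res[, 1], p_raw = res[, 2], p_fdr = p_fdr,
             significant = p_fdr < alpha, row.names = NULL)
}

#' Cohen's d between two performance samples
#'
#' Standardized mean difference `(mean_a - mean_b) / pooled_sd`, used to
#' compare per-repeat cross-validation accuracy distributions of two models.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop_wmcov("both samples need >= 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) {
    if (mean(a) == mean(b)) return(0)
    stop_wmcov("zero pooled sd with unequal means; d undefined")
  }
  (mean(a) - mean(b)) / sp
}

#' @export
print.wmcov_network <- function(x, ...) {
  cat(sprintf("weighted network: %d regions, %d retained edges (alpha=%g, df=%d)\n",
              nrow(x$weights), sum(x$retained_mask) / 2, x$alpha, x$df))
  invisible(x)
}
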