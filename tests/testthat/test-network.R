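conn <- function(vals, C = 22L) {
  vals <- (vals + t(vals)) / 2; diag(vals) <- 1
  structure(list(values = vals, metric = "wavelet_pearson",
                 n_samples_per_entry = as.integer(C)),
            class = "wmcov_connectivity")
}

test_that("positive-significant thresholding matches a p-value oracle", {
  # all strong positive -> all retained; all negative -> none
  hi <- conn(matrix(0.99, 4, 4))
  expect_equal(sum(threshold_positive(hi)$retained_mask), 12)
  lo <- conn(matrix(-0.99, 4, 4))
  expect_equal(sum(threshold_positive(lo)$retained_mask), 0)

  # r = 0.30 removed, r = 0.50 retained at C = 22; oracle = cor.test on
  # vectors constructed to have exactly that sample correlation
  r_oracle_p <- function(r, C) {
    x <- scale(seq_len(C))[, 1]
    resid <- scale(residuals(lm(rnorm(C) ~ x)))[, 1]
    y <- r * x + sqrt(1 - r^2) * resid
    stopifnot(abs(cor(x, y) - r) < 1e-12)
    cor.test(x, y)$p.value
  }
  set.seed(61)
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.30; m[1, 3] <- m[3, 1] <- 0.50
  net <- threshold_positive(conn(m, 22))
  expect_false(net$retained_mask[1, 2])
  expect_true(net$retained_mask[1, 3])
  expect_equal(net$p_values[1, 2], r_oracle_p(0.30, 22), tolerance = 1e-9)
  expect_equal(net$p_values[1, 3], r_oracle_p(0.50, 22), tolerance = 1e-9)

  # metadata guards
  bare <- conn(m); bare$n_samples_per_entry <- NULL
  expect_error(threshold_positive(bare), "n_samples_per_entry")
  klm <- conn(m); klm$metric <- "kl_similarity"
  expect_error(threshold_positive(klm), "wavelet_pearson")
})

test_that("thresholding is monotone in alpha", {
  set.seed(62)
  for (rep in 1:5) {
    m <- matrix(runif(100, -1, 1), 10, 10)
    cm <- conn(m)
    alphas <- sort(runif(4, 0.001, 0.5))
    masks <- lapply(alphas, function(a) threshold_positive(cm, a)$retained_mask)
    for (k in 1:3)
      expect_true(all(masks[[k]] <= masks[[k + 1]]))
  }
})

test_that("node strength: trivial cases and the double-loop oracle", {
  empty <- threshold_positive(conn(matrix(-0.5, 3, 3)))
  expect_equal(unname(node_strength(empty)), c(0, 0, 0))

  tri <- threshold_positive(conn(matrix(0.5, 3, 3), C = 200))
  expect_equal(unname(node_strength(tri)), c(1, 1, 1))

  set.seed(63)
  cm <- conn(matrix(runif(144, -1, 1), 12, 12))
  net <- threshold_positive(cm)
  s <- node_strength(net)
  for (r in 1:12) {
    acc <- 0
    for (j in 1:12) acc <- acc + net$weights[r, j]
    expect_equal(unname(s[r]), acc)
  }

  # additivity under edge-disjoint union
  w1 <- net$weights; w2 <- matrix(0, 12, 12)
  w2[1, 12] <- w2[12, 1] <- 0.4      # edge absent from w1? force disjoint
  w2[w1 != 0] <- 0
  net1 <- net; net12 <- net
  net12$weights <- w1 + w2
  expect_equal(node_strength(net12), node_strength(net1) + rowSums(w2))
})

test_that("strength-score correlation: identity, FDR calibration, R = 1", {
  set.seed(64)
  S <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, sprintf("region%02d", 1:5)))
  res <- strength_score_correlation(S, S[, 3])
  expect_equal(res$r[3], 1, tolerance = 1e-12)
  expect_true(res$significant[3])
  expect_equal(which.min(res$p_fdr), 3L)
  # corrected p matches the independent BH oracle
  expect_equal(res$p_fdr, oracle_bh(res$p_raw), tolerance = 1e-12)

  # null calibration: mean count of FDR-significant regions stays near
  # alpha-level false discovery behaviour
  counts <- replicate(100, {
    S0 <- matrix(rnorm(100 * 12), 100, 12)
    sum(strength_score_correlation(S0, rnorm(100))$significant)
  })
  expect_lte(mean(counts), 0.05 * 12 * 1.5)

  # single region: BH leaves p unchanged
  S1 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "region01"))
  y <- rnorm(30)
  r1 <- strength_score_correlation(S1, y)
  expect_equal(r1$p_raw, r1$p_fdr)

  expect_error(strength_score_correlation(S[1:8, ], rnorm(8)), "complete cases")
  # missing scores are dropped per task
  y2 <- S[, 1]; y2[1:5] <- NA
  expect_equal(strength_score_correlation(S, y2)$r[1], 1, tolerance = 1e-12)
})

test_that("BH correction is monotone: raising a raw p never lowers any corrected p", {
  set.seed(65)
  for (rep in 1:20) {
    p <- runif(12)
    i <- sample(12, 1)
    p2 <- p; p2[i] <- min(1, p[i] + runif(1, 0, 1 - p[i]))
    expect_true(all(oracle_bh(p2) >= oracle_bh(p) - 1e-12))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("Cohen's d: hand cases and antisymmetry", {
  expect_equal(cohens_d(c(0.5, 0.6, 0.7), c(0.2, 0.3, 0.4)), 3)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- a + sqrt(mean(c(var(a), var(a))))   # shift by one pooled sd
  expect_equal(cohens_d(b, a), 1)
  set.seed(66)
  x <- rnorm(20); y <- rnorm(15, 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(c(1, 1), c(2, 2)), "zero pooled sd")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})
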