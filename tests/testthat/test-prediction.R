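test_that("select_features: trivial contracts and null type-I rate", {
  set.seed(71)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- X[, 4]
  expect_true(4 %in% select_features(X, y))
  expect_setequal(select_features(X, rnorm(50), alpha = 1 - 1e-12), 1:10)
  Xc <- X; Xc[, 2] <- 5
  expect_warning(sel <- select_features(Xc, y), "constant")
  expect_false(2 %in% sel)
  expect_error(select_features(X[1:5, ], y[1:5]), "at least 10")

  rates <- replicate(200, {
    Xn <- matrix(rnorm(100 * 66), 100, 66)
    length(select_features(Xn, rnorm(100))) / 66
  })
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("fit_predict_svr: degenerate, linear-signal, duplicated features", {
  set.seed(72)
  X <- matrix(rnorm(40), 40, 1)
  expect_equal(fit_predict_svr(X, rep(3, 40), X[1:5, , drop = FALSE]),
               rep(3, 5))
  # empty selection fallback: training mean
  y <- rnorm(40)
  expect_equal(fit_predict_svr(X[, 0, drop = FALSE], y,
                               X[1:7, 0, drop = FALSE]),
               rep(mean(y), 7))

  n <- 200
  x <- matrix(rnorm(n), n, 1)
  tr <- 1:150; te <- 151:200
  pred <- fit_predict_svr(x[tr, , drop = FALSE], x[tr, 1],
                          x[te, , drop = FALSE])
  expect_gt(cor(pred, x[te, 1]), 0.95)

  # duplicating a column halves gamma but doubles squared distances:
  # the kernel, and hence the predictions, are unchanged
  X1 <- matrix(rnorm(60), 60, 1)
  y1 <- sin(X1[, 1]) + 0.1 * rnorm(60)
  X2 <- cbind(X1, X1)
  p1 <- fit_predict_svr(X1[1:40, , drop = FALSE], y1[1:40],
                        X1[41:60, , drop = FALSE])
  p2 <- fit_predict_svr(X2[1:40, ], y1[1:40], X2[41:60, ])
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("permutation p-value: identity, symmetry, null uniformity", {
  set.seed(73)
  y <- rnorm(50)
  expect_equal(permutation_pvalue(y, y, 999, seed = 1), 1 / 1000)
  pred <- rnorm(50)
  expect_equal(permutation_pvalue(y, pred, 200, seed = 5),
               permutation_pvalue(y, -pred, 200, seed = 5))
  expect_error(permutation_pvalue(rep(1, 20), rnorm(20)), "constant")

  ps <- replicate(500, permutation_pvalue(rnorm(30), rnorm(30), 99,
                                          seed = sample.int(1e6, 1)))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})

test_that("repeated_cv: determinism, leakage immunity, convergence", {
  set.seed(74)
  n <- 60; E <- 20
  X <- matrix(rnorm(n * E), n, E)
  y <- X[, 3] + 0.5 * rnorm(n)
  cfg <- prediction_config(n_repeats = 5, n_permutations = 99, seed = 42)
  p1 <- repeated_cv(X, y, cfg)
  p2 <- repeated_cv(X, y, cfg)
  expect_identical(p1$per_repeat, p2$per_repeat)
  expect_identical(p1$permutation_p, p2$permutation_p)

  # corrupting held-out scores must not change held-out predictions
  fold1 <- p1$first_repeat$fold == 1
  y_bad <- y; y_bad[fold1] <- y[fold1] + 100
  p_bad <- repeated_cv(X, y_bad, cfg)
  expect_equal(p_bad$first_repeat$pred[fold1], p1$first_repeat$pred[fold1],
               tolerance = 1e-10)

  # r_mean stabilizes as repeats grow (independent seed blocks)
  r_small <- vapply(1:4, function(s)
    repeated_cv(X, y, prediction_config(n_repeats = 2, n_permutations = 19,
                                        seed = s))$r_mean, 1)
  r_large <- vapply(1:4, function(s)
    repeated_cv(X, y, prediction_config(n_repeats = 10, n_permutations = 19,
                                        seed = 100 + s))$r_mean, 1)
  expect_lt(sd(r_large), sd(r_small) + 0.05)

  expect_error(repeated_cv(X[1:20, ], y[1:20], cfg), "at least 30")
})

test_that("split-half transfer: tie rule and phantom controls", {
  set.seed(75)
  # tie rule: a subject exactly at the mean age joins the younger group
  n <- 45
  ages <- c(rep(20, 22), 30, rep(40, 22))   # mean exactly 30
  X <- matrix(rnorm(n * 8), n, 8)
  y <- X[, 1] + 0.3 * rnorm(n)
  cfg <- prediction_config(n_repeats = 1, n_permutations = 99, seed = 3)
  tr <- split_half_transfer(X, y, ages, cfg)
  expect_equal(tr$young_to_old$n_train, 23)  # 22 young + the tied subject
  expect_equal(tr$young_to_old$n_test, 22)

  # shared signal in both halves transfers in both directions
  n2 <- 80
  X2 <- matrix(rnorm(n2 * 10), n2, 10)
  y2 <- X2[, 5] + 0.3 * rnorm(n2)
  ages2 <- c(runif(40, 20, 40), runif(40, 60, 80))
  tr2 <- split_half_transfer(X2, y2, ages2, cfg)
  expect_gt(tr2$young_to_old$r, 0)
  expect_gt(tr2$old_to_young$r, 0)

  # signal only in the training half: no transfer
  y3 <- c(X2[1:40, 5] + 0.1 * rnorm(40), rnorm(40))
  tr3 <- split_half_transfer(X2, y3, ages2, cfg)
  expect_lt(abs(tr3$young_to_old$r), 0.45)
  expect_gt(tr3$young_to_old$permutation_p, 0.01)

  expect_error(split_half_transfer(X2[1:20, ], y2[1:20], ages2[1:20], cfg),
               ">= 15")
})

test_that("predictive_pattern: exact edge, FDR calibration, sign", {
  set.seed(76)
  n <- 60; R <- 8; E <- R * (R - 1) / 2
  X <- matrix(rnorm(n * E), n, E)
  pat <- predictive_pattern(X, X[, 10])
  ij <- edge_index(R)[10, ]
  expect_equal(pat$pattern[ij[1], ij[2]], 1)
  expect_equal(which.min(pat$edge_table$p_fdr), 10L)
  expect_equal(pat$pattern, t(pat$pattern))
  expect_equal(diag(pat$pattern), rep(0, R))
  pat_neg <- predictive_pattern(X, -X[, 10])
  expect_equal(pat_neg$pattern[ij[1], ij[2]], -1)

  counts <- replicate(100, {
    Xn <- matrix(rnorm(40 * E), 40, E)
    sum(predictive_pattern(Xn, rnorm(40))$edge_table$sign != 0)
  })
  expect_lte(mean(counts), 0.05 * E * 1.5)
})

test_that("prediction config validates its invariants", {
  expect_error(prediction_config(k_folds = 1))
  expect_error(prediction_config(selection_alpha = 0))
  expect_error(prediction_config(n_repeats = 0))
  cfg <- prediction_config()
  expect_equal(cfg$k_folds, 10L)
  expect_equal(cfg$svr$cost, 1)
  expect_equal(cfg$svr$epsilon, 0.1)
})
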