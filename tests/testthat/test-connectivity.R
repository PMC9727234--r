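make_fv <- function(data, labels = NULL) {
  C <- dim(data)[4]
  structure(list(data = data,
                 channel_labels = labels %||% sprintf("ch%02d", seq_len(C)),
                 basis = "sym4", levels = 3L, boundary_mode = "symmetric"),
            class = "wmcov_feature_volume")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("regional means match the voxel-loop oracle", {
  set.seed(21)
  shp <- c(16, 16, 16)
  fvd <- array(rnorm(prod(shp) * 8), c(shp, 8))
  atlas <- block_atlas(shp, c(3L, 1L, 1L))
  rf <- regional_features(make_fv(fvd), atlas)
  for (r in 1:3) for (ch in 1:8) {
    acc <- 0; n <- 0
    for (x in 1:16) for (y in 1:16) for (z in 1:16)
      if (atlas$labels[x, y, z] == r) { acc <- acc + fvd[x, y, z, ch]; n <- n + 1 }
    expect_equal(unname(rf$values[r, ch]), acc / n, tolerance = 1e-12)
  }
})

test_that("regional features: trivial contracts and error paths", {
  shp <- c(8, 8, 8)
  atlas <- block_atlas(shp, c(2L, 1L, 1L))
  ones <- make_fv(array(1, c(shp, 5)))
  expect_true(all(regional_features(ones, atlas)$values == 1))

  labvals <- array(rep(as.numeric(atlas$labels), 4), c(shp, 4))
  rf <- regional_features(make_fv(labvals), atlas)
  expect_equal(unname(rf$values), cbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2)))

  expect_error(regional_features(make_fv(array(0, c(9, 8, 8, 2))), atlas),
               "does not match")
  mask <- array(TRUE, shp); mask[atlas$labels == 2] <- FALSE
  expect_error(regional_features(ones, atlas, mask), "no voxels")
})

test_that("wavelet-Pearson connectivity: closed-form and contracts", {
  rf <- structure(list(values = rbind(c(1, 2, 3, 4), c(1, 3, 2, 5),
                                      c(4, 3, 2, 1)),
                       region_ids = 1:3, channel_labels = letters[1:4]),
                  class = "wmcov_regional_features")
  cm <- wavelet_pearson_connectivity(rf)
  # hand computation: centered cross-product 5.5, variances 5 and 8.75
  expect_equal(cm$values[1, 2], 5.5 / sqrt(5 * 8.75))
  expect_equal(cm$values[1, 3], -1)           # reversed row
  expect_equal(diag(cm$values), rep(1, 3))
  expect_equal(cm$values, t(cm$values))
  expect_identical(cm$n_samples_per_entry, 4L)

  rf$values[2, ] <- 7
  expect_error(wavelet_pearson_connectivity(rf), "constant feature vector")
})

test_that("Pearson connectivity is relabel-equivariant and affine-invariant", {
  set.seed(31)
  base <- matrix(rnorm(6 * 22), 6, 22)
  rf <- structure(list(values = base, region_ids = 1:6,
                       channel_labels = sprintf("c%d", 1:22)),
                  class = "wmcov_regional_features")
  cm <- wavelet_pearson_connectivity(rf)$values
  for (k in 1:5) {
    p <- sample(6)
    rfp <- rf; rfp$values <- base[p, ]
    expect_equal(wavelet_pearson_connectivity(rfp)$values, cm[p, p],
                 ignore_attr = TRUE)
  }
  rfa <- rf; rfa$values[3, ] <- 2.5 * base[3, ] + 7   # per-region affine map
  expect_equal(wavelet_pearson_connectivity(rfa)$values, cm,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("KL similarity: identity, matching and separated distributions", {
  set.seed(41)
  shp <- c(28, 28, 28)
  atlas <- block_atlas(shp, c(2L, 1L, 1L))
  n_half <- sum(atlas$labels == 1)
  # identical distributions in both regions
  vol <- array(0, shp)
  vol[atlas$labels == 1] <- rnorm(n_half)
  vol[atlas$labels == 2] <- rnorm(sum(atlas$labels == 2))
  cm <- kl_similarity_connectivity(vol, atlas)
  expect_equal(unname(diag(cm$values)), rep(1, 2))  # exp(0) exactly
  expect_gt(cm$values[1, 2], 0.9)
  expect_equal(cm$values, t(cm$values))

  # N(0,1) vs N(2,1): closed form D_sym = (mu1-mu2)^2 = 4 nats; the
  # distributions overlap, so the KDE tails are accurate where they matter
  vol2 <- array(0, shp)
  vol2[atlas$labels == 1] <- rnorm(n_half, 0, 1)
  vol2[atlas$labels == 2] <- rnorm(sum(atlas$labels == 2), 2, 1)
  cm2 <- kl_similarity_connectivity(vol2, atlas)
  dsym <- -log(cm2$values[1, 2])
  expect_lt(abs(dsym - 4) / 4, 0.25)

  # N(0,1) vs N(5,1): essentially disjoint supports; the floored discrete
  # divergence saturates above the closed form 25, and the similarity is
  # driven to (numerically) zero -- the operative ordering contract
  vol3 <- array(0, shp)
  vol3[atlas$labels == 1] <- rnorm(n_half, 0, 1)
  vol3[atlas$labels == 2] <- rnorm(sum(atlas$labels == 2), 5, 1)
  cm3 <- kl_similarity_connectivity(vol3, atlas)
  expect_lt(cm3$values[1, 2], 0.01)
  expect_gt(-log(cm3$values[1, 2]), 25 * 0.75)

  tiny <- as_atlas(array(c(rep(1L, 5), rep(2L, 500), rep(0L, 3 * 512 - 505)),
                         c(8, 8, 24)))
  expect_error(kl_similarity_connectivity(rand_volume(c(8, 8, 24), 1), tiny),
               "fewer than 10")
})

test_that("edge vectorization: counts, order, round trip, validation", {
  expect_equal(nrow(edge_index(12)), 66)    # 12 regions -> 66 edges
  expect_equal(nrow(edge_index(17)), 136)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  ev <- vectorize_edges(m)
  expect_equal(ev$values, c(0.1, 0.2, 0.3))  # row-major upper triangle
  expect_equal(devectorize_edges(ev), m)

  set.seed(51)
  s <- matrix(rnorm(64), 8, 8); s <- s + t(s); diag(s) <- 0
  expect_equal(devectorize_edges(vectorize_edges(s)), s)

  bad <- m; bad[1, 2] <- 0.5
  expect_error(vectorize_edges(bad), "asymmetric")
})
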