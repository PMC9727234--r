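# Regional wavelet features and interregional connectivity.
#
# A subject's fingerprint is the R x C matrix of per-region mean wavelet
# features; connectivity is the Pearson correlation of the region rows over
# the C channels (the structural covariance edge), or, as a baseline, a
# symmetrized KL-divergence similarity of raw-intensity distributions.

.check_atlas <- function(atlas) {
  labs <- atlas$labels
  stopifnot(is.array(labs), length(dim(labs)) == 3)
  u <- sort(unique(as.vector(labs)))
  u <- u[u != 0]
  R <- length(u)
  if (R < 1L || !identical(as.integer(u), seq_len(R)))
    stop_wmcov("atlas labels must be consecutive integers 1..R (found: %s)",
               paste(utils::head(u, 8), collapse = ","))
  R
}

#' Build an atlas object
#'
#' @param labels 3D integer array, 0 = background, 1..R = regions.
#' @param region_names Optional character vector of length R.
#' @return Object of class `wmcov_atlas`.
#' @export
as_atlas <- function(labels, region_names = NULL) {
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  atlas <- structure(list(labels = labels, region_names = region_names),
                     class = "wmcov_atlas")
  R <- .check_atlas(atlas)
  atlas$n_regions <- R
  if (is.null(region_names))
    atlas$region_names <- sprintf("region%02d", seq_len(R))
  else stopifnot(length(region_names) == R)
  atlas
}

#' @export
print.wmcov_atlas <- function(x, ...) {
  cat(sprintf("atlas: %s grid, %d regions, %d labeled voxels\n",
              paste(dim(x$labels), collapse = "x"), x$n_regions,
              sum(x$labels != 0)))
  invisible(x)
}

#' Regional mean wavelet features
#'
#' Averages each feature channel over every atlas region, producing the
#' R x C regional feature matrix (one wavelet fingerprint row per region).
#' Features are computed on the full grid first; the atlas (and optional
#' mask) only select which voxels enter the mean.
#'
#' @param fv A `wmcov_feature_volume` from [build_feature_volume()].
#' @param atlas A `wmcov_atlas` on the same voxel grid.
#' @param mask Optional logical/0-1 array on the same grid.
#' @return Object of class `wmcov_regional_features`: `values` (R x C),
#'   `region_ids`, `channel_labels`.
#' @export
regional_features <- function(fv, atlas, mask = NULL) {
  stopifnot(inherits(fv, "wmcov_feature_volume"), inherits(atlas, "wmcov_atlas"))
  d <- dim(fv$data)
  if (!identical(d[1:3], dim(atlas$labels)))
    stop_wmcov("feature volume grid %s does not match atlas grid %s",
               paste(d[1:3], collapse = "x"),
               paste(dim(atlas$labels), collapse = "x"))
  R <- atlas$n_regions
  lab <- as.vector(atlas$labels)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:3]))
      stop_wmcov("mask grid does not match the atlas grid")
    lab[!as.logical(mask)] <- 0L
  }
  keep <- lab != 0L
  counts <- tabulate(lab[keep], nbins = R)
  if (any(counts == 0L))
    stop_wmcov("region(s) %s have no voxels after masking",
               paste(which(counts == 0L), collapse = ","))
  C <- d[4]
  flat <- matrix(fv$data, nrow = prod(d[1:3]), ncol = C)
  sums <- rowsum(flat[keep, , drop = FALSE], group = lab[keep], reorder = TRUE)
  values <- sums / counts
  dimnames(values) <- list(atlas$region_names, fv$channel_labels)
  structure(list(values = values, region_ids = seq_len(R),
                 channel_labels = fv$channel_labels, n_voxels = counts),
            class = "wmcov_regional_features")
}

.new_connectivity <- function(values, metric, n_samples, region_names = NULL) {
  dimnames(values) <- list(region_names, region_names)
  structure(list(values = values, metric = metric,
                 n_samples_per_entry = n_samples),
            class = "wmcov_connectivity")
}

#' Wavelet-Pearson structural covariance connectivity
#'
#' The subject-level connectivity matrix: entry (i, j) is the Pearson
#' correlation of region i's and region j's mean wavelet feature vectors
#' over the C channels. The channel count is stored so downstream edge
#' significance tests can use df = C - 2.
#'
#' @param rf A `wmcov_regional_features` object.
#' @return `wmcov_connectivity` with `metric = "wavelet_pearson"`.
#' @export
wavelet_pearson_connectivity <- function(rf) {
  stopifnot(inherits(rf, "wmcov_regional_features"))
  X <- rf$values
  if (ncol(X) < 3L) stop_wmcov("need at least 3 feature channels")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop_wmcov("region(s) %s have a constant feature vector; correlation undefined",
               paste(which(sds == 0), collapse = ","))
  vals <- stats::cor(t(X))
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  .new_connectivity(vals, "wavelet_pearson", ncol(X), rownames(X))
}

#' KL-divergence similarity connectivity (baseline)
#'
#' Classical morphological-similarity baseline: each region's raw voxel
#' intensity distribution is estimated with a Gaussian KDE on a shared grid
#' spanning the pooled intensity range; edges are
#' `exp(-[KL(Pi||Pj) + KL(Pj||Pi)])`, so identical distributions give 1 and
#' dissimilar ones approach 0.
#'
#' @param volume Raw 3D intensity volume (not wavelet features).
#' @param atlas A `wmcov_atlas` on the same grid.
#' @param mask Optional mask.
#' @param n_grid Number of shared density evaluation points (default 128).
#' @param bandwidth_rule `"silverman"` (default, `stats::bw.nrd0`) or `"sj"`.
#' @param floor Density floor applied before renormalization (default 1e-12).
#' @return `wmcov_connectivity` with `metric = "kl_similarity"`.
#' @export
kl_similarity_connectivity <- function(volume, atlas, mask = NULL,
                                       n_grid = 128L,
                                       bandwidth_rule = c("silverman", "sj"),
                                       floor = 1e-12) {
  stopifnot(inherits(atlas, "wmcov_atlas"))
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (!identical(dim(volume), dim(atlas$labels)))
    stop_wmcov("volume grid does not match the atlas grid")
  lab <- as.vector(atlas$labels)
  if (!is.null(mask)) lab[!as.logical(mask)] <- 0L
  R <- atlas$n_regions
  v <- as.vector(volume)
  samples <- split(v[lab != 0L], lab[lab != 0L])
  if (length(samples) != R)
    stop_wmcov("region(s) emptied by the mask")
  nvox <- vapply(samples, length, 1L)
  if (any(nvox < 10L))
    stop_wmcov("region(s) %s have fewer than 10 voxels",
               paste(which(nvox < 10L), collapse = ","))
  if (any(vapply(samples, stats::sd, 1) == 0))
    stop_wmcov("region(s) with zero intensity variance; density degenerate")
  rng <- range(unlist(samples))
  dens <- vapply(samples, function(s) {
    bw <- if (bandwidth_rule == "silverman") stats::bw.nrd0(s) else stats::bw.SJ(s)
    d <- stats::density(s, bw = bw, from = rng[1], to = rng[2], n = n_grid)$y
    d <- pmax(d, floor)
    d / sum(d)
  }, numeric(n_grid))
  vals <- matrix(1, R, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    dsym <- sum(dens[, i] * log(dens[, i] / dens[, j])) +
            sum(dens[, j] * log(dens[, j] / dens[, i]))
    vals[i, j] <- vals[j, i] <- exp(-dsym)
  }
  .new_connectivity(vals, "kl_similarity", n_grid, atlas$region_names)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Row-major strict upper triangle: (1,2), (1,3), ..., (1,R), (2,3), ...
#' A 12-region atlas yields the 66 interregional features used as the
#' subject-level predictors; 17 regions yield 136.
#'
#' @param cm `wmcov_connectivity` or a plain symmetric matrix.
#' @param tol Maximum tolerated asymmetry (default 1e-9).
#' @return Object of class `wmcov_edge_vector`: `values` (length
#'   R(R-1)/2) and `edge_index` (two-column matrix of (i, j), i < j).
#' @export
vectorize_edges <- function(cm, tol = 1e-9) {
  m <- if (inherits(cm, "wmcov_connectivity")) cm$values else cm
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol)
    stop_wmcov("matrix is asymmetric beyond tolerance %g", tol)
  R <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major
  colnames(idx) <- c("i", "j")
  structure(list(values = m[cbind(idx[, 1], idx[, 2])],
                 edge_index = idx, n_regions = R),
            class = "wmcov_edge_vector")
}

#' Rebuild a symmetric hollow matrix from an edge vector
#'
#' Inverse of [vectorize_edges()] up to the (zeroed) diagonal.
#'
#' @param ev `wmcov_edge_vector`, or a numeric vector with `n_regions`.
#' @param n_regions Required when `ev` is a bare vector.
#' @return Symmetric R x R matrix with zero diagonal.
#' @export
devectorize_edges <- function(ev, n_regions = NULL) {
  if (inherits(ev, "wmcov_edge_vector")) {
    vals <- ev$values; R <- ev$n_regions; idx <- ev$edge_index
  } else {
    R <- n_regions %||% stop_wmcov("n_regions required for a bare vector")
    stopifnot(length(ev) == R * (R - 1) / 2)
    vals <- ev
    idx <- edge_index(R)
  }
  m <- matrix(0, R, R)
  m[cbind(idx[, 1], idx[, 2])] <- vals
  m + t(m)
}

#' Canonical edge index for R regions
#'
#' @param R Number of regions.
#' @return Two-column integer matrix of (i, j) pairs, i < j, row-major.
#' @export
edge_index <- function(R) {
  i <- rep(seq_len(R - 1), times = (R - 1):1)
  j <- unlist(lapply(seq_len(R - 1), function(a) (a + 1):R))
  cbind(i = i, j = j)
}

#' Edge labels ("i-j") for R regions
#' @param R Number of regions.
#' @return Character vector of length R(R-1)/2.
#' @export
edge_labels <- function(R) {
  idx <- edge_index(R)
  sprintf("e%02d_%02d", idx[, 1], idx[, 2])
}

#' @export
print.wmcov_connectivity <- function(x, ...) {
  cat(sprintf("%s connectivity: %d regions, n per entry = %d\n",
              x$metric, nrow(x$values), x$n_samples_per_entry))
  invisible(x)
}
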