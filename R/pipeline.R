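# End-to-end orchestration: phantom -> wavelet features -> connectivity ->
# network metrics / prediction, with a JSON run manifest.

#' Single-subject connectivity from a raw volume
#'
#' Runs the full feature chain for one subject: level-`levels` 3D DWT,
#' 4D feature volume assembly, regional mean features, then either the
#' wavelet-Pearson connectivity or the KL-similarity baseline.
#'
#' @param volume 3D array (preprocessed tissue-density map).
#' @param atlas A `wmcov_atlas` on the same grid.
#' @param basis,levels Wavelet basis and depth (defaults sym4, 3).
#' @param metric `"wavelet_pearson"` (default) or `"kl_similarity"`.
#' @param mask Optional mask.
#' @return A `wmcov_connectivity`.
#' @export
subject_connectivity <- function(volume, atlas, basis = "sym4", levels = 3L,
                                 metric = c("wavelet_pearson", "kl_similarity"),
                                 mask = NULL) {
  metric <- match.arg(metric)
  if (metric == "kl_similarity")
    return(kl_similarity_connectivity(volume, atlas, mask = mask))
  fv <- build_feature_volume(dwt3(volume, basis = basis, levels = levels))
  wavelet_pearson_connectivity(regional_features(fv, atlas, mask = mask))
}

#' Edge table for a whole cohort
#'
#' @param cohort A `wmcov_cohort` (or a plain list of 3D arrays plus an
#'   `atlas`).
#' @param atlas Atlas; defaults to the cohort's own.
#' @param basis,levels,metric Passed to [subject_connectivity()].
#' @return N x E matrix of subject edge vectors, columns in
#'   [edge_index()] order and named by [edge_labels()].
#' @export
cohort_edge_table <- function(cohort, atlas = NULL, basis = "sym4",
                              levels = 3L, metric = "wavelet_pearson") {
  volumes <- if (inherits(cohort, "wmcov_cohort")) cohort$volumes else cohort
  atlas <- atlas %||% cohort$atlas
  R <- atlas$n_regions
  E <- R * (R - 1) / 2
  out <- matrix(NA_real_, length(volumes), E,
                dimnames = list(NULL, edge_labels(R)))
  for (s in seq_along(volumes)) {
    cm <- subject_connectivity(volumes[[s]], atlas, basis, levels, metric)
    out[s, ] <- vectorize_edges(cm)$values
  }
  out
}

#' Node-strength table for a whole cohort
#'
#' @param edge_table N x E matrix from [cohort_edge_table()].
#' @param n_channels Wavelet channel count each edge was computed over
#'   (df = n_channels - 2 in the edge test); default 22.
#' @param alpha Edge significance level (default 0.05).
#' @return N x R matrix of node strengths.
#' @export
cohort_node_strengths <- function(edge_table, n_channels = 22L, alpha = 0.05) {
  E <- ncol(edge_table)
  R <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  out <- matrix(NA_real_, nrow(edge_table), R,
                dimnames = list(NULL, sprintf("region%02d", seq_len(R))))
  for (s in seq_len(nrow(edge_table))) {
    cm <- .new_connectivity(devectorize_edges(edge_table[s, ], R) + diag(R),
                            "wavelet_pearson", n_channels)
    out[s, ] <- node_strength(threshold_positive(cm, alpha))
  }
  out
}

#' Run the full phantom pipeline from a declarative config
#'
#' Stages: (1) phantom generation (atlas + volumes + scores), (2) per-
#' subject wavelet connectivity and edge vectors, (3) node strengths and
#' strength-score correlations, (4) repeated-CV prediction. All
#' intermediates are written under `out_dir` as NIfTI/CSV plus a JSON run
#' manifest; a completed stage (its outputs already present) is skipped on
#' rerun.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#'   Sections: `phantom` (grid, regions, subjects, edges as "i:j:rho"
#'   strings, noise, seed), `features` (basis, levels), `prediction`
#'   (folds, repeats, permutations, alpha).
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly; side effect: files + `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) jsonlite::read_json(config, simplifyVector = TRUE)
         else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- cfg$phantom
  if (is.null(ph)) stop_wmcov("config needs a 'phantom' section")
  feats <- cfg$features %||% list()
  basis <- feats$basis %||% "sym4"
  levels <- as.integer(feats$levels %||% 3L)
  prd <- cfg$prediction %||% list()
  seed <- as.integer(ph$seed %||% 1L)

  edges <- lapply(ph$edges %||% list(), parse_edge_spec)
  spec <- phantom_spec(grid_shape = ph$grid %||% c(32L, 32L, 32L),
                       n_regions = ph$regions %||% 12L,
                       n_subjects = ph$subjects %||% 50L,
                       coupled_edges = edges,
                       score_noise_sd = ph$noise %||% 1,
                       texture_smoothness = ph$smoothness %||% 1,
                       seed = seed)

  atlas_file <- file.path(out_dir, "atlas.nii.gz")
  scores_file <- file.path(out_dir, "scores.csv")
  edges_file <- file.path(out_dir, "edge_table.csv")
  strengths_file <- file.path(out_dir, "node_strengths.csv")
  strength_corr_file <- file.path(out_dir, "strength_correlations.csv")
  perf_file <- file.path(out_dir, "performance.csv")
  manifest_file <- file.path(out_dir, "manifest.json")

  # stage 1: phantom
  atlas <- generate_atlas(spec$grid_shape, spec$n_regions, seed)
  cohort <- NULL
  if (!file.exists(scores_file) || !file.exists(edges_file)) {
    if (!identical(dim(atlas$labels), spec$grid_shape))
      stop_wmcov("atlas grid mismatch")  # fail fast before heavy compute
    cohort <- generate_cohort(atlas, spec)
    write_nifti(atlas$labels, atlas_file, datatype = "int16")
    write.csv(cohort$subjects, scores_file, row.names = FALSE)
  }

  # stage 2: features + connectivity
  if (!file.exists(edges_file)) {
    et <- cohort_edge_table(cohort, basis = basis, levels = levels)
    write.csv(cbind(subject_id = cohort$subjects$subject_id,
                    as.data.frame(et)), edges_file, row.names = FALSE)
  }
  edf <- read.csv(edges_file, check.names = FALSE)
  et <- as.matrix(edf[, -1, drop = FALSE])
  subjects <- read.csv(scores_file)

  # stage 3: node strengths + strength-score correlations
  C <- 7L * levels + 1L
  if (!file.exists(strengths_file)) {
    st <- cohort_node_strengths(et, n_channels = C)
    write.csv(cbind(subject_id = subjects$subject_id, as.data.frame(st)),
              strengths_file, row.names = FALSE)
  }
  st <- as.matrix(read.csv(strengths_file, check.names = FALSE)[, -1])
  sc <- strength_score_correlation(st, subjects$score)
  write.csv(sc, strength_corr_file, row.names = FALSE)

  # stage 4: prediction
  config_pred <- prediction_config(
    k_folds = as.integer(prd$folds %||% 10L),
    n_repeats = as.integer(prd$repeats %||% 50L),
    selection_alpha = prd$alpha %||% 0.05,
    n_permutations = as.integer(prd$permutations %||% 1000L),
    seed = seed)
  perf <- repeated_cv(et, subjects$score, config_pred)
  write.csv(data.frame(task = "score", r_mean = perf$r_mean, r_sd = perf$r_sd,
                       p = perf$permutation_p, mae_mean = perf$mae_mean,
                       mae_sd = perf$mae_sd, n = perf$n_subjects_used),
            perf_file, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wmcov")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = seed,
    config = cfg,
    parameters = list(basis = basis, levels = levels,
                      edge_alpha = 0.05, svr = config_pred$svr,
                      k_folds = config_pred$k_folds,
                      n_repeats = config_pred$n_repeats,
                      n_permutations = config_pred$n_permutations,
                      selection_alpha = config_pred$selection_alpha),
    input_checksums = as.list(tools::md5sum(c(scores_file, edges_file))))
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# "3:7:0.6" -> c(3, 7, 0.6)
parse_edge_spec <- function(s) {
  if (is.numeric(s)) return(s)
  parts <- as.numeric(strsplit(s, ":")[[1]])
  if (length(parts) != 3 || anyNA(parts))
    stop_wmcov("bad edge spec '%s'; expected i:j:rho", s)
  parts
}
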