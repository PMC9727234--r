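---
title: "Single-subject white matter covariance connectivity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject white matter covariance connectivity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmcov)
```

## The metric

Classical voxel-based morphometry (VBM) gives each voxel a single scalar
(a modulated tissue density), which is not enough to define interregional
*similarity* for one subject. wmcov turns each voxel into a feature
*vector* with a level-3 separable 3D discrete wavelet transform: 7 detail
orientations per level plus the final approximation give
$C = 7L + 1 = 22$ channels at $L = 3$. Each channel is resampled back to
the native grid, each atlas region $r$ is summarized by the mean feature
vector $f_r \in \mathbb{R}^{22}$, and the subject-level connectivity
between regions $i$ and $j$ is the Pearson correlation
$\mathrm{corr}(f_i, f_j)$ over channels. For a 12-region white matter
atlas this yields a $12 \times 12$ matrix and $66$ upper-triangle edges
per subject; a 17-region gray matter atlas yields $136$.

Downstream, edges feed two analyses:

* **Node strength**: edges with $r > 0$ significant at $p < 0.05$
  (two-sided $t$, $\mathrm{df} = C - 2 = 20$ over channels) form a
  weighted network; a region's strength is the sum of its retained edge
  weights. Strengths are correlated with cognition across subjects,
  Benjamini–Hochberg corrected across regions.
* **Prediction**: per training fold, edges significantly correlated with
  the score ($p < 0.05$, $\mathrm{df} = n_\mathrm{train} - 2$) enter an
  epsilon-SVR; repeated 10-fold cross-validation summarizes accuracy as
  mean $\pm$ sd of the pooled out-of-fold correlation $r$ and MAE.

## Wavelet transform choices

* **Basis.** The reference decomposition is "near symmetric", the
  standard description of the least-asymmetric Daubechies (symlet)
  family. The order is not pinned anywhere, so the default is `sym4`
  (8 taps), configurable via `basis =` in `dwt3()`. All filter taps are
  the published orthonormal constants.
* **Boundary handling.** Half-point symmetric extension by
  filter-length − 1 samples, valid-part convolution, even-sample
  decimation — the classical MATLAB-style scheme. Coefficient lengths are
  $\lfloor (n + L_f - 1)/2 \rfloor$, slightly redundant, which is what
  buys exact reconstruction (`inverse_dwt3()`, max abs error below
  1e−8 in float64) on arbitrary non-dyadic grids.
* **4D assembly.** How differently sized subbands become one 4D grid is
  not stated in the source method. wmcov uses value-preserving
  nearest-neighbor block replication: a level-$\ell$ coefficient covers
  its $2^\ell$-voxel dyadic support per axis. Crucially, the map is
  *receptive-field aligned*: after $\ell$ cascaded decimations the
  coefficient $k$ summarizes input samples centered on
  $2^\ell k - (2^\ell - 1)(L_f - 1)/2$, and voxels are assigned to the
  nearest center. Ignoring this phase term misplaces level-3 subbands by
  up to $\sim 24$ voxels and silently decouples regional features from
  the anatomy under them. A trilinear mode (`interp = "linear"`) is
  offered behind a flag.
* Only the final-level approximation is kept (standard multilevel
  convention), hence $7L + 1$ channels, ordered approximation first,
  coarse to fine.

## KL-divergence baseline

The comparison metric estimates each region's raw-intensity density with
a Gaussian KDE (Silverman bandwidth) on a shared 128-point grid spanning
the pooled range, floors densities at 1e−12, renormalizes, and sets the
edge to $\exp[-(\mathrm{KL}(P_i\|P_j) + \mathrm{KL}(P_j\|P_i))]$.
Self-similarity is exactly 1.

**Known limitation.** The discrete floored divergence is accurate only
where the two samples overlap. For essentially disjoint distributions
(e.g. unit-variance Gaussians 5 sd apart, closed form
$D_\mathrm{sym} = 25$ nats) every cross-evaluation hits the floor and the
estimate saturates near $2\log(\bar{p}/10^{-12}) \approx 40$ nats — no
bounded-support KDE can track a 5-sigma tail. The tests therefore check
closed-form tracking at a resolvable separation (2 sd, 4 nats, within
25%) and only the similarity *ordering* (edge < 0.01) in the saturated
regime. On real tissue-density maps intensities share support, so the
floor rarely binds.

## Prediction protocol

* **SVR.** "Default parameters" are only reproducible by pinning them:
  radial-basis kernel, cost 1, epsilon 0.1, gamma = 1/(number of selected
  features), with features and target standardized by training-fold
  statistics and predictions mapped back — the canonical libsvm/e1071
  defaults. The solver is a small deterministic SMO (sequential minimal
  optimization) with first-order working-set selection; it matches
  scikit-learn's SVR predictions to ~1e−3 on shared fixtures at the same
  hyperparameters.
* **Empty selection.** If no edge survives selection in a fold, that fold
  predicts the training mean (the reference protocol is silent; this
  keeps every fold defined and is visible in `mean_n_selected`).
* **Per-repeat accuracy** is the correlation of the *pooled* out-of-fold
  predictions with the observed scores (the natural reading of a
  per-model $r \pm$ sd and MAE table), not per-fold averages.
* **Permutation significance.** `permutation_pvalue()` implements the
  classical two-sided label-shuffling test
  $p = (1 + \#\{|r_b| \ge |r_\mathrm{obs}|\})/(B + 1)$ for two *fixed*
  vectors. For cross-validated predictions that test is anticonservative:
  the predictions depend on the scores through the training folds, so the
  true null spread of $r$ exceeds the naive permutation null (measured on
  20 null phantom cohorts: 25% of cohorts "significant" at 0.05).
  `repeated_cv()` therefore re-runs the entire selection + SVR pipeline on
  every permuted score vector (holding the first repeat's fold partition
  fixed), which restores calibration (0/20 null cohorts significant). The
  naive test remains correct — and is used — for split-half transfer,
  where the model never sees the test scores.
* **Split-half transfer** splits at the mean age; a subject exactly at
  the mean joins the younger group (the boundary case is otherwise
  undefined). Training happens wholly in one group, testing once in the
  other, both directions.
* **Randomness.** One master seed; every fold partition and permutation
  stream uses a seed derived from (master, stream index), so any single
  repeat is reproducible in isolation and two runs with the same
  configuration are bitwise identical.
* Multiple cognitive tasks are modeled independently, complete-case per
  task.

## The synthetic phantom

No generative model for the real data exists, so the phantom's
statistical structure is the package's own design:

* **Volumes** are nonnegative "tissue density" maps: baseline 1 inside an
  ellipsoidal brain mask, plus Gaussian-blurred white-noise texture
  (`texture_smoothness` = 1 voxel, amplitude 0.05), clipped at 0.
* **Atlases** grow R compact parcels by nearest-seed assignment from
  random seed voxels inside the mask, redrawing (deterministically) until
  every parcel has ≥ 64 voxels.
* **Coupling.** Each coupled edge $(i, j, \rho)$ has a per-subject latent
  $z \sim N(0,1)$. Two fixed, *independent* detail-channel texture
  profiles (drawn once per edge, levels 3 and 2 only, zero-mean across
  active channels) are synthesized into the wavelet coefficients
  overlapping region $i$ and region $j$ (each coefficient weighted by its
  dyadic block's region coverage), masked to their own region in voxel
  space (boundary blocks would otherwise leak the same profile into
  adjacent regions and flip the coupling sign), normalized so the induced
  centered regional detail-feature shift has norm `inject_amp` = 2
  regardless of parcel size or shape, and added to the volume with the
  common weight $\Phi(-z)$. Regional feature vectors are dominated by the approximation
  channel, so extra orthogonal detail structure strictly *de*correlates a
  region from its neighbours (with relative detail loads $x, y$ the edge
  behaves like $\rho_0/\sqrt{(1+x^2)(1+y^2)}$). Attenuating that
  structure jointly in both regions as $z$ grows therefore makes the
  $(i,j)$ edge increase monotonically in $z$ — with a
  geometry-independent sign — while the score
  $\sum_e \rho_e z_e + \varepsilon$ is linear in $z$, so edge and score
  correlate with the sign of $\rho$. The pair edge moves quadratically
  more than the other edges incident to $i$ or $j$, which is what makes
  the implant recoverable as an *edge*, not just a node effect. Two
  literal alternatives fail structurally: a weight monotone in $|z|$
  decorrelates the edge from the $z$-linear score, and a single component
  literally shared by both regions acts through the ratio of the regions'
  approximation magnitudes, flipping the coupling's sign with atlas
  geometry (both were measured, not just argued; see the decisions
  ledger of the build).
* **Why wavelet-domain injection, not mean shifts:** an isolated mean
  shift moves one approximation entry of one region and barely moves a
  22-channel correlation; multi-channel detail structure lives exactly
  where the metric looks. Injection uses only coarse channels because a
  level-3 coefficient shifts the regional mean feature as much as a
  level-1 coefficient while adding $8^{\ell}$-fold less voxel variance,
  which keeps the zero-clipping nearly inactive and the generator
  effectively linear.
* **Amplitudes** (texture 0.05, injection 2) were fixed once from an
  8-seed pilot so that a coupled cohort shows an edge–score sample
  correlation near 0.85 (comfortably above the 0.4 contract) with a
  consistent sign across atlas seeds, and were not revisited afterwards.
* **What the phantom does not emulate:** scanner artifacts, registration
  error, anatomical covariance between *un*coupled regions, non-Gaussian
  score distributions, or missingness mechanisms. Edges incident to a
  coupled region co-vary with the score by construction (the region's
  whole fingerprint moves), so a green recovery test establishes that the
  implanted edge is detected and ranks above the background — not that
  background edges are silent.
* Ages are uniform on 20–89 and deliberately uncoupled from scores,
  mirroring the reference cohort's reported age-independence of
  cognition; sex is an unused covariate column.

## Numerical conventions

Float64 throughout; reconstruction tolerance 1e−8; connectivity symmetry
enforced to 1e−12 and edge vectorization validated at 1e−9; degenerate
inputs (constant feature rows, emptied regions, < 10-voxel regions for
KDE, constant scores) are hard, named errors rather than silent NaNs.
BH-FDR is applied across regions for strength analyses and across the
$E$ edges for pattern discovery. Edge significance uses
$\mathrm{df} = C - 2$ over wavelet channels; the channel count is carried
inside every connectivity object so the df is never guessed.

## What a green suite establishes

Unit tests pin each operation to independent oracles (direct-convolution
filter bank, voxel loops, closed-form Pearson/KL values, a hand-rolled
BH implementation); acceptance tests check the analytic edge-count law,
reconstruction, estimator tracking, null calibration of the full
protocol, and implanted-signal recovery on phantoms. None of this
certifies performance on real MRI — the reference cohort's headline
accuracies require the original 315-subject dataset, which is outside
the build.
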