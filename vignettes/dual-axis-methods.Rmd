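---
title: "Dual-axis network topology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-axis network topology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdax)
```

netdax quantifies two complementary, dissociable axes of individualized
functional brain-network topology in focal epilepsy: **system integrity** —
how faithfully a person's resting-state networks align with canonical
intrinsic-connectivity systems — and **system integration** — how strongly
individual voxels participate in multiple overlapping networks (connector-hub
topology). Both axes are derived from a single substrate: reliable,
spatially overlapping subject-level networks estimated by block-bootstrap
sparse dictionary decomposition. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
made where the methodology left them open.

## The substrate: overlapping subject-level networks

Each vertex's BOLD time series is modeled as a sparse linear combination of a
small number of temporal "atoms" (network timecourses): `X ≈ D C` with `X`
the T×V series, `D` a T×K unit-norm temporal dictionary, and `C` a K×V
coefficient matrix with at most `sparsity` (default 3) nonzero entries per
vertex. Because a vertex may load on several atoms, networks are explicitly
allowed to overlap in space — the property that makes voxel-wise
multi-network participation (k-hubness) well defined.

`sparse_decompose()` alternates batch orthogonal matching pursuit with an
atom-wise rank-1 dictionary update. Three numerical safeguards matter in
practice:

* **Entry/prune threshold** (`min_explained`, default 0.2). An atom enters a
  vertex's code only if it explains at least this fraction of the current
  residual sum of squares, and after coding, atoms whose *unique*
  contribution (partial R²) falls below the same fraction of the vertex's
  total energy are pruned. The entry rule keeps chance selections off
  noise-only vertices (at T = 150 frames the best of a few atoms explains a
  few percent of pure noise by chance); the backward prune stops a pure atom
  from compensating another atom's residual impurity, which would otherwise
  inflate supports and k.
* **Restarts with coherence selection** (`n_restarts`, default 6).
  Alternating minimization has local optima in which one atom absorbs a
  mixture of two sources. Such solutions are recognizable: the mixed atom is
  strongly correlated with the pure atom it overlaps. Each decomposition is
  restarted from several initializations — alternating plain k-means of the
  standardized vertex series with an over-clustered (2K-center) solution
  reduced by greedy max-min selection — and the dictionary with the lowest
  mutual coherence (maximum absolute inter-atom correlation) is kept, with
  reconstruction error as the tie-break.
* **Monotone error.** After each dictionary update a vertex's new code is
  kept only if it lowers its residual, so the recorded per-iteration
  reconstruction error never increases.

Reliability is assessed by temporal block bootstrap: the series is resampled
as contiguous blocks of 20–60 s (uniform lengths, last block truncated), a
scheme that preserves low-frequency structure and autocorrelation within
blocks; `B = 200` resamples at full scale, far fewer at toy scale. Each
resample is decomposed with a warm start: the original-data dictionary,
*resampled with the same frame indices* (atoms are temporal patterns, so
they must live in the resample's time basis). The bootstraps therefore probe
the stability of the original solution rather than re-exploring the whole
optimization landscape. Pooled bootstrap maps are sign-aligned,
correlation-normalized, and clustered by k-means into K consensus clusters;
the consensus loading is the cluster centroid, the consensus support keeps
vertices present in at least half the cluster members, and an atom's
reproducibility is the fraction of resamples contributing to its cluster
(clusters below `reproducibility_threshold = 0.5` are dropped).

The model order K is chosen on the original (non-bootstrapped) series by a
BIC-style penalized reconstruction error,
`T·V·log(MSE) + λ·K·(T + V_active)·log(T·V)` with `V_active` the mean
support size per atom and `λ = 1`. The methodology named no criterion; this
one is a deliberate, pluggable choice, and the criterion curve over all
candidates is always reported. At full scale the search runs 18–40 in steps
of two.

Atoms whose absolute loading mass lies mostly (> 50%) outside the
gray-matter mask are flagged as likely noise (`flag_noise_atoms()`); the
default analyses keep the full atom set and expose the flag as a switch,
mirroring the choice to report results on the unfiltered set.

## Axis 1 — system integrity (correspondence)

Given binary supports for the K individualized networks and the M networks
of a canonical atlas, the K×M Dice matrix `D(k,m) = 2|A_k∩B_m|/(|A_k|+|B_m|)`
is summarized three ways: **CNR** (canonical network representation), the
column-wise maximum — how strongly each canonical system is expressed;
**normativity**, the mean CNR; and **non-normativity**, one minus the
row-wise maximum averaged over the individual's networks — the share of
individual topology not explained by any canonical system. Individualized
atoms are binarized at the consensus support (|loading| > ε, ε = 1e-8,
shared with k-hubness); component-atlas supports are weight > 0; label-atlas
supports are label equality. Column-max ties break toward the lowest atom
index and the winning atom is recorded.

Significance of an (atom, canonical network) overlap uses spin permutations:
a uniform random 3D rotation is applied to the spherical vertex cloud and
atlas values are reassigned by a greedy one-to-one nearest-neighbor matching
(tightest matches first). Because the assignment is a permutation, every
spin is an exact relabeling — the multiset of atlas labels is preserved —
and p-values use the add-one formula, so `p ∈ [1/(n_perm+1), 1]`.
Subcortical correspondence is plain volumetric Dice against the 14 emulated
subcortical regions with no spin inference, since rotation nulls are not
meaningful off the sphere.

Cross-atlas consensus: each atlas's CNR vector is projected into the shared
parcel space — label atlases through the weight matrix
`W(m,p) = |network m ∩ parcel p| / |parcel p|` (so `p = cᵀW`; unlabeled
vertices deflate the weights), component atlases as the mean CNR over
components whose positive mask touches the parcel (uncovered parcels get 0
and are marked uncovered) — and parcels are averaged across *covering*
atlases only. Parcels covered by no atlas are flagged missing and excluded
from the 17-network summaries.

## Axis 2 — system integration (k-hubness)

k-hubness counts, per vertex, the retained consensus atoms with loading
magnitude above ε. k = 1 marks a single-network vertex; k ≥ 2 marks a
connector hub participating in multiple systems. k is computed on the
reproducibility-filtered consensus supports (deterministic, and the natural
reading of counting "consensus networks"), is invariant to atom sign flips
and reordering, and satisfies the accounting identity that the sum of k over
vertices equals the total support cardinality. Regional summaries average k
over gray-matter member vertices of the 34 hemisphere-split cortical
networks and the 14 subcortical regions; regions with no gray-matter
vertices are reported missing, never zero.

## Normative deviations (w-scores)

Every topology metric is converted into a covariate-adjusted deviation from
a healthy reference. The reference model is Bayesian linear regression with
a ridge-type conjugate Gaussian prior whose scale is chosen by
marginal-likelihood grid search; continuous covariates (sex, age, head
motion, and the retained atom count for topology features) enter through a
cubic B-spline with four interior knots placed at quantiles of the healthy
training values — "distributed across the covariate range" leaves the
placement open, and quantile knots spend flexibility where the data are.
The model is trained exclusively on healthy participants; patient rows
verifiably never touch the fit.

Heteroskedastic noise is estimated in two stages: log squared residuals are
regressed on the linear continuous covariates (with the `E[log χ²₁]` bias
correction), the mean model is refit once with the implied inverse-variance
weights, and the predictive sd is rescaled so standardized healthy residuals
have unit variance. This is a deliberate simplification of full joint
optimization — the claim is equivalence at the level of the w-score
definition and its calibration, not of the estimator internals.

`w = (y − predicted mean) / predicted sd`, preserving sign, in units of
healthy variability. Calibration is verified on held-out synthetic healthy
subjects (per-feature mean within ±0.1, sd within 0.9–1.1 at n = 500), and
w-scores are exactly invariant to positive affine rescaling of the raw
feature. Subjects whose covariates fall outside the training range are
flagged (their values are clamped for basis evaluation), never silently
suppressed.

## Group inference

Global summaries (normativity, non-normativity) are tested with two-sided
one-sample t tests of w against zero and BH-FDR across the family.
Regional/network measures use permutation max-T: the one-sample null flips
the signs of subject deviation rows — the natural exchangeability assumption
for a symmetric null, since the permutation scheme was not spelled out —
and the corrected p of a region compares its |t| to the null distribution of
the maximum |t| across regions, controlling family-wise error. Two-sample
(label-shuffle) and correlation (covariate-shuffle) variants reuse the same
max-T machinery for subtype contrasts and stage associations. Constant
columns are excluded with a flag, and corrected p always dominates raw p.

Spatial similarity between statistical maps is Pearson r with a spin null
built by rotating parcel centroids (vertex-level maps rotate the vertex
cloud); the similarity-space summary places each syndrome at (r with the
reference profile, mean |difference| from it), optionally per feature
family.

## Subtype and stage inference

Correspondence w-scores (the 26-feature set: 2 global + 17 network-level
consensus + 7 bilateral subcortical CNRs) are sign-aligned on the
patient-sample mean direction so larger always means more abnormal, then
modeled with a z-score event formulation: each feature passes waypoints
z = 1, 2, 3, its expected value following the piecewise-linear trajectory
through its waypoint positions in the event ordering, reaching `z_max` at
the sequence end. `z_max = 5` and per-feature `σ = 1` are configurable
defaults (features are z-scaled; the cited framework's values are not
restated in the methodology). Subject likelihoods marginalize a uniform
stage prior in log space.

Fitting is hierarchical: the one-subtype model by greedy event reinsertion
from `n_start` random admissible orderings followed by Metropolis MCMC over
admissible pairwise swaps; each C-subtype model splits the weakest subtype
of the C−1 solution (2-cluster split of its subjects' MAP stages),
re-optimizes orderings under responsibility weights, and runs MCMC in which
only the proposed component is re-evaluated. Full-scale defaults are 25
starts and 10,000 MCMC iterations; tests use reduced sizes. The subtype
count is selected by five-fold cross-validation with
`CVIC(C) = −2 Σ held-out log-likelihood`, minimized over C. One honest
caveat, visible in synthetic experiments: when the truth has one subtype, a
two-subtype model degenerates to two near-copies of the true ordering and
CVIC differences sit within noise, so strict argmin selection between C = 1
and C = 2 is close to a coin toss on null data — with genuinely distinct
subtypes the margin is enormous. Assignments are MAP over the joint
(subtype, stage) posterior; subjects whose aligned z-scores all sit below
the first waypoint are classified Stage 0 ("network-correspondence normal")
by an explicit raw-threshold rule layered on the MAP stage, because
borderline subjects (a single z just under 1) can otherwise be placed at
stage 1 by the likelihood.

## Sparse canonical correlation

Topology deviations are linked to clinical–cognitive blocks by penalized
matrix decomposition: alternating soft-thresholded power iterations maximize
`uᵀXᵀYv` under unit ℓ2 norms and per-side ℓ1 bounds, the threshold solved in
closed form over the sorted coefficient segments; later dimensions (capped
at four) deflate the previous rank-1 term. With inactive penalties and
orthonormal within-block columns the solution coincides with classical CCA
exactly. Penalties are selected by permutation z-statistics (Fisher-
transformed observed correlation against row-permuted nulls) over a grid of
10 evenly spaced ℓ1 bounds per side between 1 and √dim; significance uses
the add-one permutation p on the first canonical correlation (default 1000
permutations; 200 for selection). Subdomain analysis runs the full
selection–fit–test pipeline for every pair of named feature blocks and
applies BH-FDR across pairs. Cognition is summarized by the first principal
component of the standardized test battery, sign-fixed so higher means
better; subjects missing more than 30% of tests are dropped (flagged), the
remainder mean-imputed. Categorical clinical variables are one-hot coded
then standardized.

## The synthetic-data module: what it does and does not emulate

Every stage is exercised on data with recorded ground truth. The toy
geometry is a unit-sphere point cloud in which "vertices" and "voxels" are
the same objects: one geometry serves spin tests, parcels, and BOLD. It has
spatially contiguous parcels (nearest-centroid patches, never spanning the
x = 0 hemisphere split), a 17-network partition over parcels, a gray-matter
mask with a southern-cap "boundary shell", and 14 subcortical labels in a
reserved polar band (seven per hemisphere) emulating subcortical
segmentation. Planted networks are contiguous gray-matter patches with a
controlled fraction of two-network vertices, so voxel-wise k is known
exactly; BOLD is timecourses × supports plus AR(1) noise (coefficient 0.4
by default, making bootstrap autocorrelation preservation testable), with
SNR defined per vertex as planted-signal sd over noise sd — stated here
because the source methodology never defines a simulation. Cohort,
progression, and cross-block generators plant covariate effects, group
deviations, event-sequence trajectories, and a sparse cross-block latent
with known supports.

What the generators do *not* emulate: realistic hemodynamics, spatial noise
correlations, real surface meshes, multi-site effects, or the visual
identification of artifact components. Passing the recovery and calibration
tests therefore demonstrates that the estimators are correct and
well-calibrated under their stated assumptions — not that those assumptions
hold in any particular clinical data set.

## Problem sizes and defaults used by the test suite

The packaged studies are deliberately small: 400-vertex spheres, 20 parcels,
K = 4 planted networks, 150 frames, SNR 2, 8–20 bootstraps, 20-subject toy
cohorts (12 healthy / 8 patients, with a lean one-covariate spline design at
that size); staging recovery uses n = 200 subjects with 10 features
(σ = 0.5), subtype-count selection replicates n = 100 with 5 features, and
sparse-CCA recovery n = 500 with a planted latent correlation of 0.8.
Full-scale defaults (B = 200, K searched 18–40, 10,000 permutations,
25 starts / 10,000 MCMC iterations, 1000-spin nulls) remain the function
defaults.

## Known limitations

* The decomposition's restart/coherence heuristic assumes network
  timecourses are only weakly correlated; strongly coupled networks could
  defeat coherence-based selection.
* The order-selection criterion is a stated choice, not a validated
  replication of the original tooling's (unnamed) criterion.
* CVIC-based subtype-count selection is indecisive at the C vs C+1 boundary
  when the extra subtype is redundant (see above).
* Heteroskedastic normative noise is log-linear in the continuous
  covariates; sharper variance structure would be mis-specified.
* Spin nulls are exact relabelings but still approximate exchangeability
  for maps whose autocorrelation structure differs strongly from the
  atlas's.
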