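---
title: "Multi-level analysis of lifespan changes in resting-state connectivity"
author: "connAge maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level analysis of lifespan changes in resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connAge)
```

## The scientific problem

Healthy aging reorganizes the brain's large-scale functional networks:
coupling between nodes of the same resting-state network (RSN) tends to
weaken while coupling across networks tends to strengthen, and part of the
age-related decline in general cognitive performance appears to run through
these connectivity changes. `connAge` implements a multi-level analysis of
this phenomenon on resting-state fMRI derivatives:

1. **voxel level** — subject-specific RSN maps (from dual regression
   against group templates) are compared against a young-adult reference
   with the eta-squared similarity statistic, a global index of network
   integrity;
2. **node level** — a whole-brain parcellation (499 ROIs, 142 of which
   belong to 14 canonical RSNs) yields per-subject Pearson connectivity
   matrices, thresholded into binary graphs whose topology is summarized by
   a standard metric battery across a sweep of network-defining thresholds;
3. **network level** — within-network (WNFC) and between-network (BNFC)
   functional connectivity as means of Fisher-z values over exact node-pair
   sets;
4. **inference** — partial correlations of every measure with age, sex and
   ACE-R total score (a 0-100 general-cognition screen), BH-FDR control per
   table, and bootstrap mediation of the age-cognition association through
   connectivity.

Because raw cohort data of this kind are not publicly distributable, the
package ships a synthetic-cohort generator with planted, known effects, so
every stage of the pipeline is testable end-to-end by parameter recovery.

## Models and statistics

### Eta-squared similarity

For two maps $a$ and $b$ on a common voxel set of size $V$, with
$m_i = (a_i + b_i)/2$ and $\bar M$ the grand mean of $m$:

$$\eta^2 \;=\; 1 \;-\;
\frac{\sum_{i=1}^{V}\left[(a_i - m_i)^2 + (b_i - m_i)^2\right]}
     {\sum_{i=1}^{V}\left[(a_i - \bar M)^2 + (b_i - \bar M)^2\right]}$$

The statistic lies in $[0, 1]$: it is 1 iff $a = b$, and 0 when the mean
image is constant at $\bar M$ (e.g. $b = -a$). Unlike a correlation it is
sensitive to scale — `etaSquared(a, 2 * a) < 1` — which is exactly what a
network-integrity index needs: both pattern changes and amplitude changes
count as dissimilarity. The bound follows from the identity
$\sum[(a-\bar M)^2 + (b-\bar M)^2] = 2\sum(m-\bar M)^2 + \tfrac12\sum(a-b)^2$.

The voxel set matters: $V$ changes the statistic. By default voxels where
either map is non-zero enter the comparison; an explicit mask can be
supplied and is recorded with the result. The reference map per RSN is the
voxelwise mean of the subject maps of all subjects aged at most 30 years
(configurable; a cutoff of 40 produces nearly identical references on
synthetic cohorts, which the test suite asserts).

### Temporal preprocessing

From the confound-regression step onward (spatial preprocessing is out of
scope): the first 5 volumes are dropped at ingestion; 24 motion-derived
regressors $[R_t, R_t^2, R_{t-1}, R_{t-1}^2]$ from the 6 rigid-body
parameters, three nuisance signals (CSF, white matter, global), their first
differences, and an intercept (31 columns) are regressed out by least
squares; the residuals are band-pass filtered to 0.01-0.1 Hz. The filter is
a second-order Butterworth applied forward-backward (zero phase): the
literature rarely states a realization, and zero-phase filtering avoids
phase shifts that would bias connectivity estimates. Lagged and differenced
design columns zero-fill their first row so T never changes. Motion
screening excludes a dataset when mean FD $\ge$ 0.2 mm or more than 20% of
volumes have FD > 0.2 mm; FD converts rotations to arc length on a 50 mm
sphere (the paper-silent radius follows the original FD convention).
Design columns are scaled to unit norm before the QR factorization —
translations (mm), squared radians and their lags differ by orders of
magnitude, and unscaled columns can masquerade as rank deficiency; genuine
deficiency falls back to the pseudoinverse with a warning.

### Dual regression

Stage 1 fits every time point's volume jointly onto all K group templates
(multivariate least squares), giving K component time courses; stage 2 fits
every voxel's series jointly onto all K time courses, giving K
subject-specific maps. Joint rather than marginal regression matters
whenever templates overlap spatially — the test suite includes a case where
the two disagree and the joint answer matches the normal-equations oracle.
Stage-2 time courses are variance-normalized by default (the common
convention; a flag disables it), so map units are covariances with
unit-variance courses.

### Graph metrics

Connectivity matrices are thresholded at r = 0.20, 0.25, 0.30, 0.35, 0.40
(strict `>`; ties at the threshold are excluded — measure-zero in floats
but the convention must be deterministic; negative correlations never form
edges). On each binary graph: characteristic path length (mean geodesic
over *reachable* pairs, with the unreachable count reported — the
convention for disconnected graphs is logged because tools differ), global
efficiency (mean inverse geodesic, $1/\infty = 0$), mean degree, mean
fractional betweenness (normalized by $(n-1)(n-2)/2$ so a complete graph
scores 0 and a star's centre 1; raw values are also available), Louvain
modularity (best of 10 seeded restarts), and the hierarchy exponent (the
negative slope of log clustering vs log degree over nodes with degree > 1
and positive clustering). All path-based metrics are verified against a
brute-force all-pairs enumeration on every small graph to $10^{-12}$.

### Network-level connectivity

Correlations are Fisher-transformed ($z = \mathrm{atanh}\, r$) first, then
averaged: WNFC of a k-node network averages exactly $k(k-1)/2$ pair values,
BNFC of a (k, l) pair exactly $k \cdot l$; diagonals never enter and the
cells tile the $142 \cdot 141/2$ RSN-subset pairs exactly once. All 91
unordered network pairs are emitted; significance filtering belongs to the
inference layer.

### Inference

Partial correlations residualize both variables on the covariates plus an
intercept; p-values use the t distribution on $n - 2 - k$ degrees of
freedom. BH-FDR is applied per output table (per-column families). The KS
normality check standardizes the values before comparison with the
standard normal — comparing raw values against N(0, 1) would reject for any
shifted sample regardless of shape, so the standardized variant is the
meaningful check (the package documents rather than resolves what the
original Matlab usage did). Mediation fits three shared-covariate OLS
regressions (giving paths a; b and c'; c), so the indirect effect satisfies
$ab = c - c'$ exactly — asserted to $10^{-10}$ on the point estimate and on
every bootstrap draw. Bootstrap inference resamples subjects with
replacement (default 10,000 draws; sex controlled throughout), reporting
per-path z (mean/SD of the bootstrap distribution) and two-sided percentile
p-values floored at $2/n_{boot}$. Percentile intervals were chosen over
bias-corrected ones for transparency; degenerate resamples (a constant
regressor) are redrawn and counted. Mediation runs only for measures with
uncorrected p < 0.05 against both age and ACE-R, mirroring the candidate
rule of the analysis the package implements.

## The synthetic cohort: what it emulates and what it does not

`generateCohort()` and its companions emulate the study conditions of a
129-subject lifespan cohort (ages 21-86, uniform — the published decade
table is roughly balanced; 72% female; ACE-R around 96 with realistic
decline; 198 volumes at TR 2.5 s):

* **Node time series** are Gaussian with a block correlation matrix:
  within-network coupling $0.30 - 0.15\,z$ and cross-network coupling
  $0.05 + 0.10\,z$, where $z = (\text{age}-50)/35$; blocks touching non-RSN
  nodes stay flat. The matrix is repaired to the nearest sampleable
  correlation matrix by eigenvalue clipping at $10^{-6}$ and rescaling to
  unit diagonal, which guarantees Cholesky sampling even at extreme planted
  couplings. Volumes are i.i.d. by default (serial correlation after
  band-passing is unspecified in the literature); an AR(1) option exists.
* **Spatial maps** mix each subject's template with the mean of the other
  templates at weight $\lambda = \mathrm{clip}(0.15 + 0.15\,z +
  \mathcal N(0, 0.08),\, 0,\, 0.95)$ plus voxel noise (SD 0.1), on a small
  24 x 24 x 12 grid — full MNI resolution adds nothing to testing a
  voxelwise statistic. The subject-level scatter term is essential: without
  it $\lambda$ is a deterministic function of age and the similarity-age
  correlation is nearly perfect, unlike any real cohort.
* **Cognition** follows the mediation model ACE-R $= 96 - 1.0\,z +
  1.5\,M + \mathcal N(0, 2.5)$ with mediator $M = -1.0\,z + u$,
  $u \sim \mathcal N(0, 0.4)$, clipped to [0, 100]; $u$ also feeds back
  into the subject's within-network couplings (share 0.30), so measured
  connectivity carries the mediation signal.
* **Motion** is a 6-parameter random walk; 10% of subjects by default get a
  step scale (0.08 mm) that violates the FD criteria, the rest 0.02 mm.

These defaults were calibrated once, against the regime the emulated study
reports rather than against any test outcome: ACE-R/age correlation near
-0.4, and partial correlations of similarity and WNFC with age (controlling
sex and ACE-R) in the moderate -0.3 to -0.5 band. They are study
conditions, not tuning knobs.

What the generator does **not** emulate: scanner physics, spatial
autocorrelation and smoothing, physiological noise structure, non-Gaussian
BOLD marginals, ACE-R subscores, or any voxelwise group inference. Passing
parameter-recovery tests therefore demonstrates that the pipeline's
estimators recover planted monotone age effects and mediation signs under
Gaussian block structure — not that they would be unbiased on real fMRI.

## Numerical and design choices

* Seeded determinism everywhere: every generator runs under a private RNG
  state (`withSeed`), and the pipeline derives per-stage, per-subject child
  seeds from one master seed, so toggling stages never shifts another
  stage's stream and a rerun is byte-identical.
* Fisher transform clips $|r| \ge 1$ to $1 - 10^{-7}$ with a warning
  (numerically perfect correlations otherwise map to infinity).
* Band edges must satisfy $0 \le \text{low} < \text{high} <$ Nyquist;
  the series is demeaned before filtering (DC is in the stop band, and
  removing it first keeps the forward-backward pass free of edge
  transients).
* Degenerate inputs fail loudly and early: constant node series name the
  offending node; an empty reference subgroup, a single-node WNFC network,
  a zero eta-squared denominator and an edgeless modularity call are all
  errors, not NAs.
* Covariates that are constant in the analysed subsample (e.g. a
  single-sex subgroup after screening) are dropped from partial
  correlations and mediation rather than silently pseudoinverted.

## Problem sizes used by the shipped checks

The test-suite cohorts are sized so the full multi-level recovery runs on a
single CPU in minutes: 150-subject cohorts on the 142-node RSN subset with
193 volumes for the end-to-end sign-recovery checks (the RSN-level
statistics — eta-squared, WNFC, BNFC — use only RSN nodes; a full 499-node
subject is built once to verify the 499 x 499 contract), 20 cohort seeds,
bootstrap sizes of 1,000-2,000 for calibration studies versus the 10,000
default for single analyses. The acceptance script evaluates the analytic
eta-squared endpoints on a freshly generated 24 x 24 x 12 map.

## Known limitations

* Group ICA itself is not implemented; templates are inputs (synthetic
  blob templates in tests). Voxelwise nonparametric group inference (e.g.
  permutation + TFCE) is out of scope.
* The graph conventions on disconnected graphs, betweenness normalization
  and the hierarchy fit follow this package's documented definitions; other
  toolboxes differ and the output metadata records the convention rather
  than claiming equivalence.
* The bootstrap uses percentile p-values; BCa is not implemented.
* Real-data effect sizes cannot be reproduced without the original cohort;
  all quantitative acceptance is parameter recovery on synthetic data plus
  the analytic surfaces of the statistics themselves.
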