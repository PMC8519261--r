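---
title: "Methods: linking regional expression to cortical thickness statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking regional expression to cortical thickness statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxpls)
```

`ctxpls` connects two measurements made over the same cortical parcellation:
gene expression of the healthy brain, sampled at stereotactic points by a
few donors, and regional statistics of cortical thickness (CT) from a
patient-control cohort. This vignette documents the models, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data validation does and does not establish.

## Sample-to-parcel mapping

Expression samples are points in mm (MNI) space; the parcellation is an
integer-labelled voxel volume with an affine mapping 0-based voxel indices
to mm (the NIfTI convention; stored in the sform with code 2). A sample is
assigned:

1. to the region of its containing voxel, when labelled (distance recorded
   as 0 — the point lies inside the parcel);
2. otherwise to the region of the nearest labelled *voxel centre* within
   `tolerance_mm` (default 2 mm, the conventional tolerance for atlas
   expression data), ties to the lower region id;
3. otherwise it stays unassigned.

Distance to voxel centres, rather than to the parcel surface, is a
convention: it is unambiguous, cheap, and matches common practice; for
typical 1-2 mm voxels the difference is below the voxel scale. The region
× gene predictor matrix averages expression per donor within a region and
then across donors that contributed at least one sample there — a donor
with no samples in a region is excluded from that region's mean, never
imputed as zero, because zero is a data value on the expression scale, not
a missing-data code. Regions with no samples from any donor are dropped and
reported.

## Regional imaging statistics

* **Group contrast**: Welch's unequal-variance t-test per region, oriented
  control minus patient, so positive t means thinner cortex in patients
  (atrophy). Benjamini-Hochberg correction runs across exactly the supplied
  region family (68 bilateral regions for reporting; the 34 single-
  hemisphere statistics feed the PLS, matching a left-hemisphere-only
  expression matrix).
* **Hemispheric contrast**: right minus left, paired by default since the
  same subjects contribute both hemispheres; an unpaired Welch variant is
  available and the mode is recorded in the output. BH across 34.
* **CT-clinical coupling**: per (region, feature), an ordinary
  least-squares fit of `CT ~ score + age` on complete cases among patients
  (no imputation — available-n per feature is reported instead), testing
  the score coefficient against zero. BH runs jointly across all 34 × 9
  cells. Cells with fewer than 4 complete cases or a singular design are
  flagged and excluded from the BH family. Sex is carried in the tables but
  not modelled; only age is adjusted for. Scores enter untransformed.

Degenerate Welch inputs are resolved explicitly: both groups constant with
equal means gives a flagged undefined statistic; constant with different
means a flagged infinite statistic with p = 0.

## Partial least squares

The core is NIPALS with rank-one deflation of both blocks. Per component:
unit X-weights `w` (for a single response, directly proportional to
`X'y`), scores `t = Xw`, unit Y-weights `c`, Y-scores `u = Yc`, loadings
`p = X't/t't` and `q = Y't/t't`, inner coefficient `beta = u't/t't`, then
`X <- X - tp'`, `Y <- Y - tq'`. The rotated weights `R = W(P'W)^{-1}`
satisfy `T = Xc R` and are the gene weights used for ranking; prediction
coefficients are `B = RQ'`.

Numerical conventions:

* **Preprocessing** — columns of both blocks are mean-centred; unit-variance
  scaling is off by default (expression values share a scale and the
  response is a single t-vector or a t-matrix on a common scale) but
  available and recorded in the fit.
* **Sign** — each component is flipped, if needed, so `cor(t_k, u_k) >= 0`;
  at an exact zero correlation the largest-magnitude weight entry is made
  positive. This fixes an otherwise arbitrary sign consistently across
  platforms.
* **Convergence** — the inner loop stops when the weight vector changes by
  less than 1e-12. The iteration cap is 5000: the inner loop is a power
  iteration on `X'YY'X`, whose convergence rate is the eigen-gap ratio, and
  near-degenerate multi-response blocks genuinely need thousands of
  iterations to reach 1e-12; a few hundred iterations would abort on
  well-posed random instances.
* **Rank exhaustion** — once deflation reduces the X block below 1e-18 of
  its original sum of squares, further components would rotate numerical
  noise with exploding `(P'W)^{-1}` factors; the fit stops with a rank
  error instead. Zero-variance predictor columns are retained with exactly
  zero weight so gene indexing is preserved.
* **Explained variance** — component k explains
  `||t_k p_k'||^2_F / ||Xc||^2_F` of X (analogously of Y), reported in
  percent; X fractions sum to 100 at full rank.

**Component selection** is leave-one-out cross-validation: each fold refits
(re-centring inside the fold, so no information leaks), predicts the
held-out response with k = 0..K components, and accumulates PRESS;
`RMSEP(k) = sqrt(PRESS/(n p))` and the optimum is the argmin over k >= 1
with ties resolved towards fewer components. A caveat worth knowing: when
the predictor block carries appreciable noise beyond its dominant
structure, that noise is *fixed structure* from the model's point of view,
and extra components can genuinely lower held-out error; with n ≈ 34
regions the RMSEP curve is then nearly flat and its LOO estimate noisy, so
argmin selection scatters across small k. The selection concentrates on
k = 1 when the predictor block is dominated by (or exactly) rank one —
which is how the validation scenarios plant it.

## Preranked gene-set enrichment

Genes are ranked by descending signed weight, ties broken by gene id
(recorded in the output metadata). The enrichment score is the signed
maximum deviation of the classic weighted running sum: member genes add
`|w|^exponent / Σ_set |w|^exponent`, non-members subtract `1/(N - N_H)`;
the exponent defaults to 1 (the field's default weighted statistic;
0 gives the unweighted Kolmogorov-Smirnov form). ES is in [-1, 1] by
construction.

Because the input is a preranked gene list with no sample-level phenotype,
the only coherent null is gene-label permutation: `n_perm` (default
10,000) random same-size member draws per set size. The two-sided p-value
is `(1 + #{|ES_null| >= |ES|}) / (n_perm + 1)`; the normalised score
divides ES by the mean |null ES| of matching sign; BH-FDR runs across all
tested sets (defaults: sizes 10-500 after universe intersection, all
recorded). A set's direction is the sign of the median member weight:
`+` means the set's genes are more expressed where the response (e.g. the
atrophy t-statistic) is higher.

A known limitation of gene-label permutation, documented rather than
hidden: co-expressed gene sets violate the null's exchangeability
assumption. If a set's members share a loading on a spatial expression
gradient, their PLS weights share the common random factor `g'y`, the set
clusters at one end of the ranking even when the response carries no
signal, and the permutation p-value is anti-conservative. This is a
property of the method class, not of this implementation; null-scenario
validation therefore plants independent gene loadings.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
the physics of the measurements:

* a 3D label volume of cuboid parcels (default 34, edge 3 voxels of 2 mm,
  one-voxel background gaps), region ids ascending along the first axis so
  the planted gradient is a spatial ("caudal-rostral") axis;
* per-donor point samples, Poisson counts per donor-region cell (mean 5)
  with a 10% chance of an empty cell — exercising the missing-donor
  averaging path — and expression
  `mu_j + a_j g_i + N(0, sigma_e)` at coordinates uniform inside the
  region's voxels;
* a two-group CT cohort: controls `N(base_i, sigma_ct)`, patients
  `N(base_i - delta_i, sigma_ct)`, both hemispheres, optional extra
  left-hemisphere thinning in patients, draws truncated at 0.5 mm (CT is
  physically positive; the bound is recorded in the scenario);
* clinical scores as linear functions of left-hemisphere CT plus an age
  term and noise, with missing-completely-at-random entries written as
  empty TSV fields (never zero).

Defaults follow the motivating study where it states them (34 regions, six
donors, 149 patients, 369 controls, cohort mean ages 64.8/65.7 and male
fractions 0.657/0.481, nine clinical features, ~20% missing clinical
entries) and a scientist's judgement where it does not: baseline CT uniform
in 2.2-3.0 mm, CT noise 0.25 mm (typical between-subject regional SD),
log-intensity expression baseline N(7, 1) with noise SD 0.5, gene loadings
N(0, 0.5), and a default group effect of `0.1 mm` per gradient unit so
atrophy co-varies with the expression axis. Every generated object is a
pure function of the scenario and its seed.

What passing the synthetic validation shows: the mapping equals an
exhaustive nearest-voxel search; the statistics match closed-form oracles;
the PLS equals independent reference implementations and recovers planted
loadings and gradients; enrichment p-values converge to enumerated exact
tails; and the full pipeline detects a planted co-loaded module with the
correct direction while staying quiet when nothing is planted. What it
does not show: robustness to the things real data add — spatial
autocorrelation beyond the planted gradient, donor effects, registration
error, non-Gaussian CT distributions, and co-expression structure in the
null (see above). Conclusions about real cohorts still require the usual
domain-level scrutiny.

## Problem sizes used in validation

The shipped tests and the acceptance script run at deliberately modest
sizes — 34 regions, 60-500 genes, 21 gene sets, 500-2,000 permutations,
50-seed simulation blocks — chosen so the whole validation executes in a
few minutes while keeping every statistical check well-powered; all sizes
are set in one place at the top of each script and scale up without code
changes.
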