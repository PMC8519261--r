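# ctxpls

Imaging transcriptomics of cortical thickness changes via partial least
squares.

## The problem

Regional cortical atrophy in neurodegenerative disease (the motivating case
is Parkinson's disease) has an unknown molecular basis: which genes, and
which biological pathways, are preferentially expressed in the cortical
regions that thin? One way to ask the question is to combine two very
different datasets over a shared cortical parcellation:

* **regional gene expression in the healthy brain** — microarray samples
  from a handful of donors, each sample a point in MNI (mm) space with an
  expression vector over ~20k genes (the Allen Human Brain Atlas layout);
* **regional cortical thickness (CT) statistics in a patient cohort** — per
  Desikan-Killiany region, the Welch t-statistic of the patient-control CT
  difference, or the t-statistics of region-wise regressions of CT on
  clinical severity scores.

With 34 regions and ~20k collinear genes, ordinary regression is hopeless;
partial least squares (PLS) regression is the standard tool, followed by
gene-set enrichment on the resulting gene weights. `ctxpls` implements this
pipeline end to end for analysts who have regional CT tables and
atlas-style expression data, and — because the real inputs are large,
access-controlled downloads — ships a synthetic-data generator with planted
structure so every stage can be exercised and validated at desk scale.

## What the package computes

**Sample-to-parcel mapping.** Each expression sample is assigned to the
region of the voxel containing its MNI coordinate, or to the nearest
labelled voxel centre within a 2 mm tolerance (Euclidean distance in mm;
ties to the lower region id). The predictor matrix `X` (regions × genes) is
built by two-level averaging: within each donor per region, then across the
donors that contributed samples there.

**Regional statistics.** Per region, the Welch unequal-variance t-statistic
of the control-minus-patient CT difference (positive t = atrophy), a paired
left-right contrast, and per-(region, feature) ordinary least squares fits

    CT_i = alpha + beta1 * K_j + beta2 * Age + eps

whose `t(beta1)` quantifies the CT-clinical coupling. All p-values are
Benjamini-Hochberg corrected within their stated family (68 bilateral
regions, 34 unilateral regions, or all 34 × 9 regression cells).

**PLS by NIPALS.** For centred blocks `X` (n × m) and `Y` (n × p), each
component extracts a unit X-weight vector `w` maximising the covariance of
the scores `t = Xw` and `u = Yc`, with loadings `p = X't/t't`,
`q = Y't/t't`, inner relation `u ≈ beta·t`, and rank-one deflation of both
blocks. The rotated weights

    R = W (P'W)^{-1},   T = Xc R

are the per-gene weights used for ranking (`model-1`: single response =
t(ΔCT); `model-2`: multi-response = the regions × features t-matrix).
Leave-one-out cross-validation (PRESS/RMSEP, re-centring inside each fold)
selects the component count.

**Preranked enrichment.** Genes are ranked by descending signed weight; a
set's enrichment score is the signed maximum deviation of the weighted
running sum (hits gain `|w|/Σ_set|w|`, misses lose `1/(N−N_H)`), with a
same-size random-gene permutation null, sign-matched normalised scores,
two-sided permutation p-values, BH-FDR across sets, and a `+`/`−` direction
from the median member weight.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (34 regions, 300 genes, 6 donors, 149 patients / 369 controls, a
15-gene module co-loaded on the planted caudal-rostral gradient that also
drives the planted CT effect):

```sh
Rscript analysis/01_simulate.R        # writes results/data/ (NIfTI, CSVs, TSVs, GMT)
Rscript analysis/02_map_expression.R  # assignment + region x gene matrix
Rscript analysis/03_imaging_stats.R   # Welch / paired / regression tables
Rscript analysis/04_model1.R          # single-response PLS + enrichment
Rscript analysis/05_model2.R          # multi-response PLS + enrichment
```

Stage 4 prints, for the default seed:

```
component-1 score vs t(dCT): Pearson r = 0.956
explained variance: 75.9% of expression, 91.4% of CT change
leave-one-out CV optimum: 1 component(s)
enriched gene sets (FDR < 0.05): 1 of 21
                    set size es      nes            p          q direction
 planted_atrophy_module   15  1 2.177753 0.0004997501 0.01049475         +
```

Reading: the component-1 expression score tracks the regional atrophy
t-statistics (r = 0.96, one latent component suffices per LOO CV), and the
only enriched set is the planted module, recovered with the correct
positive direction (its genes are more expressed where atrophy is
stronger). The equivalent real-data run would substitute the Allen atlas
donor folders, a FreeSurfer Desikan-Killiany label volume, and cohort CT /
clinical tables in the same layouts.

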