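#!/usr/bin/env Rscript

# Stage 4: single-response PLS (model-1).
#
# Predicts the regional Welch t-statistics of the CT group difference from
# regional gene expression, examines component-1 (leave-one-out CV confirms
# the component count), and tests gene sets on the component-1 gene weights
# with the permutation-null running-sum statistic. Outputs under
# results/run/model1/.

library(ctxpls)

SEED <- 1L
cfg <- pipeline_config(
  parcellation = "results/data/parcellation.nii",
  donor_dir = "results/data",
  ct_table = "results/data/ct.tsv",
  clinical_table = "results/data/clinical.tsv",
  gmt = "results/data/gene_sets.gmt",
  out_dir = "results/run",
  gsea_nperm = 2000, seed = SEED)

res <- run_model1(cfg)

ev <- explained_variance(res$fit)
cat(sprintf("\ncomponent-1 score vs t(dCT): Pearson r = %.3f\n",
            res$report$responses$pearson_r[1]))
cat(sprintf("explained variance: %.1f%% of expression, %.1f%% of CT change\n",
            ev$x_pct[1], ev$y_pct[1]))
cat(sprintf("leave-one-out CV optimum: %d component(s)\n", res$cv$optimal))
sig <- res$gsea[res$gsea$q < 0.05, ]
cat(sprintf("enriched gene sets (FDR < 0.05): %d of %d\n",
            nrow(sig), nrow(res$gsea)))
if (nrow(sig) > 0)
  print(sig[, c("set", "size", "es", "nes", "p", "q", "direction")],
        row.names = FALSE)
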