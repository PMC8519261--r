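#!/usr/bin/env Rscript

# Stage 5: multi-response PLS (model-2).
#
# Predicts the 34 x 9 matrix of t-statistics from the CT-clinical
# regressions (stage 3) from the same expression matrix, retains the first
# two components for enrichment, and reports per-clinical-feature score
# correlations and Y-loadings. Outputs under results/run/model2/.

library(ctxpls)

SEED <- 1L
cfg <- pipeline_config(
  parcellation = "results/data/parcellation.nii",
  donor_dir = "results/data",
  ct_table = "results/data/ct.tsv",
  clinical_table = "results/data/clinical.tsv",
  gmt = "results/data/gene_sets.gmt",
  out_dir = "results/run",
  n_components_model2 = 3, retain_model2 = 2,
  gsea_nperm = 2000, seed = SEED)

res <- run_model2(cfg)

ev <- explained_variance(res$fit)
cat(sprintf("\nlatent correlations r(t_k, u_k): %s\n",
            paste(sprintf("comp%d %.2f", ev$component,
                          res$report$components$r_tu), collapse = ", ")))
cat(sprintf("first two components explain %.1f%% of expression, %.1f%% of the response\n",
            ev$x_cum_pct[2], ev$y_cum_pct[2]))
cat("\nper-feature component-1 correlations and Y-loadings:\n")
r1 <- res$report$responses
print(r1[r1$component == 1, c("response", "pearson_r", "q_loading")],
      row.names = FALSE, digits = 3)
for (k in names(res$gsea)) {
  g <- res$gsea[[k]]
  cat(sprintf("%s: %d of %d sets enriched (FDR < 0.05)\n",
              k, sum(g$q < 0.05), nrow(g)))
}
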