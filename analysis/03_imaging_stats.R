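#!/usr/bin/env Rscript

# Stage 3: regional imaging statistics.
#
# (a) Welch t-tests of the patient-control CT difference per region,
#     oriented so positive t = thinner in patients (atrophy), BH-corrected
#     across the 68 bilateral regions;
# (b) paired left-right contrasts within patients, BH-corrected across 34;
# (c) per-(region, feature) regressions CT ~ score + age in patients, with
#     the t-statistic of the score coefficient, BH across all 34 x 9 cells.
# Tables land under results/stats/.

library(ctxpls)

data_dir <- "results/data"
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ct <- read.delim(file.path(data_dir, "ct.tsv"), na.strings = "")
clinical <- read.delim(file.path(data_dir, "clinical.tsv"), na.strings = "",
                       check.names = FALSE)
regions <- sub("^lh_", "", grep("^lh_", names(ct), value = TRUE))

bilateral <- regional_group_contrast(ct, grep("^(lh|rh)_", names(ct),
                                              value = TRUE))
cat(sprintf("group contrast: %d of %d regions significant (BH q < 0.05), max |t| = %.2f\n",
            sum(bilateral$q < 0.05), nrow(bilateral), max(abs(bilateral$t))))

hemi <- hemispheric_contrast(ct, regions, group = "patient")
cat(sprintf("hemispheric contrast (paired, patients): %d of %d regions significant\n",
            sum(hemi$q < 0.05), nrow(hemi)))

reg <- ct_clinical_regression(ct, clinical, regions)
tested <- is.na(reg$flag)
cat(sprintf("CT-clinical regressions: %d cells tested, %d significant, n per cell %d-%d\n",
            sum(tested), sum(reg$q < 0.05, na.rm = TRUE),
            min(reg$n[tested]), max(reg$n[tested])))

wt <- function(df, name) write.table(df, file.path(out_dir, name),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE)
wt(bilateral, "contrast_bilateral.tsv")
wt(hemi, "contrast_hemispheric.tsv")
wt(reg, "ct_clinical_regression.tsv")
cat("statistics written to", out_dir, "\n")
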