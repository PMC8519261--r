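#!/usr/bin/env Rscript

# Stage 2: map expression samples to parcels and build the predictor matrix.
#
# Samples are assigned to the region of their containing voxel, or to the
# nearest labelled voxel centre within 2 mm; expression is then averaged per
# donor within each region and across the donors that contributed samples.
# Writes the assignment table, the region x gene matrix and the QC table of
# per-(donor, region) sample counts under results/mapping/.

library(ctxpls)

data_dir <- "results/data"
out_dir <- "results/mapping"

parc <- read_parcellation(file.path(data_dir, "parcellation.nii"))
samples <- read_donor_samples(data_dir)
cat(sprintf("loaded %d samples from %d donors, %d genes\n",
            nrow(samples$annot), length(unique(samples$annot$donor)),
            length(samples$gene_ids)))

asg <- assign_samples(samples, parc, tolerance_mm = 2)
cat(sprintf("assigned: %d by containment, %d by nearest voxel (<= 2 mm), %d unassigned\n",
            sum(asg$method == "containment"), sum(asg$method == "nearest"),
            sum(asg$method == "unassigned")))

rex <- aggregate_expression(samples, asg,
                            region_ids = seq_along(parc$region_names),
                            region_names = parc$region_names)
cat(sprintf("predictor matrix: %d regions x %d genes; dropped regions: %d\n",
            nrow(rex$X), ncol(rex$X), length(rex$dropped_regions)))
cat(sprintf("samples per region: %d-%d (median %.0f)\n",
            min(colSums(rex$counts)), max(colSums(rex$counts)),
            median(colSums(rex$counts))))

write_mapping(rex, asg, out_dir)
cat("mapping artifacts written to", out_dir, "\n")
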