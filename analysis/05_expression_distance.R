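#!/usr/bin/env Rscript
# Proportion-weighted pseudobulk expression distances between samples and
# their classical-MDS projection: metastatic samples should scatter more
# widely (larger within-condition distances) and separate from marrow
# controls along the planted tumor expression shift.

library(nichecompare)

counts <- read_counts_mtx("results/qc/filtered/matrix.mtx",
                          "results/qc/filtered/features.tsv",
                          "results/qc/filtered/barcodes.tsv")
cell_meta <- read_result_table("results/qc/cell_meta_filtered.tsv")
sample_meta <- read_result_table("results/cohort/sample_meta.tsv")

pb <- pseudobulk_profiles(counts, cell_meta, min_cells = 10)
ed <- expression_distance(pb)
xy <- mds_project(ed)

dir.create("results/distance", showWarnings = FALSE, recursive = TRUE)
dm <- data.frame(sample_a = rownames(ed$D)[row(ed$D)],
                 sample_b = colnames(ed$D)[col(ed$D)],
                 distance = as.vector(ed$D))
write_table(dm[dm$sample_a < dm$sample_b, ], "results/distance/distances.tsv")
coords <- data.frame(sample_id = rownames(xy), mds1 = xy[, 1], mds2 = xy[, 2])
coords$condition <- sample_meta$condition[match(coords$sample_id,
                                                sample_meta$sample_id)]
write_table(coords, "results/distance/mds_coordinates.tsv", sort_keys = NA)

cond <- sample_meta$condition[match(rownames(ed$D), sample_meta$sample_id)]
between <- mean(ed$D[cond == "BoneMet", cond == "Primary"], na.rm = TRUE)
wa <- ed$D[cond == "BoneMet", cond == "BoneMet"]
within_bm <- mean(wa[upper.tri(wa)], na.rm = TRUE)
wb <- ed$D[cond == "Benign", cond == "Benign"]
within_benign <- mean(wb[upper.tri(wb)], na.rm = TRUE)
message(sprintf("mean distance BoneMet-Primary %.4f | within BoneMet %.4f | within Benign %.4f",
                between, within_bm, within_benign))
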