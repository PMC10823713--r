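#!/usr/bin/env Rscript
# Applies the three cell-level QC gates (>= 700 UMI, <= 20% mitochondrial
# transcripts, doublet score <= 0.4) to the simulated cohort and reports
# per-sample removals. Downstream scripts consume the filtered cohort.

library(nichecompare)

cohort_dir <- "results/cohort"
counts <- read_counts_mtx(file.path(cohort_dir, "matrix.mtx"),
                          file.path(cohort_dir, "features.tsv"),
                          file.path(cohort_dir, "barcodes.tsv"))
cell_meta <- read_result_table(file.path(cohort_dir, "cell_meta.tsv"))

out <- apply_qc(counts, cell_meta, nc_config())
rp <- out$report
message(sprintf("retained %d / %d cells (%d low-UMI, %d high-mito, %d doublet removed)",
                sum(rp$retained), sum(rp$n_input),
                sum(rp$removed_low_umi), sum(rp$removed_high_mito),
                sum(rp$removed_high_doublet)))

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_table(rp, "results/qc/qc_report.tsv")
write_counts_mtx(out$counts, "results/qc/filtered")
write_table(out$cell_meta, "results/qc/cell_meta_filtered.tsv",
            sort_keys = NA)
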