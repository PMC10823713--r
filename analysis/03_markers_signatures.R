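#!/usr/bin/env Rscript
# Marker detection (one-vs-rest Wilcoxon with p-derived Z > 3) and
# signature scoring: scores the planted exhaustion-like gene set per cell,
# averages it per sample within CTLs, and tests BoneMet against each
# control fraction with BH correction across the comparisons.

library(nichecompare)

counts <- read_counts_mtx("results/qc/filtered/matrix.mtx",
                          "results/qc/filtered/features.tsv",
                          "results/qc/filtered/barcodes.tsv")
cell_meta <- read_result_table("results/qc/cell_meta_filtered.tsv")
sample_meta <- read_result_table("results/cohort/sample_meta.tsv")
truth <- jsonlite::fromJSON("results/cohort/truth.json")

norm <- normalize_counts(counts)
markers <- find_markers(norm, cell_meta$cluster)
dir.create("results/markers", showWarnings = FALSE, recursive = TRUE)
write_table(markers, "results/markers/markers.tsv")

passing <- markers[markers$passes, ]
recovered <- vapply(names(truth$markers), function(ct) {
  mean(truth$markers[[ct]] %in% passing$gene[passing$cluster == ct])
}, numeric(1))
message(sprintf("markers: %d gene/cluster pairs pass Z > 3; planted marker recovery %.0f%%",
                nrow(passing), 100 * mean(recovered)))

sig_genes <- truth$signature$genes
scores <- score_signature(norm, sig_genes)
cmp <- compare_signature_across_conditions(
  scores, cell_meta, sample_meta, cell_type = "CTL",
  condition_pairs = list(c("BoneMet", "Benign"), c("BoneMet", "Involved"),
                         c("BoneMet", "Distal"), c("BoneMet", "Primary")))
write_table(cmp$sample_scores, "results/markers/signature_sample_scores.tsv")
write_table(cmp$tests, "results/markers/signature_tests.tsv")
sig_rows <- cmp$tests[!is.na(cmp$tests$padj) & cmp$tests$padj < 0.05, ]
message(sprintf("signature: elevated in BoneMet CTLs vs %d of %d control fractions (padj < 0.05)",
                nrow(sig_rows), nrow(cmp$tests)))
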