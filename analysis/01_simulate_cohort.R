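#!/usr/bin/env Rscript
# Simulates the study cohort used by every downstream analysis script: a
# bone-marrow case-control design (BoneMet / Involved / Distal / Benign
# fractions plus Primary tumors) with planted composition shifts (Macro2,
# MSC2 up in bone metastasis), an exhaustion-like signature in BoneMet
# CTLs, tumor DE genes between BoneMet and Primary, and two planted
# ligand-receptor axes (RANKL-RANK from MSC2, CCL18-CCR8 from Macro2).
# Writes the 10x-style MTX triple, metadata tables and the ground-truth
# record under results/cohort/.

library(nichecompare)

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Scaled-down sample counts per condition (the full clinical design has
# 9/4/4/12/9/14/9 samples; we keep the case-control ratios at sizes a
# laptop run finishes in minutes).
spec <- cohort_spec(
  conditions = c(BoneMet = 9, Involved = 4, Distal = 4, Benign = 7,
                 Primary = 9),
  cells_per_sample = c(300, 600),
  n_genes = 1000,
  signature = list(n_genes = 10, fold = 2, cell_type = "CTL",
                   condition = "BoneMet"),
  de = list(n_genes = 50, lfc = 2, cell_type = "Tumor",
            condition_a = "BoneMet", condition_b = "Primary"),
  qc_low_umi = 0.05, qc_high_mito = 0.03, qc_high_doublet = 0.02,
  seed = 20260927L)

sim <- simulate_cohort(spec)
message(sprintf("simulated %d cells x %d genes across %d samples",
                ncol(sim$counts), nrow(sim$counts), nrow(sim$sample_meta)))

write_counts_mtx(sim$counts, out_dir)
write_table(sim$cell_meta, file.path(out_dir, "cell_meta.tsv"),
            sort_keys = NA)
write_table(sim$sample_meta, file.path(out_dir, "sample_meta.tsv"),
            sort_keys = NA)
truth_path <- file.path(out_dir, "truth.json")
writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, digits = NA,
                            force = TRUE), truth_path)
message("cohort written to ", out_dir)
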