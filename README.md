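# nichecompare

Comparative statistics for multi-sample, multi-condition single-cell
RNA-seq cohorts, built around the question of how a tumor remodels its
niche: which cell populations expand in diseased tissue relative to
controls, how strongly each subpopulation's expression program shifts,
which ligand–receptor channels connect sender and receiver cell types, and
whether a cell-state gene signature carries prognostic information in bulk
survival cohorts. The motivating setting is bone-marrow biopsies spanning
solid bone metastases, marrow adjacent to and distant from the lesion,
benign and healthy marrow, and primary tumors — but every function takes
generic counts, labels and sample metadata.

## What the package computes

| Stage | Statistic |
|---|---|
| QC gating | cells kept iff total UMI ≥ 700, mito fraction ≤ 0.20, doublet score ≤ 0.40 (strict removal rules; boundary cells kept) |
| Markers | one-vs-rest Wilcoxon per gene/cluster; signed probit Z = sign(Δmean)·Φ⁻¹(1−p/2), filter Z > 3 |
| Signatures | per-cell score = mean normalized expression over the gene set; per-sample mean; sample-level Wilcoxon + BH across condition pairs |
| Composition (clustered) | per-sample within-major-population fractions, ≥ 50-cell gate, two-sided Wilcoxon + BH across cell types |
| Composition (cluster-free) | per-sample 2D KDE on a shared 400×400 grid; condition mean maps; per-bin standardized Wilcoxon difference |
| Expression distance | D(i,j) = Σₛ wₛ (1 − Pearson of pseudobulk profiles), wₛ ∝ mean subpopulation proportion, renormalized over shared subpopulations; classical MDS |
| Pseudobulk DE | per-sample aggregation with 10/320-cell gates, median-of-ratios size factors, moment NB dispersion, NB GLM Wald test, BH; 100× leave-one-out resampling with per-gene support |
| Ligand–receptor | score = mean(ligand in A) × mean(receptor in B) with a 10 %-expressing gate; p from 1000 joint label permutations (add-one estimator); screen ligand Z > 4 and receptor Z > 0 |
| Survival | top/bottom 25 % stratification by mean signature expression; two-sided log-rank + KM; Cox with age and stage; 200× gene-subset bootstrap reporting the 0.90-quantile p |

A synthetic-cohort generator (`cohort_spec()` / `simulate_cohort()`,
`survival_cohort_spec()` / `simulate_survival_cohort()`,
`simulate_nb_pseudobulk()`) plants known composition shifts, markers,
signatures, DE genes, ligand–receptor couplings and signature-linked
hazards, and returns a truth record so every stage can be validated
against ground truth.

## Worked example

The numbered drivers under `analysis/` run the full workflow on a
simulated cohort (9 bone-metastasis, 4 involved, 4 distal, 7 benign
marrow samples plus 9 primary tumors; ~15,000 cells after simulation):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_qc.R
Rscript analysis/06_pseudobulk_de.R
Rscript analysis/08_survival.R
```

prints (abridged):

```
simulated 15139 cells x 1000 genes across 33 samples
retained 13621 / 15139 cells (761 low-UMI, 454 high-mito, 303 doublet removed)
DE: 50 significant genes (padj < 0.05, |log2FC| > 1.5) over 100 LOO rounds
  planted recall 1.00 | false discoveries 0 | mean LOO support of planted 1.00
strata: 100 high / 100 low of 400 patients
log-rank p = 9.64e-06; Cox HR (age+stage adjusted) = 1.72 [1.18, 2.52], p = 0.00525
bootstrap stability: 0.90-quantile p = 6.45e-05 over 200 gene-subset rounds
```

The QC line shows the three gates removing exactly the planted 5 % / 3 % /
2 % nuisance cells; the DE block recovers all 50 planted log2FC = 2 tumor
genes with no false calls and unanimous leave-one-out support; the
survival block shows the planted quartile hazard (HR 2) detected by
log-rank, surviving age/stage adjustment, and stable under gene-subset
resampling. Scripts 03–07 cover markers/signatures, composition, the
expression-distance MDS and the ligand–receptor screen (the planted
RANKL→RANK and CCL18→CCR8 axes surface in their planted sender/receiver
types).

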