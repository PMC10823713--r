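---
title: "Comparative single-cell statistics in nichecompare: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative single-cell statistics in nichecompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery behind each pipeline
stage, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the design decisions that
were genuinely open. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## Normalization convention

Wherever a function needs "normalized expression" — signature scores,
ligand–receptor averages, pseudobulk profiles — it uses one fixed
convention: per-cell library-size scaling to a total of 10,000 followed by
`log(1 + x)` (`normalize_counts()`). This is the dominant convention for
UMI data; any per-cell-size normalization would serve, but fixing one
package-wide keeps every score comparable across modules. Gene identity
is by symbol, case-sensitive; signature or ligand–receptor genes absent
from the matrix are dropped with a logged count rather than imputed.

## Quality-control gating

`apply_qc()` retains a cell iff total UMI ≥ `min_umi` (700) **and**
mitochondrial fraction ≤ `max_mito` (0.20) **and** doublet score ≤
`max_doublet` (0.40). The removal rules are strict inequalities — a cell
sitting exactly on a threshold passes. Doublet scores are consumed, not
computed (they come from an upstream scrublet-style tool). When the
metadata lacks a mitochondrial fraction it is computed as the count share
of genes whose symbol starts with `MT-` (human convention); there is no
universally agreed mitochondrial gene set, so the metadata value wins
when present. For reporting, a cell failing several rules is attributed
to the first failing rule in the fixed order UMI → mito → doublet; the
retention decision itself is the conjunction, so attribution order never
changes which cells survive.

## Marker detection and the p-derived Z

`find_markers()` runs a two-sided Wilcoxon rank-sum test per gene and
cluster, one-vs-rest, on normalized expression (normal approximation with
tie correction and continuity correction — with hundreds of cells the
exact test is indistinguishable and unaffordable). The reported effect
measure is the *p-value-determined Z score*

$$ z = \operatorname{sign}(\bar x_{in} - \bar x_{out})\,\Phi^{-1}(1 - p/2), $$

i.e. the standard-normal quantile the p-value corresponds to, signed by
the direction of the mean difference. The probit transform is the only
natural map from a two-sided p to a Z; it is fixed here and capped at
|z| ≤ 37 because smaller p-values underflow double precision and would
otherwise produce infinities. A marker passes when z strictly exceeds
`marker_z = 3`; z = 3.0 exactly fails. BH correction is applied across
genes within each cluster (one testing family per cluster); clusters with
fewer than 3 cells are skipped.

## Signature scoring

A cell's signature score is the unweighted mean of its normalized
expression over the present signature genes; a sample's score is the
arithmetic mean over its (optionally cell-type-restricted) cells.
Condition comparisons are two-sided Wilcoxon tests on *sample* scores —
cells within a sample are not independent, so testing at cell level would
badly overstate significance — with BH across the condition pairs tested
in one call. Conditions contributing fewer than 2 qualifying samples are
skipped with a warning.

## Compositional analysis

**Cluster-based** (`composition_test()`): cell-type fractions are
computed per sample *within the major cell population* (T subsets over
all T-lineage cells, not over the whole sample), because whole-sample
denominators confound every subtype with shifts in unrelated
compartments. Samples contributing fewer than `min_cells_composition =
50` cells of a major population are excluded from that population's
tests so that a handful of cells cannot produce extreme fractions.
Two-sided Wilcoxon on fractions, BH across cell types within each
condition pair. Pairs left with fewer than 2 samples on either side are
reported untested rather than dropped silently.

**Cluster-free** (`density_maps()` / `density_difference()`): each
sample's cells are kernel-density-estimated on a shared grid (default
`grid = 400` bins per axis) covering the global embedding bounding box
plus 2 % padding; the bandwidth is the per-sample, per-axis
normal-reference rule (no bandwidth is canonical here; the normal
reference is the common default and the per-bin test below is rank-based,
so moderate bandwidth changes move power, not validity). Each sample map
is renormalized to sum to 1 so cell counts cancel; a condition map is the
mean over its samples. The per-bin difference statistic is the
standardized (tie-corrected, no continuity correction) Wilcoxon rank-sum
statistic comparing per-sample densities between conditions, signed so
positive means enrichment in the first condition; bins where all samples
tie (empty space) get 0. No significance threshold is imposed on the map
— standardized statistics are exposed and thresholds are a display
choice. The whole pipeline is invariant to affine rescaling of the
embedding because the grid and bandwidths follow the data.

## Expression distance

`pseudobulk_profiles()` sums raw counts per (sample, subpopulation),
drops pairs under 10 cells, then normalizes and logs the sums.
`expression_distance()` computes, for each sample pair and each
subpopulation present in both, the correlation distance
$d_s = 1 - \rho(x_{i,s}, x_{j,s})$ over the 2,000 most variable genes
across pseudobulks (restricting to variable genes removes the flat bulk
of the transcriptome whose noise dilutes $\rho$; 2,000 matches standard
HVG practice and is configurable). The overall distance is
$D_{ij} = \sum_s w_s d_s$ with $w_s$ proportional to the mean of the two
samples' subpopulation proportions, renormalized to sum to 1 over the
shared subpopulations. Mean-proportion weighting was chosen over
min-proportion weighting because the latter is discontinuous as a
subpopulation vanishes from one sample. Renormalization over shared
subpopulations is what makes $D \in [0, 2]$ and makes samples with
different subpopulation coverage comparable. Projection uses classical
(Torgerson) MDS, which reproduces Euclidean-embeddable distance matrices
exactly; coordinates are centered and defined up to rotation/sign, so
downstream comparisons should use embedded distances, never raw axes.

## Pseudobulk differential expression

`aggregate_pseudobulk()` sums counts over each sample's cells of the
target type, excluding samples under `de_min_cells = 10` cells and
downsampling samples above `de_max_cells = 320` (seeded, uniform without
replacement) so one deeply sampled tumor cannot dominate.
`nb_wald_test()` then fits, per gene, a negative-binomial GLM with a
group indicator and log size-factor offsets:

* size factors by median-of-ratios over genes positive in all samples,
  falling back to library-size ratios when fewer than 10 such genes
  exist (small pseudobulk panels);
* gene-wise dispersion by method of moments on normalized counts, using
  the pooled within-group variance (so a true fold change does not
  masquerade as overdispersion), floored at 1e-8;
* a Wald test on the group coefficient (log2FC / SE). Because the design
  is a two-group contrast, the IRLS normal equations decouple into two
  weighted group means and the whole gene panel is fit with vectorized
  matrix operations.

Genes with all-zero counts are untested; genes with mean normalized
count below `de_indep_filter_min = 1` are kept in the output but
excluded from the BH family, mirroring the intent of independent
filtering. No dispersion or fold-change shrinkage is applied — with
per-sample pseudobulks and ≥ 2 samples per group the moment estimator is
adequate, and the validation targets are calibration and recovery, not
equality with any particular reference implementation. Significance is
`padj < 0.05` and `|log2FC| > 1.5`.

`loo_resampled_de()` wraps this in `de_n_resamplings = 100` rounds, each
removing one uniformly chosen sample, re-aggregating (re-drawing the
downsampling) and re-testing with BH within the round. Reported p,
adjusted p and log2FC are medians across rounds — the median is robust to
the occasional unstable round and needs no distributional assumption;
the per-gene *support* (fraction of rounds significant) is the robustness
measure. Rounds that leave a group with fewer than 2 usable samples are
skipped; fewer than half the rounds succeeding is an error.

## Ligand–receptor screen

`lr_score()` considers every ordered cell-type pair (A, B) (including
A = B: autocrine signalling is real) and scores a ligand–receptor pair as
the product of the ligand's mean normalized expression in A and the
receptor's in B, but only when the ligand is detected in at least
`lr_expr_ratio = 10 %` of A's cells and the receptor likewise in B —
pairs failing the gate are absent, not scored zero, because a zero score
would survive into rankings. `lr_permutation_test()` builds the null by
shuffling all cells' cluster labels jointly, one shuffle per round reused
for every candidate (`lr_n_perm = 1000` rounds); per-pair independent
shuffles would cost a thousandfold more and are equivalent under
exchangeability. The p-value is the add-one estimator
$p = (1 + \#\{s_{perm} \ge s_{obs}\})/(B+1)$, which can never be 0 and is
a valid p-value at finite B. `lr_z_screen()` finally intersects the
permutation filter (p ≤ 0.05) with a differential-expression screen on
the same clustering: ligand marker Z strictly above 4 in the sender type
and receptor Z strictly above 0 in the receiver. The two filters answer
different questions — the permutation test asks "is this channel stronger
than random cell-type pairings", the Z screen asks "are these genes
actually characteristic of these cell types" — and the screen is applied
as a conjunction; genes missing from the marker table count as Z = 0 and
therefore fail. Multi-subunit receptor complexes are out of scope: rows
are single-gene pairs.

## Survival analysis

`stratify_by_signature()` scores each patient as the mean bulk expression
of the present signature genes and labels the top `floor(0.25 n)` high
and bottom `floor(0.25 n)` low, excluding the middle; boundary ties break
by stable patient-id order (documented so results are reproducible across
platforms). `logrank_km()` is the standard two-sided log-rank test with
product-limit curves; `cox_adjusted()` adds age and one-hot stage (first
sorted level as reference) and reports the Wald p for the high-vs-low
term, flagging non-convergence instead of raising.
`bootstrap_stability()` repeats stratification + log-rank
`surv_n_boot = 200` times on random subsets of the signature (default
80 % of genes, without replacement, at least 2 — the subset size is not
prescribed anywhere authoritative; 80 % perturbs the set enough to expose
single-gene dependence while keeping the score recognizable) and reports
the `surv_report_q = 0.90` empirical quantile of the round p-values with
type-7 interpolation (R's default, fixed for cross-language
reproducibility). Each round re-stratifies, since the score changes with
the subset. The quantile level is a config knob: 0.90 is the default;
0.95 gives a stricter "reproducibility" reading.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a multi-sample case-control
single-cell study: conditions with fixed sample counts (defaults mirror a
bone-metastasis design: 9 BoneMet, 4 Involved, 4 Distal, 12 Healthy, 9
Benign, 14 Primary, 9 AdjNormal), per-sample compositions drawn from a
condition-specific Dirichlet (concentration 50 ≈ 50 % coefficient of
variation for a 7 % subpopulation — compositional noise of the order seen
across human biopsies), counts drawn gene-wise NB with variance
$\mu + \mu^2/\theta$ ($\theta = 10$) around per-type mean profiles scaled
to a target library size (2,000 UMI for a unit-size cell, log-normal cell
size factors), and a synthetic embedding of Gaussian blobs per cell type.
Planted effects — composition multipliers, 8× markers, a 2× signature in
one condition/type, log2FC = 2 DE genes in one type between two
conditions, 5× ligand/receptor elevations — are recorded in a truth
record, which is the only source downstream validation reads.

Two deliberate realism constraints: planted genes are assigned the
cohort's average expression level (so effects are observable without any
planted gene dominating a library), and each cell type's mean profile is
renormalized to the target library size (marker elevation redistributes
the transcriptome rather than inflating the cell's total — real cell
types do not have 8× larger libraries because they express markers).
QC-failure cells are injected with known labels: low-UMI cells by
binomial thinning of their counts to below 700 (so recorded totals stay
consistent with the matrix), high-mito and high-doublet cells by flag
values beyond the thresholds.

What the generator does **not** emulate: batch effects, ambient RNA,
realistic doublet transcriptomes (scores are planted directly), UMAP
geometry (blobs stand in for a real embedding), gene–gene correlation
beyond the planted programs, and zero-inflation beyond what NB sampling
produces. Passing tests therefore demonstrate that the statistics recover
known effects under clean, well-specified noise — not that they are
robust to every artifact of real data.

`simulate_survival_cohort()` drives both signature-gene expression
(loading 1, residual sd 0.5) and hazard from one latent activity:
patients in the top activity quartile get `hazard_ratio` times the bottom
quartile's exponential event rate (middle half at the geometric mean),
censoring is independent exponential calibrated to the requested
fraction, and age/stage can be tied to activity (`age_confounding`,
`stage_confounding`) and to hazard (`age_hazard`) to create genuine
confounding.

## Problem sizes and numerical choices

The test suite and acceptance script run simulations at reduced but
faithful scale — e.g. 2,000-gene, 8 + 8-sample pseudobulk DE panels;
9 vs 7-sample composition cohorts of 300–500 cells per sample; 1,000
permutations for ligand–receptor nulls; 200 replicate cohorts for
calibration checks; 20–50 seeds for power estimates — sizes chosen so the
whole validation completes in minutes on one CPU while keeping every
stated gate (10/320 cells, 50 cells, 10 %, quartiles) binding.
Tie-breaking, quantile interpolation (type 7), Z capping (37), the
add-one permutation estimator, dispersion flooring (1e-8) and the KDE
bandwidth fallback for degenerate samples are all fixed and documented
above so that identical seeds give byte-identical outputs.

## Known limitations

* The log-rank power of a quartile contrast at n = 200 with 30 %
  censoring and a hazard ratio of 2 is intrinsically about 0.8 (two
  50-patient strata, ~70 events); the acceptance suite states this
  scenario and records the measured rate honestly rather than inflating
  the planted effect.
* The NB Wald test without shrinkage is anti-conservative for very small
  groups (2–3 samples a side) and genes with near-zero counts in one
  group get large, noisy fold-change estimates with correspondingly wide
  standard errors rather than being clamped.
* The cluster-free density difference tests each bin marginally; no
  spatial multiplicity control is attempted, and the map should be read
  as descriptive.
* Permutation p-values share one shuffle per round across candidates;
  p-values are marginally valid but correlated across candidates, so
  counting rejections over many candidates on one cohort has higher
  variance than the binomial count suggests.
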