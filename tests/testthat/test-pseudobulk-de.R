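test_that("aggregation sums counts, gates at 10 cells, downsamples above 320", {
  set.seed(1)
  n_cells <- c(S1 = 9, S2 = 400, S3 = 50)
  cm <- data.frame(
    barcode = sprintf("c%04d", seq_len(sum(n_cells))),
    sample_id = rep(names(n_cells), n_cells),
    cluster = "T", stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(
    matrix(1, nrow = 2, ncol = sum(n_cells),
           dimnames = list(c("g1", "g2"), cm$barcode)), sparse = TRUE)
  agg <- aggregate_pseudobulk(counts, cm, "T", seed = 3)
  expect_false("S1" %in% colnames(agg$pseudobulk))     # 9 < 10 cells
  expect_true(agg$design$excluded[agg$design$sample_id == "S1"])
  expect_equal(unname(agg$pseudobulk["g1", "S2"]), 320)  # downsampled
  expect_equal(unname(agg$pseudobulk["g1", "S3"]), 50)
  # two cells with counts [1,2] and [3,4] sum to [4,6]
  m2 <- Matrix::Matrix(matrix(c(1, 2, 3, 4), nrow = 2,
                              dimnames = list(c("g1", "g2"), c("a", "b"))),
                       sparse = TRUE)
  cm2 <- data.frame(barcode = c("a", "b"), sample_id = "S",
                    cluster = "T", stringsAsFactors = FALSE)
  agg2 <- aggregate_pseudobulk(m2, cm2, "T",
                               nc_config(de_min_cells = 1))
  expect_equal(unname(agg2$pseudobulk[, "S"]), c(4, 6))
  # downsampling is reproducible under the same seed
  agg3 <- aggregate_pseudobulk(counts, cm, "T", seed = 3)
  expect_identical(agg$pseudobulk, agg3$pseudobulk)
})

test_that("NB Wald test: null self-comparison, zero genes, integer guard", {
  sim <- simulate_nb_pseudobulk(n_genes = 300, n_a = 4, n_b = 4, n_de = 0,
                                seed = 2)
  pb <- cbind(sim$counts_a, sim$counts_b)
  # group A duplicated as group B: no fold changes, nothing significant
  res <- nb_wald_test(pb[, 1:4], pb[, 1:4])
  expect_true(all(abs(res$log2fc[res$tested]) < 0.1))
  expect_false(any(res$significant))
  # all-zero gene is untested and outside the BH family
  pb0 <- rbind(pb, zero = 0L)
  r0 <- nb_wald_test(pb0[, 1:4], pb0[, 5:8])
  expect_false(r0$tested[r0$gene == "zero"])
  expect_true(is.na(r0$padj[r0$gene == "zero"]))
  expect_error(nb_wald_test(pb[, 1:4] + 0.5, pb[, 5:8]), "integer")
})

test_that("label swap negates log2FC and preserves p", {
  sim <- simulate_nb_pseudobulk(n_genes = 200, n_de = 20, seed = 3)
  r1 <- nb_wald_test(sim$counts_a, sim$counts_b)
  r2 <- nb_wald_test(sim$counts_b, sim$counts_a)
  ok <- r1$tested
  expect_equal(r1$log2fc[ok], -r2$log2fc[ok], tolerance = 1e-6)
  expect_equal(r1$p[ok], r2$p[ok], tolerance = 1e-8)
})

test_that("planted fold changes are recovered and agree with an exact NB LRT", {
  sim <- simulate_nb_pseudobulk(n_genes = 400, n_a = 8, n_b = 8,
                                theta = 10, n_de = 40, lfc = 2, seed = 9)
  res <- nb_wald_test(sim$counts_a, sim$counts_b)
  sig <- res$gene[res$significant]
  expect_gte(mean(sim$truth$de_genes %in% sig), 0.8)
  if (length(sig) > 0) {
    expect_lte(mean(!sig %in% sim$truth$de_genes), 0.10)
  }
  # oracle cross-check: every discovery's direction matches the exact
  # two-sample NB likelihood-ratio fit on the same counts
  pb <- cbind(sim$counts_a, sim$counts_b)
  sf <- nichecompare:::size_factors(pb)
  for (g in head(sig, 25)) {
    o <- nb_lrt_oracle(sim$counts_a[g, ], sim$counts_b[g, ],
                       sf[1:8], sf[9:16], theta = 10)
    expect_equal(sign(res$log2fc[res$gene == g]), o$direction)
    expect_lt(o$p, 0.05)
  }
})

test_that("LOO resampling: support for planted genes, consistency at 1 round", {
  sim <- simulate_cohort(mini_cohort_spec(
    seed = 5, conditions = c(BoneMet = 4, Primary = 4),
    cells = c(150, 200), n_genes = 120,
    de = list(n_genes = 15, lfc = 2, cell_type = "A",
              condition_a = "BoneMet", condition_b = "Primary")))
  ga <- sim$sample_meta$sample_id[sim$sample_meta$condition == "BoneMet"]
  gb <- sim$sample_meta$sample_id[sim$sample_meta$condition == "Primary"]
  cfg <- nc_config(de_n_resamplings = 20, seed = 2)
  res <- loo_resampled_de(sim$counts, sim$cell_meta, "A", ga, gb, cfg)
  planted <- sim$truth$de$genes
  expect_gte(mean(res$support[res$gene %in% planted]), 0.9)
  expect_lte(mean(res$significant[!res$gene %in% planted]), 0.05)

  # a single round with a fixed removed sample equals the direct reduced call
  cfg1 <- nc_config(de_n_resamplings = 1, seed = 2)
  r1 <- loo_resampled_de(sim$counts, sim$cell_meta, "A", ga, gb, cfg1,
                         leave_out = gb[1])
  agg <- aggregate_pseudobulk(sim$counts, sim$cell_meta, "A", cfg1,
                              seed = nichecompare:::sub_seed(2, 1),
                              samples = c(ga, gb[-1]))
  direct <- nb_wald_test(agg$pseudobulk[, ga, drop = FALSE],
                         agg$pseudobulk[, gb[-1], drop = FALSE], cfg1)
  expect_equal(r1$p, direct$p)
  expect_equal(r1$log2fc, direct$log2fc)
})
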