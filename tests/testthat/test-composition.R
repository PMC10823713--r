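make_comp_meta <- function(counts_by_sample, conditions) {
  # counts_by_sample: named list sample -> named vector cell_type -> n
  cm <- do.call(rbind, lapply(names(counts_by_sample), function(s) {
    v <- counts_by_sample[[s]]
    data.frame(sample_id = s, cluster = rep(names(v), v),
               stringsAsFactors = FALSE)
  }))
  cm$barcode <- sprintf("c%05d", seq_len(nrow(cm)))
  sm <- data.frame(sample_id = names(counts_by_sample),
                   patient_id = paste0("P", seq_along(counts_by_sample)),
                   condition = conditions, stringsAsFactors = FALSE)
  list(cm = cm, sm = sm)
}

test_that("fractions are computed within major populations with the 50-cell gate", {
  fx <- make_comp_meta(
    list(S1 = c(A1 = 50, A2 = 50, B1 = 100),
         S2 = c(A1 = 30, A2 = 19, B1 = 100),   # 49 T-lineage cells: gated out
         S3 = c(A1 = 20, A2 = 80, B1 = 100),
         S4 = c(A1 = 60, A2 = 40, B1 = 100)),
    conditions = c("BoneMet", "BoneMet", "Benign", "Benign"))
  map <- c(A1 = "T", A2 = "T", B1 = "Myeloid")
  res <- composition_test(fx$cm, fx$sm, map,
                          condition_pairs = list(c("BoneMet", "Benign")))
  fr <- attr(res, "sample_fractions")
  expect_equal(fr["S1", "A1"], 0.5)
  expect_true(is.na(fr["S2", "A1"]))      # 49 < 50 gate
  expect_equal(fr["S2", "B1"], 1)         # other population unaffected
  row <- res[res$cell_type == "A1", ]
  expect_equal(row$n_a, 1)                 # only S1 qualifies for BoneMet
  expect_false(row$tested)                 # <2 samples on one side
  expect_true(is.na(row$p))
})

test_that("composition fractions are invariant to duplicating a sample's cells", {
  fx <- make_comp_meta(
    list(S1 = c(A = 60, B = 40), S2 = c(A = 55, B = 45),
         S3 = c(A = 30, B = 70), S4 = c(A = 25, B = 75)),
    conditions = c("BoneMet", "BoneMet", "Benign", "Benign"))
  res1 <- composition_test(fx$cm, fx$sm, NULL,
                           condition_pairs = list(c("BoneMet", "Benign")))
  dup <- fx$cm[fx$cm$sample_id == "S1", ]
  dup$barcode <- paste0(dup$barcode, "-dup")
  res2 <- composition_test(rbind(fx$cm, dup), fx$sm, NULL,
                           condition_pairs = list(c("BoneMet", "Benign")))
  expect_equal(attr(res1, "sample_fractions"),
               attr(res2, "sample_fractions"))
  expect_equal(res1$p, res2$p)
})

test_that("planted proportion shifts are recovered; BH keeps padj >= p", {
  sim <- simulate_cohort(mini_cohort_spec(
    seed = 12, conditions = c(BoneMet = 8, Benign = 8),
    cells = c(300, 400),
    multipliers = list(BoneMet = c(A = 3))))
  res <- composition_test(sim$cell_meta, sim$sample_meta, NULL,
                          condition_pairs = list(c("BoneMet", "Benign")))
  row <- res[res$cell_type == "A", ]
  expect_gt(row$frac_a_median, row$frac_b_median)
  expect_lt(row$padj, 0.05)
  expect_true(all(res$padj >= res$p - 1e-15, na.rm = TRUE))
})

test_that("density maps normalize per sample and localize point masses", {
  cm <- data.frame(
    barcode = sprintf("c%03d", 1:40),
    sample_id = rep(c("S1", "S2"), each = 20),
    embed_x = c(rep(2, 20), rnorm(20, -2, 0.1)),
    embed_y = c(rep(1, 20), rnorm(20, -1, 0.1)),
    stringsAsFactors = FALSE)
  sm <- data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
                   condition = c("BoneMet", "Benign"),
                   stringsAsFactors = FALSE)
  maps <- density_maps(cm, sm, config = nc_config(grid = 50))
  for (z in maps$sample_maps) expect_equal(sum(z), 1, tolerance = 1e-9)
  # all of S1's cells sit at (2, 1): the argmax bin must be that point's bin
  z1 <- maps$sample_maps$S1
  am <- which(z1 == max(z1), arr.ind = TRUE)
  bin_w_x <- diff(maps$grid_x[1:2]); bin_w_y <- diff(maps$grid_y[1:2])
  expect_lt(abs(maps$grid_x[am[1, 1]] - 2), bin_w_x)
  expect_lt(abs(maps$grid_y[am[1, 2]] - 1), bin_w_y)
})

test_that("density pipeline is invariant under affine coordinate rescaling", {
  sim <- simulate_cohort(mini_cohort_spec(seed = 4, cells = c(100, 150)))
  cfg <- nc_config(grid = 40)
  m1 <- density_maps(sim$cell_meta, sim$sample_meta, config = cfg)
  cm2 <- sim$cell_meta
  cm2$embed_x <- 3 * cm2$embed_x + 7
  cm2$embed_y <- 0.5 * cm2$embed_y - 2
  m2 <- density_maps(cm2, sim$sample_meta, config = cfg)
  for (s in names(m1$sample_maps)) {
    expect_equal(m1$sample_maps[[s]], m2$sample_maps[[s]], tolerance = 1e-8)
  }
})

test_that("density difference is antisymmetric and flags planted enrichment", {
  sim <- simulate_cohort(mini_cohort_spec(
    seed = 21, conditions = c(BoneMet = 5, Benign = 5),
    cells = c(200, 250), multipliers = list(BoneMet = c(A = 4))))
  cfg <- nc_config(grid = 60)
  maps <- density_maps(sim$cell_meta, sim$sample_meta, config = cfg)
  d_ab <- density_difference(maps, "BoneMet", "Benign")
  d_ba <- density_difference(maps, "Benign", "BoneMet")
  expect_equal(d_ab, -d_ba)
  # bins near the enriched type's blob center lean positive
  ctr <- sim$truth$embedding_centers["A", ]
  ix <- which(abs(maps$grid_x - ctr[1]) < 1.5)
  iy <- which(abs(maps$grid_y - ctr[2]) < 1.5)
  expect_gt(mean(d_ab[ix, iy]), mean(d_ab))
  # identical sample sets on both sides: all-zero statistic
  same <- density_difference(maps, "BoneMet", "BoneMet")
  expect_true(all(same == 0))
})
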