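tiny_counts <- function() {
  m <- Matrix::Matrix(matrix(c(1, 0,   # cell1 (S1, A)
                               3, 2,   # cell2 (S1, A)
                               5, 5,   # cell3 (S2, A)
                               2, 8),  # cell4 (S2, B)
                             nrow = 2,
                             dimnames = list(c("g1", "g2"),
                                             paste0("c", 1:4))),
                      sparse = TRUE)
  cm <- data.frame(barcode = paste0("c", 1:4),
                   sample_id = c("S1", "S1", "S2", "S2"),
                   cluster = c("A", "A", "A", "B"),
                   stringsAsFactors = FALSE)
  list(counts = m, cm = cm)
}

test_that("pseudobulk profiles sum counts, gate on cells, ignore cell order", {
  fx <- tiny_counts()
  pb <- pseudobulk_profiles(fx$counts, fx$cm, min_cells = 1)
  # S1/A sums [4, 2] before normalization -> log1p(1e4 * c(4,2)/6)
  expect_equal(unname(pb$profiles[, "S1|A"]),
               log1p(1e4 * c(4, 2) / 6))
  expect_equal(pb$pairs$proportion[pb$pairs$sample_id == "S1"], 1)
  # permuting cell order leaves profiles unchanged
  perm <- c(2, 1, 4, 3)
  pb2 <- pseudobulk_profiles(fx$counts[, perm], fx$cm[perm, ], min_cells = 1)
  expect_equal(pb$profiles[, colnames(pb$profiles)],
               pb2$profiles[, colnames(pb$profiles)])
  # pairs under the gate are dropped
  pb10 <- pseudobulk_profiles(fx$counts, fx$cm, min_cells = 10)
  expect_equal(ncol(pb10$profiles), 0)
})

test_that("distances: identical samples at 0, anticorrelated at 2, weights sum to 1", {
  profiles <- cbind("S1|A" = c(1, 2, 3, 5), "S2|A" = c(1, 2, 3, 5),
                    "S3|A" = c(5, 4, 3, 1))
  pb <- structure(list(
    profiles = profiles,
    pairs = data.frame(sample_id = c("S1", "S2", "S3"),
                       subpopulation = "A", n_cells = 50, proportion = 1,
                       stringsAsFactors = FALSE)),
    class = "nc_pseudobulk")
  ed <- expression_distance(pb, n_top_genes = 4)
  expect_equal(ed$D["S1", "S2"], 0)
  expect_equal(ed$D["S1", "S1"], 0)
  expect_equal(ed$D, t(ed$D))
  # S3 is a perfect anticorrelation of S1 in the only shared subpopulation
  expect_equal(ed$D["S1", "S3"], 2, tolerance = 1e-12)
  expect_equal(ed$detail$weight, rep(1, 3))  # single shared subpopulation
  expect_true(all(ed$D >= 0 & ed$D <= 2))
})

test_that("per-pair weights renormalize over shared subpopulations", {
  sim <- simulate_cohort(mini_cohort_spec(seed = 3, cells = c(200, 250)))
  pb <- pseudobulk_profiles(sim$counts, sim$cell_meta, min_cells = 10)
  ed <- expression_distance(pb, n_top_genes = 50)
  agg <- tapply(ed$detail$weight,
                paste(ed$detail$sample_a, ed$detail$sample_b), sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("classical MDS reproduces Euclidean-embeddable distances", {
  set.seed(5)
  xy <- cbind(rnorm(7), rnorm(7))
  rownames(xy) <- paste0("S", 1:7)
  D <- euclid_dist(xy)
  proj <- mds_project(D)
  expect_equal(euclid_dist(proj), D, tolerance = 1e-6,
               ignore_attr = TRUE)
  # equilateral triple embeds with all pairwise distances equal
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(paste0("T", 1:3), paste0("T", 1:3))
  ptri <- mds_project(tri, k = 2)
  dd <- euclid_dist(ptri)[upper.tri(diag(3))]
  expect_true(all(abs(dd - dd[1]) < 1e-8))
  # duplicated sample lands on its original
  D2 <- rbind(cbind(D, D[, 7]), c(D[7, ], 0))
  rownames(D2)[8] <- colnames(D2)[8] <- "S7dup"
  p2 <- mds_project(D2)
  expect_lt(sqrt(sum((p2["S7", ] - p2["S7dup", ])^2)), 1e-8)
  expect_error(mds_project(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("planted transcriptional shift separates conditions in distance", {
  ok <- vapply(1:10, function(s) {
    sim <- simulate_cohort(mini_cohort_spec(
      seed = s, conditions = c(BoneMet = 5, Primary = 5),
      cells = c(250, 300), n_genes = 200,
      de = list(n_genes = 40, lfc = 2, cell_type = "A",
                condition_a = "BoneMet", condition_b = "Primary")))
    pb <- pseudobulk_profiles(sim$counts, sim$cell_meta)
    ed <- expression_distance(pb)
    cond <- sim$sample_meta$condition[match(rownames(ed$D),
                                            sim$sample_meta$sample_id)]
    between <- mean(ed$D[cond == "BoneMet", cond == "Primary"])
    wi_a <- ed$D[cond == "BoneMet", cond == "BoneMet"]
    wi_b <- ed$D[cond == "Primary", cond == "Primary"]
    within <- mean(c(wi_a[upper.tri(wi_a)], wi_b[upper.tri(wi_b)]))
    between > within
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
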