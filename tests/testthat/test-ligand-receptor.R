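lr_fixture <- function(seed = 5) {
  spec <- mini_cohort_spec(
    seed = seed, conditions = c(BoneMet = 4), cells = c(300, 400),
    n_genes = 150, cell_types = c(A = 0.35, B = 0.35, C = 0.3),
    lr = data.frame(ligand = "LIG1", receptor = "REC1",
                    type_a = "A", type_b = "B", fold = 5))
  sim <- simulate_cohort(spec)
  list(sim = sim, nr = normalize_counts(sim$counts))
}

test_that("LR scores are products of means and the 10% gate is enforced", {
  nr <- Matrix::Matrix(matrix(c(
    2, 2, 2, 2, 2, 2, 2, 2, 2, 2,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0,  3, 3, 3, 3, 3, 3, 3, 3, 3, 3,
    1, 0, 0, 0, 0, 0, 0, 0, 0, 0,  0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("L", "R", "RARE"), sprintf("c%02d", 1:20))),
    sparse = TRUE)
  cl <- rep(c("A", "B"), each = 10)
  lrt <- data.frame(ligand = c("L", "RARE", "GONE"),
                    receptor = c("R", "R", "R"))
  expect_message(cand <- lr_score(nr, cl, lrt), "absent from matrix")
  ab <- cand[cand$ligand == "L" & cand$cell_type_a == "A" &
               cand$cell_type_b == "B", ]
  expect_equal(ab$score, 6)  # mean 2 x mean 3
  expect_equal(ab$expr_ratio_ligand, 1)
  # RARE is detected in 10% of A: exactly at the gate, retained (>= rule)
  expect_true(any(cand$ligand == "RARE" & cand$cell_type_a == "A"))
  # L is expressed nowhere in B: no candidate with B as sender, not score 0
  expect_false(any(cand$ligand == "L" & cand$cell_type_a == "B"))
  expect_false(any(cand$ligand == "GONE"))
})

test_that("permutation p uses add-one and planted couplings are detected", {
  fx <- lr_fixture(seed = 5)
  lrt <- data.frame(ligand = "LIG1", receptor = "REC1")
  cand <- lr_score(fx$nr, fx$sim$cell_meta$cluster, lrt)
  cfg <- nc_config(lr_n_perm = 200)
  res <- lr_permutation_test(fx$nr, fx$sim$cell_meta$cluster, cand, cfg)
  hit <- res[res$cell_type_a == "A" & res$cell_type_b == "B", ]
  # planted 5x/5x coupling beats every shuffle: p at the add-one floor
  expect_equal(hit$p, 1 / 201)
  expect_true(hit$passes_perm)
  expect_true(all(res$p >= 1 / 201 & res$p <= 1))
  # determinism under the config seed
  res2 <- lr_permutation_test(fx$nr, fx$sim$cell_meta$cluster, cand, cfg)
  expect_identical(res, res2)
})

test_that("scores are equivariant under expression scaling and cell order", {
  fx <- lr_fixture(seed = 6)
  lrt <- data.frame(ligand = "LIG1", receptor = "REC1")
  cand <- lr_score(fx$nr, fx$sim$cell_meta$cluster, lrt)
  cand_scaled <- lr_score(fx$nr * 2, fx$sim$cell_meta$cluster, lrt)
  expect_equal(cand_scaled$score, 4 * cand$score)
  perm <- sample(ncol(fx$nr))
  cand_perm <- lr_score(fx$nr[, perm], fx$sim$cell_meta$cluster[perm], lrt)
  ord <- order(cand$cell_type_a, cand$cell_type_b)
  ord2 <- order(cand_perm$cell_type_a, cand_perm$cell_type_b)
  expect_equal(cand$score[ord], cand_perm$score[ord2])
})

test_that("the Z screen is a strict conjunction with missing genes as Z=0", {
  base <- data.frame(ligand = "L", receptor = "R",
                     cell_type_a = "A", cell_type_b = "B",
                     p = 0.01, passes_perm = TRUE,
                     stringsAsFactors = FALSE)
  mk <- data.frame(gene = c("L", "R", "L", "R"),
                   cluster = c("A", "B", "B", "A"),
                   z = c(4.0, 0.0, 1, 1), stringsAsFactors = FALSE)
  # ligand z exactly 4 fails; receptor z exactly 0 fails
  r <- lr_z_screen(base, mk)
  expect_false(r$passes_z)
  mk$z <- c(6, 1, 1, 1)
  r2 <- lr_z_screen(base, mk)
  expect_true(r2$passes_z)
  expect_true(r2$reported)
  expect_equal(as.integer(attr(r2, "pair_counts")["A", "B"]), 1)
  # unscreened gene -> Z 0 -> fails
  expect_message(r3 <- lr_z_screen(base, mk[mk$gene != "R", ]), "missing")
  expect_false(r3$passes_z)
})

test_that("tightening any threshold only shrinks the reported set", {
  fx <- lr_fixture(seed = 7)
  lrt <- data.frame(ligand = "LIG1", receptor = "REC1")
  cl <- fx$sim$cell_meta$cluster
  cand <- lr_score(fx$nr, cl, lrt)
  cfg <- nc_config(lr_n_perm = 200)
  perm <- lr_permutation_test(fx$nr, cl, cand, cfg)
  mk <- find_markers(fx$nr, cl, genes = c("LIG1", "REC1"))
  loose <- lr_z_screen(perm, mk, cfg)
  tight_z <- lr_z_screen(perm, mk, nc_config(lr_n_perm = 200,
                                             lr_ligand_z = 10,
                                             lr_receptor_z = 2))
  expect_true(all(which(tight_z$reported) %in% which(loose$reported)))
  cand_tight <- lr_score(fx$nr, cl, lrt,
                         nc_config(lr_expr_ratio = 0.5))
  expect_lte(nrow(cand_tight), nrow(cand))
})
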