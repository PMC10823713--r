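# Small cohort builders and independent oracles shared across test files.

# A compact two-condition cohort with all planted effects switched off
# unless requested. Keeps tests fast; acceptance tests use the sizes the
# validation protocol states.
mini_cohort_spec <- function(seed = 1,
                             conditions = c(BoneMet = 4, Benign = 4),
                             cells = c(150, 250),
                             n_genes = 60,
                             cell_types = c(A = 0.4, B = 0.35, C = 0.25),
                             multipliers = list(),
                             markers_per_type = 2,
                             signature = NULL, de = NULL, lr = NULL,
                             qc = c(0, 0, 0), ...) {
  cohort_spec(conditions = conditions, cells_per_sample = cells,
              n_genes = n_genes, cell_types = cell_types,
              condition_multipliers = multipliers,
              markers_per_type = markers_per_type,
              signature = signature, de = de, lr_couplings = lr,
              qc_low_umi = qc[1], qc_high_mito = qc[2],
              qc_high_doublet = qc[3], seed = seed, ...)
}

# Exact two-sample NB likelihood-ratio oracle for the Wald DE test: known
# dispersion, size-factor offsets, group means fit by ML on a grid-free
# 1-D optimization. Independent of the package's IRLS path.
nb_lrt_oracle <- function(ya, yb, sf_a, sf_b, theta) {
  nll <- function(log_mu, y, sf) {
    -sum(dnbinom(y, mu = exp(log_mu) * sf, size = theta, log = TRUE))
  }
  fit1 <- function(y, sf) {
    optimize(nll, c(-15, 15), y = y, sf = sf)$objective
  }
  ll_sep <- -(fit1(ya, sf_a) + fit1(yb, sf_b))
  ll_com <- -fit1(c(ya, yb), c(sf_a, sf_b))
  lrt <- 2 * (ll_sep - ll_com)
  dir <- sign(mean(ya / sf_a) - mean(yb / sf_b))
  list(p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE), direction = dir)
}

# Euclidean distance matrix of a 2D point set (oracle for classical MDS).
euclid_dist <- function(xy) {
  as.matrix(dist(xy))
}
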