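#' Aggregate per-sample pseudobulk counts for one cell type
#'
#' Sums raw counts over each sample's cells of the target type. Samples
#' with fewer than \code{config$de_min_cells} cells (default 10) are
#' excluded; samples with more than \code{config$de_max_cells} (default
#' 320) are downsampled to the maximum uniformly without replacement
#' (seeded), so no single deep sample dominates its pseudobulk.
#'
#' @param counts Genes x cells raw count matrix.
#' @param cell_meta Cohort cell metadata.
#' @param cell_type Cluster label to aggregate.
#' @param config An [nc_config()] object.
#' @param seed Seed for downsampling (default \code{config$seed}).
#' @param samples Optional restriction to these sample ids.
#' @return A list: \code{pseudobulk} (genes x samples integer matrix) and
#'   \code{design} (data.frame: sample_id, n_cells_total, n_cells_used,
#'   excluded).
#' @export
aggregate_pseudobulk <- function(counts, cell_meta, cell_type,
                                 config = nc_config(), seed = NULL,
                                 samples = NULL) {
  counts <- as_dgc(counts)
  cells <- cell_meta[cell_meta$cluster == cell_type, , drop = FALSE]
  if (!is.null(samples)) {
    cells <- cells[cells$sample_id %in% samples, , drop = FALSE]
  }
  if (nrow(cells) == 0) stop("no cells of type '", cell_type, "'")
  set.seed(seed %||% config$seed)
  split_bc <- split(cells$barcode, cells$sample_id)
  design <- data.frame(sample_id = names(split_bc),
                       n_cells_total = lengths(split_bc),
                       stringsAsFactors = FALSE, row.names = NULL)
  used <- lapply(split_bc, function(bc) {
    if (length(bc) < config$de_min_cells) return(character(0))
    if (length(bc) > config$de_max_cells) {
      bc <- sample(bc, config$de_max_cells)
    }
    bc
  })
  design$n_cells_used <- lengths(used)
  design$excluded <- design$n_cells_used == 0
  kept <- design$sample_id[!design$excluded]
  pb <- vapply(kept, function(s) {
    as.numeric(Matrix::rowSums(counts[, used[[s]], drop = FALSE]))
  }, numeric(nrow(counts)))
  pb <- matrix(pb, nrow = nrow(counts),
               dimnames = list(rownames(counts), kept))
  list(pseudobulk = pb, design = design)
}

# Median-of-ratios size factors (library-size ratio fallback when fewer
# than 10 genes are positive in every sample), normalized to geometric
# mean 1.
size_factors <- function(pb) {
  pos <- rowSums(pb > 0) == ncol(pb)
  if (sum(pos) >= 10) {
    lg <- log(pb[pos, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- exp(apply(lg - geo, 2, median))
  } else {
    lib <- colSums(pb)
    sf <- lib / exp(mean(log(pmax(lib, 1))))
  }
  sf / exp(mean(log(sf)))
}

# Vectorised two-group NB GLM with log link and per-sample offsets.
# For a binary design the IRLS normal equations decouple into two
# weighted group means, so the whole gene set is fit with matrix ops.
# Returns natural-log group coefficients and the Wald SE of their
# difference (1/sum(w_A) + 1/sum(w_B) on the information scale).
nb_fit_two_group <- function(y, sf, grp, alpha, n_iter = 50, tol = 1e-10) {
  idx_a <- which(grp == 1)
  idx_b <- which(grp == 0)
  mu_floor <- 1e-8
  fit_group <- function(yg, sg, alpha) {
    m <- log(pmax(rowSums(yg) / sum(sg), mu_floor))
    for (it in seq_len(n_iter)) {
      mu <- exp(m) %o% sg  # genes x samples
      w <- mu / (1 + alpha * mu)
      z <- m + rowSums(w * (yg - mu) / mu) / rowSums(w)
      delta <- z - m
      m <- pmax(z, log(mu_floor))
      if (max(abs(delta)) < tol) break
    }
    mu <- exp(m) %o% sg
    w <- mu / (1 + alpha * mu)
    list(m = m, winfo = rowSums(w))
  }
  fa <- fit_group(y[, idx_a, drop = FALSE], sf[idx_a], alpha)
  fb <- fit_group(y[, idx_b, drop = FALSE], sf[idx_b], alpha)
  beta <- fa$m - fb$m
  se <- sqrt(1 / fa$winfo + 1 / fb$winfo)
  list(beta = beta, se = se, m_a = fa$m, m_b = fb$m)
}

#' Negative-binomial Wald test on pseudobulk counts
#'
#' Compares two groups of per-sample pseudobulk count vectors gene by gene:
#' size factors by median-of-ratios, gene-wise NB dispersion by method of
#' moments on normalized counts (pooled within-group variance, floored at
#' 1e-8), NB GLM with a group indicator and log size-factor offsets, and a
#' two-sided Wald test on the group coefficient. Genes with all-zero
#' counts are reported untested; genes with mean normalized count below
#' \code{config$de_indep_filter_min} are excluded from the BH family
#' (independent-filtering analogue) and get \code{padj = NA}.
#'
#' @param pb_a,pb_b Genes x samples integer matrices (raw aggregated
#'   counts; same gene order).
#' @param config An [nc_config()] object.
#' @return A data.frame: \code{gene}, \code{base_mean}, \code{log2fc}
#'   (group A relative to B), \code{se} (log2 scale), \code{stat},
#'   \code{p}, \code{padj}, \code{significant}, \code{tested}.
#' @export
nb_wald_test <- function(pb_a, pb_b, config = nc_config()) {
  stopifnot(nrow(pb_a) == nrow(pb_b))
  if (ncol(pb_a) < 2 || ncol(pb_b) < 2) stop("need >= 2 samples per group")
  pb <- cbind(pb_a, pb_b)
  if (any(pb < 0) || any(pb != round(pb))) {
    stop("pseudobulk counts must be non-negative integers (raw counts)")
  }
  grp <- rep(c(1, 0), c(ncol(pb_a), ncol(pb_b)))
  sf <- size_factors(pb)
  q <- sweep(pb, 2, sf, "/")
  base_mean <- rowMeans(q)
  tested <- rowSums(pb) > 0
  # pooled within-group moment estimate of dispersion
  ma <- rowMeans(q[, grp == 1, drop = FALSE])
  mb <- rowMeans(q[, grp == 0, drop = FALSE])
  rss <- rowSums((q[, grp == 1, drop = FALSE] - ma)^2) +
    rowSums((q[, grp == 0, drop = FALSE] - mb)^2)
  v <- rss / (ncol(pb) - 2)
  alpha <- pmax((v - base_mean) / base_mean^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8

  log2fc <- se <- stat <- p <- rep(NA_real_, nrow(pb))
  if (any(tested)) {
    fit <- nb_fit_two_group(pb[tested, , drop = FALSE], sf, grp,
                            alpha[tested])
    log2fc[tested] <- fit$beta / log(2)
    se[tested] <- fit$se / log(2)
    stat[tested] <- fit$beta / fit$se
    p[tested] <- 2 * pnorm(-abs(stat[tested]))
  }
  in_family <- tested & base_mean >= config$de_indep_filter_min
  padj <- rep(NA_real_, nrow(pb))
  padj[in_family] <- p.adjust(p[in_family], "BH")
  res <- data.frame(
    gene = rownames(pb) %||% as.character(seq_len(nrow(pb))),
    base_mean = base_mean, log2fc = log2fc, se = se, stat = stat,
    p = p, padj = padj,
    significant = !is.na(padj) & padj < config$de_padj &
      abs(log2fc) > config$de_lfc,
    tested = tested,
    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Leave-one-out resampled pseudobulk differential expression
#'
#' Runs \code{n_resamplings} rounds (default 100); each round removes one
#' uniformly chosen sample, re-aggregates the pseudobulks (re-drawing any
#' downsampling) and re-runs the NB Wald test with BH correction within
#' the round. Per gene the reported p, adjusted p and log2 fold change are
#' medians across rounds, and the resampling support is the fraction of
#' rounds in which the gene met the significance rule (padj <
#' \code{de_padj} and |log2FC| > \code{de_lfc}).
#'
#' @param counts Genes x cells raw count matrix.
#' @param cell_meta Cohort cell metadata.
#' @param cell_type Cluster label to test.
#' @param group_a,group_b Character vectors of sample ids (>= 3 each, so a
#'   round that removes one still has >= 2).
#' @param config An [nc_config()] object.
#' @param leave_out Optional character vector (length \code{n_resamplings})
#'   fixing the sample removed in each round; default uniform draws.
#' @return A data.frame like [nb_wald_test()] plus \code{support}, with
#'   attribute \code{"n_rounds"} (successful rounds).
#' @export
loo_resampled_de <- function(counts, cell_meta, cell_type,
                             group_a, group_b, config = nc_config(),
                             leave_out = NULL) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  all_samples <- c(group_a, group_b)
  n_rounds <- config$de_n_resamplings
  set.seed(sub_seed(config$seed, 77L))
  drop_seq <- leave_out %||% sample(all_samples, n_rounds, replace = TRUE)
  stopifnot(length(drop_seq) == n_rounds)

  genes <- rownames(counts)
  acc_p <- acc_padj <- acc_lfc <- matrix(NA_real_, length(genes), n_rounds,
                                         dimnames = list(genes, NULL))
  sig_cnt <- integer(length(genes))
  ok_rounds <- 0L
  for (r in seq_len(n_rounds)) {
    keep <- setdiff(all_samples, drop_seq[r])
    ga <- intersect(group_a, keep)
    gb <- intersect(group_b, keep)
    agg <- aggregate_pseudobulk(counts, cell_meta, cell_type, config,
                                seed = sub_seed(config$seed, r),
                                samples = keep)
    pb <- agg$pseudobulk
    ga <- intersect(ga, colnames(pb))
    gb <- intersect(gb, colnames(pb))
    if (length(ga) < 2 || length(gb) < 2) {
      nc_msg("round ", r, " skipped: a group fell below 2 usable samples")
      next
    }
    res <- nb_wald_test(pb[, ga, drop = FALSE], pb[, gb, drop = FALSE],
                        config)
    ok_rounds <- ok_rounds + 1L
    acc_p[, ok_rounds] <- res$p
    acc_padj[, ok_rounds] <- res$padj
    acc_lfc[, ok_rounds] <- res$log2fc
    sig_cnt <- sig_cnt + as.integer(res$significant)
  }
  min_ok <- max(1L, floor(n_rounds / 2))
  if (ok_rounds < min_ok) {
    stop("only ", ok_rounds, " of ", n_rounds, " resampling rounds usable")
  }
  acc_p <- acc_p[, seq_len(ok_rounds), drop = FALSE]
  acc_padj <- acc_padj[, seq_len(ok_rounds), drop = FALSE]
  acc_lfc <- acc_lfc[, seq_len(ok_rounds), drop = FALSE]
  med <- function(m) apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) median(x) else NA_real_
  })
  p_med <- med(acc_p); padj_med <- med(acc_padj); lfc_med <- med(acc_lfc)
  pb_full <- aggregate_pseudobulk(counts, cell_meta, cell_type, config,
                                  seed = sub_seed(config$seed, 0L),
                                  samples = all_samples)$pseudobulk
  res <- data.frame(
    gene = genes,
    base_mean = rowMeans(sweep(pb_full, 2, size_factors(pb_full), "/")),
    log2fc = lfc_med, p = p_med, padj = padj_med,
    support = sig_cnt / ok_rounds,
    significant = !is.na(padj_med) & padj_med < config$de_padj &
      !is.na(lfc_med) & abs(lfc_med) > config$de_lfc,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_rounds") <- ok_rounds
  res
}
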