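#' Specify a synthetic multi-condition single-cell cohort
#'
#' Defines a cohort of samples across disease conditions with cell-type
#' structure and planted, recorded effects: condition-specific composition
#' shifts, cell-type marker genes, a signature elevated in one
#' condition/cell-type, differentially expressed genes between two
#' conditions within one cell type, ligand-receptor couplings between
#' cell-type pairs, and flagged QC-failure cells. The defaults emulate a
#' bone-marrow/bone-metastasis case-control design (9 bone-metastasis, 4
#' involved, 4 distal, 12 healthy, 9 benign marrow samples, plus 14 primary
#' tumors and 9 adjacent-normal samples) with myeloid, lymphoid, stromal
#' and tumor compartments.
#'
#' @param conditions Named integer vector: samples per condition.
#' @param cells_per_sample Length-2 range; per-sample cell counts are drawn
#'   uniformly from it.
#' @param cell_types Named numeric vector of baseline cell-type proportions
#'   (normalized internally).
#' @param condition_multipliers Named list: per condition, a named vector of
#'   proportion multipliers (planted composition shifts); proportions are
#'   renormalized after multiplication.
#' @param dirichlet_conc Dirichlet concentration controlling across-sample
#'   compositional variability (larger = less variable).
#' @param n_genes Number of genes.
#' @param base_mean_shape,base_mean_scale Gamma parameters shaping the
#'   per-gene baseline NB means (skew only; means are rescaled to
#'   \code{target_umi}).
#' @param target_umi Expected total UMI of a unit-size cell; baseline means
#'   are rescaled so their sum equals it.
#' @param nb_theta NB dispersion: variance = mu + mu^2/theta.
#' @param markers_per_type,marker_fold Planted marker genes per cell type
#'   and their fold elevation.
#' @param signature List \code{(n_genes, fold, cell_type, condition)}: genes
#'   elevated \code{fold}-fold in that cell type within that condition
#'   (NULL to disable).
#' @param de List \code{(n_genes, lfc, cell_type, condition_a, condition_b)}:
#'   genes whose expression in \code{cell_type} differs by \code{lfc} (log2)
#'   in \code{condition_a} relative to all other conditions (NULL to
#'   disable).
#' @param lr_couplings Data frame with columns \code{ligand}, \code{receptor},
#'   \code{type_a}, \code{type_b}, \code{fold}: gene symbols to plant as
#'   ligand (elevated in \code{type_a}) and receptor (elevated in
#'   \code{type_b}) (NULL to disable).
#' @param embed_sd Gaussian spread of each cell type's embedding blob.
#' @param qc_low_umi,qc_high_mito,qc_high_doublet Fractions of cells planted
#'   as QC failures of each kind (disjoint).
#' @param size_factor_sd Log-normal sd of per-cell size factors.
#' @param seed Integer seed.
#'
#' @return A list of class \code{nc_cohort_spec}.
#' @export
cohort_spec <- function(conditions = c(Healthy = 12, Benign = 9, Involved = 4,
                                       Distal = 4, BoneMet = 9, Primary = 14,
                                       AdjNormal = 9),
                        cells_per_sample = c(500, 1500),
                        cell_types = c(CTL = 0.18, Treg = 0.05, NK = 0.08,
                                       Bcell = 0.10, Mono = 0.15,
                                       Macro1 = 0.10, Macro2 = 0.07,
                                       MSC1 = 0.06, MSC2 = 0.06,
                                       Tumor = 0.15),
                        condition_multipliers = list(
                          BoneMet = c(Macro2 = 3, MSC2 = 3)
                        ),
                        dirichlet_conc = 50,
                        n_genes = 2000,
                        base_mean_shape = 0.3,
                        base_mean_scale = 10 / 3,
                        target_umi = 2000,
                        nb_theta = 10,
                        markers_per_type = 5,
                        marker_fold = 8,
                        signature = list(n_genes = 10, fold = 2,
                                         cell_type = "CTL",
                                         condition = "BoneMet"),
                        de = list(n_genes = 50, lfc = 2,
                                  cell_type = "Tumor",
                                  condition_a = "BoneMet",
                                  condition_b = "Primary"),
                        lr_couplings = data.frame(
                          ligand = c("TNFSF11", "CCL18"),
                          receptor = c("TNFRSF11A", "CCR8"),
                          type_a = c("MSC2", "Macro2"),
                          type_b = c("Mono", "Treg"),
                          fold = c(5, 5)
                        ),
                        embed_sd = 0.8,
                        qc_low_umi = 0.05,
                        qc_high_mito = 0.03,
                        qc_high_doublet = 0.02,
                        size_factor_sd = 0.3,
                        seed = 1L) {
  stopifnot(length(conditions) >= 1, all(conditions >= 1),
            !is.null(names(conditions)),
            length(cells_per_sample) == 2,
            cells_per_sample[1] >= 1,
            cells_per_sample[2] >= cells_per_sample[1],
            all(cell_types > 0), !is.null(names(cell_types)),
            dirichlet_conc > 0, n_genes > 0, nb_theta > 0,
            marker_fold > 0, embed_sd > 0,
            qc_low_umi >= 0, qc_high_mito >= 0, qc_high_doublet >= 0,
            qc_low_umi + qc_high_mito + qc_high_doublet < 1)
  for (cond in names(condition_multipliers)) {
    if (!cond %in% names(conditions)) {
      stop("multiplier given for unknown condition '", cond, "'")
    }
    bad <- setdiff(names(condition_multipliers[[cond]]), names(cell_types))
    if (length(bad) > 0) stop("multiplier for unknown cell type: ",
                              paste(bad, collapse = ", "))
  }
  spec <- list(conditions = conditions,
               cells_per_sample = cells_per_sample,
               cell_types = cell_types / sum(cell_types),
               condition_multipliers = condition_multipliers,
               dirichlet_conc = dirichlet_conc,
               n_genes = n_genes,
               base_mean_shape = base_mean_shape,
               base_mean_scale = base_mean_scale,
               target_umi = target_umi,
               nb_theta = nb_theta,
               markers_per_type = markers_per_type,
               marker_fold = marker_fold,
               signature = signature, de = de,
               lr_couplings = lr_couplings,
               embed_sd = embed_sd,
               qc_low_umi = qc_low_umi, qc_high_mito = qc_high_mito,
               qc_high_doublet = qc_high_doublet,
               size_factor_sd = size_factor_sd,
               seed = as.integer(seed))
  class(spec) <- "nc_cohort_spec"
  spec
}

#' True cell-type proportions of a cohort spec
#'
#' The renormalized baseline-times-multiplier proportions for one condition
#' (the analytic ground truth for composition tests).
#'
#' @param spec An \code{nc_cohort_spec}.
#' @param condition Condition name.
#' @return Named numeric vector summing to 1.
#' @export
true_fractions <- function(spec, condition) {
  p <- spec$cell_types
  mult <- spec$condition_multipliers[[condition]]
  if (!is.null(mult)) p[names(mult)] <- p[names(mult)] * mult
  p / sum(p)
}

#' Simulate a multi-condition single-cell cohort
#'
#' Draws per-sample cell-type compositions from a condition-specific
#' Dirichlet, gene counts from per-type NB profiles with per-cell size
#' factors, places cells on a synthetic 2D embedding (Gaussian blob per
#' type), and injects flagged QC-failure cells. Every planted effect is
#' returned in the \code{truth} record; downstream validation reads planted
#' effects only from there.
#'
#' @param spec An [cohort_spec()] object.
#' @return A list with elements \code{counts} (sparse genes x cells),
#'   \code{cell_meta} (data.frame: barcode, sample_id, cluster, embed_x,
#'   embed_y, total_umi, mito_frac, doublet_score), \code{sample_meta}
#'   (data.frame: sample_id, patient_id, condition) and \code{truth}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "nc_cohort_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  types <- names(spec$cell_types)
  n_types <- length(types)

  # --- gene roles -----------------------------------------------------------
  base_mean <- rgamma(G, shape = spec$base_mean_shape,
                      scale = spec$base_mean_scale)
  base_mean <- pmax(base_mean, 1e-4)
  base_mean <- base_mean * (spec$target_umi %||% 2000) / sum(base_mean)
  gene_names <- sprintf("G%05d", seq_len(G))
  n_marker <- spec$markers_per_type * n_types
  n_sig <- if (is.null(spec$signature)) 0 else spec$signature$n_genes
  n_de <- if (is.null(spec$de)) 0 else spec$de$n_genes
  lr <- spec$lr_couplings
  n_lr <- if (is.null(lr)) 0 else 2 * nrow(lr)
  if (n_marker + n_sig + n_de + n_lr > G) {
    stop("n_genes too small for the requested planted effects")
  }
  idx <- seq_len(n_marker + n_sig + n_de + n_lr)
  marker_idx <- matrix(idx[seq_len(n_marker)], nrow = spec$markers_per_type)
  off <- n_marker
  sig_idx <- if (n_sig) idx[off + seq_len(n_sig)] else integer(0); off <- off + n_sig
  de_idx <- if (n_de) idx[off + seq_len(n_de)] else integer(0); off <- off + n_de
  lr_idx <- if (n_lr) idx[off + seq_len(n_lr)] else integer(0)
  # planted genes get the cohort's average expression level so effects are
  # observable without dominating any cell's library
  planted <- c(as.vector(marker_idx), sig_idx, de_idx, lr_idx)
  base_mean[planted] <- spec$target_umi / G
  if (n_lr) {
    lig_idx <- lr_idx[seq_len(nrow(lr))]
    rec_idx <- lr_idx[nrow(lr) + seq_len(nrow(lr))]
    gene_names[lig_idx] <- lr$ligand
    gene_names[rec_idx] <- lr$receptor
  }

  # per-type NB mean profiles (genes x types): markers and LR genes elevated
  profiles <- matrix(base_mean, nrow = G, ncol = n_types,
                     dimnames = list(gene_names, types))
  for (t in seq_len(n_types)) {
    profiles[marker_idx[, t], t] <- profiles[marker_idx[, t], t] * spec$marker_fold
  }
  if (n_lr) {
    for (k in seq_len(nrow(lr))) {
      profiles[lig_idx[k], lr$type_a[k]] <-
        profiles[lig_idx[k], lr$type_a[k]] * lr$fold[k]
      profiles[rec_idx[k], lr$type_b[k]] <-
        profiles[rec_idx[k], lr$type_b[k]] * lr$fold[k]
    }
  }
  # cell types keep comparable library sizes: marker elevation redistributes
  # the transcriptome rather than inflating the cell's total
  profiles <- sweep(profiles, 2, colSums(profiles) / spec$target_umi, "/")

  # --- samples --------------------------------------------------------------
  sample_meta <- do.call(rbind, lapply(names(spec$conditions), function(cond) {
    n <- spec$conditions[[cond]]
    data.frame(condition = rep(cond, n), idx = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  sample_meta$sample_id <- sprintf("%s_%02d", sample_meta$condition,
                                   sample_meta$idx)
  sample_meta$patient_id <- sprintf("P%03d", seq_len(nrow(sample_meta)))
  sample_meta <- sample_meta[, c("sample_id", "patient_id", "condition")]

  centers <- cbind(10 * cos(2 * pi * seq_len(n_types) / n_types),
                   10 * sin(2 * pi * seq_len(n_types) / n_types))
  rownames(centers) <- types

  counts_list <- vector("list", nrow(sample_meta))
  meta_list <- vector("list", nrow(sample_meta))
  for (s in seq_len(nrow(sample_meta))) {
    cond <- sample_meta$condition[s]
    lo <- spec$cells_per_sample[1]; hi <- spec$cells_per_sample[2]
    n_cells <- if (lo == hi) lo else sample(lo:hi, 1)
    p_true <- true_fractions(spec, cond)
    alpha <- p_true * spec$dirichlet_conc
    p_samp <- rgamma(n_types, shape = alpha)
    p_samp <- p_samp / sum(p_samp)
    type_of <- sample(types, n_cells, replace = TRUE, prob = p_samp)
    sfac <- exp(rnorm(n_cells, 0, spec$size_factor_sd))
    mu <- profiles[, type_of, drop = FALSE] *
      rep(sfac, each = G)  # genes x cells
    if (n_sig && cond == spec$signature$condition) {
      hit <- type_of == spec$signature$cell_type
      if (any(hit)) mu[sig_idx, hit] <- mu[sig_idx, hit] * spec$signature$fold
    }
    if (n_de && cond == spec$de$condition_a) {
      hit <- type_of == spec$de$cell_type
      if (any(hit)) mu[de_idx, hit] <- mu[de_idx, hit] * 2^spec$de$lfc
    }
    cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = spec$nb_theta),
                  nrow = G)
    emb <- centers[type_of, , drop = FALSE] +
      matrix(rnorm(2 * n_cells, 0, spec$embed_sd), ncol = 2)
    counts_list[[s]] <- as_dgc(Matrix::Matrix(cnt, sparse = TRUE))
    meta_list[[s]] <- data.frame(
      barcode = sprintf("%s-C%05d", sample_meta$sample_id[s], seq_len(n_cells)),
      sample_id = sample_meta$sample_id[s],
      cluster = type_of,
      embed_x = emb[, 1], embed_y = emb[, 2],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, counts_list)
  cell_meta <- do.call(rbind, meta_list)
  rownames(counts) <- gene_names
  colnames(counts) <- cell_meta$barcode
  rownames(cell_meta) <- NULL
  n_total <- ncol(counts)

  # --- QC nuisance ----------------------------------------------------------
  n_low <- round(spec$qc_low_umi * n_total)
  n_mito <- round(spec$qc_high_mito * n_total)
  n_dbl <- round(spec$qc_high_doublet * n_total)
  flagged <- sample(n_total, n_low + n_mito + n_dbl)
  low_i <- flagged[seq_len(n_low)]
  mito_i <- flagged[n_low + seq_len(n_mito)]
  dbl_i <- flagged[n_low + n_mito + seq_len(n_dbl)]
  if (n_low > 0) {
    # binomial thinning to a sub-threshold total UMI
    tot <- Matrix::colSums(counts[, low_i, drop = FALSE])
    target <- sample(100:699, n_low, replace = TRUE)
    for (k in seq_along(low_i)) {
      j <- low_i[k]
      if (tot[k] <= target[k]) { target[k] <- min(tot[k], 699); next }
      col <- counts[, j]
      nz <- which(col > 0)
      # binomial thinning; rejected draws that overshoot 699 are redrawn
      repeat {
        kept <- rbinom(length(nz), size = col[nz], prob = target[k] / tot[k])
        if (sum(kept) < 700) break
      }
      counts[nz, j] <- kept
    }
  }
  counts <- Matrix::drop0(counts)
  mito_frac <- runif(n_total, 0, 0.15)
  mito_frac[mito_i] <- runif(n_mito, 0.201, 0.6)
  doublet <- runif(n_total, 0, 0.35)
  doublet[dbl_i] <- runif(n_dbl, 0.401, 0.95)
  cell_meta$total_umi <- as.integer(Matrix::colSums(counts))
  cell_meta$mito_frac <- mito_frac
  cell_meta$doublet_score <- doublet

  truth <- list(
    fractions = lapply(setNames(nm = names(spec$conditions)),
                       function(cond) true_fractions(spec, cond)),
    markers = setNames(lapply(seq_len(n_types), function(t)
      gene_names[marker_idx[, t]]), types),
    marker_fold = spec$marker_fold,
    signature = if (n_sig) c(spec$signature,
                             list(genes = gene_names[sig_idx])) else NULL,
    de = if (n_de) c(spec$de, list(genes = gene_names[de_idx])) else NULL,
    lr = if (n_lr) cbind(lr, ligand_gene = gene_names[lig_idx],
                         receptor_gene = gene_names[rec_idx]) else NULL,
    qc = list(low_umi = cell_meta$barcode[low_i],
              high_mito = cell_meta$barcode[mito_i],
              high_doublet = cell_meta$barcode[dbl_i]),
    embedding_centers = centers
  )
  list(counts = counts, cell_meta = cell_meta, sample_meta = sample_meta,
       truth = truth)
}

#' Simulate pseudobulk NB count matrices for two groups
#'
#' Direct sample-level NB simulation used to validate the pseudobulk DE
#' test: per-gene baseline means shared across samples, a planted log2 fold
#' change for a subset of genes in group A, and per-sample library-size
#' factors.
#'
#' @param n_genes Number of genes.
#' @param n_a,n_b Samples per group.
#' @param theta NB dispersion (variance = mu + mu^2/theta).
#' @param n_de Number of planted DE genes (elevated in group A).
#' @param lfc Planted log2 fold change.
#' @param mean_log_mu,mean_log_sd Log-normal parameters of baseline means.
#' @param size_factor_sd Log-normal sd of per-sample depth factors.
#' @param seed Integer seed.
#' @return List with \code{counts_a}, \code{counts_b} (genes x samples
#'   integer matrices) and \code{truth} (planted gene names and lfc).
#' @export
simulate_nb_pseudobulk <- function(n_genes = 2000, n_a = 8, n_b = 8,
                                   theta = 10, n_de = 100, lfc = 2,
                                   mean_log_mu = log(50), mean_log_sd = 1.5,
                                   size_factor_sd = 0.25, seed = 1L) {
  stopifnot(n_de <= n_genes)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mu0 <- exp(rnorm(n_genes, mean_log_mu, mean_log_sd))
  de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
  fc <- rep(1, n_genes)
  fc[genes %in% de_genes] <- 2^lfc
  sf_a <- exp(rnorm(n_a, 0, size_factor_sd))
  sf_b <- exp(rnorm(n_b, 0, size_factor_sd))
  draw <- function(mu, sf) {
    m <- outer(mu, sf)
    matrix(rnbinom(length(m), mu = as.vector(m), size = theta),
           nrow = length(mu),
           dimnames = list(genes, sprintf("S%02d", seq_along(sf))))
  }
  counts_a <- draw(mu0 * fc, sf_a)
  counts_b <- draw(mu0, sf_b)
  colnames(counts_b) <- sprintf("S%02d", n_a + seq_len(n_b))
  list(counts_a = counts_a, counts_b = counts_b,
       truth = list(de_genes = de_genes, lfc = lfc))
}

#' Specify a synthetic bulk survival cohort
#'
#' A latent per-patient signature activity drives both the expression of the
#' signature genes and the event hazard: patients in the top activity
#' quartile have \code{hazard_ratio} times the baseline hazard of the bottom
#' quartile (middle half intermediate). Age and stage covariates can be
#' confounded with activity.
#'
#' @param n Number of patients.
#' @param signature_genes Character vector of signature gene names.
#' @param n_noise_genes Additional unrelated genes.
#' @param loading Effect of latent activity on signature-gene expression.
#' @param noise_sd Residual expression sd.
#' @param hazard_ratio Top-vs-bottom activity-quartile hazard ratio.
#' @param baseline_hazard Event rate (1/days) of the bottom quartile.
#' @param censoring_rate Fraction of patients independently censored.
#' @param age_confounding Added to age per unit activity (0 = none).
#' @param age_hazard Log hazard ratio per year of age (0 = age carries no
#'   risk; combined with \code{age_confounding} it makes age a genuine
#'   confounder).
#' @param stage_confounding Logit shift toward higher stage per unit
#'   activity (0 = none).
#' @param seed Integer seed.
#' @return A list of class \code{nc_survival_spec}.
#' @export
survival_cohort_spec <- function(n = 200,
                                 signature_genes = sprintf("SIG%02d", 1:10),
                                 n_noise_genes = 90,
                                 loading = 1,
                                 noise_sd = 0.5,
                                 hazard_ratio = 2,
                                 baseline_hazard = 1 / 1000,
                                 censoring_rate = 0.3,
                                 age_confounding = 0,
                                 age_hazard = 0,
                                 stage_confounding = 0,
                                 seed = 1L) {
  stopifnot(n >= 8, length(signature_genes) >= 1, hazard_ratio > 0,
            baseline_hazard > 0, censoring_rate >= 0, censoring_rate < 1,
            noise_sd >= 0)
  spec <- list(n = n, signature_genes = unique(signature_genes),
               n_noise_genes = n_noise_genes, loading = loading,
               noise_sd = noise_sd, hazard_ratio = hazard_ratio,
               baseline_hazard = baseline_hazard,
               censoring_rate = censoring_rate,
               age_confounding = age_confounding,
               age_hazard = age_hazard,
               stage_confounding = stage_confounding,
               seed = as.integer(seed))
  class(spec) <- "nc_survival_spec"
  spec
}

#' Simulate a bulk survival cohort
#'
#' @param spec A [survival_cohort_spec()] object.
#' @return A list with \code{cohort} (list: expr genes x patients, time,
#'   event, age, stage, patient_id) and \code{truth} (latent activity and
#'   quartile hazard groups).
#' @export
simulate_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "nc_survival_spec"))
  if (length(spec$signature_genes) == 0) stop("empty signature")
  set.seed(spec$seed)
  n <- spec$n
  act <- rnorm(n)
  sig <- spec$signature_genes
  genes <- c(sig, sprintf("NOISE%04d", seq_len(spec$n_noise_genes)))
  expr <- rbind(
    matrix(rep(spec$loading * act, each = length(sig)), nrow = length(sig)) +
      matrix(rnorm(length(sig) * n, 0, spec$noise_sd), nrow = length(sig)),
    matrix(rnorm(spec$n_noise_genes * n), nrow = spec$n_noise_genes)
  )
  dimnames(expr) <- list(genes, sprintf("PT%04d", seq_len(n)))
  qs <- quantile(act, c(0.25, 0.75), type = 7)
  hgrp <- ifelse(act >= qs[2], "top", ifelse(act <= qs[1], "bottom", "mid"))
  age <- rnorm(n, 60, 10) + spec$age_confounding * act
  rate <- spec$baseline_hazard *
    c(top = spec$hazard_ratio, mid = sqrt(spec$hazard_ratio), bottom = 1)[hgrp] *
    exp((spec$age_hazard %||% 0) * (age - 60))
  t_event <- rexp(n, rate = rate)
  event <- rep(1L, n)
  time <- t_event
  if (spec$censoring_rate > 0) {
    # independent exponential censoring with the rate that yields the
    # requested expected censoring fraction against the mean event rate
    c_rate <- mean(rate) * spec$censoring_rate / (1 - spec$censoring_rate)
    t_cens <- rexp(n, rate = c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  time <- pmax(time, 1e-6)
  stage_logit <- 0.5 * stats::rlogis(n) + spec$stage_confounding * act
  stage_cut <- quantile(stage_logit, c(0.4, 0.7, 0.9), type = 7)
  stage <- cut(stage_logit, c(-Inf, stage_cut, Inf),
               labels = c("I", "II", "III", "IV"))
  cohort <- list(expr = expr, time = time, event = event,
                 age = age, stage = as.character(stage),
                 patient_id = colnames(expr))
  list(cohort = cohort,
       truth = list(activity = act, hazard_group = hgrp,
                    hazard_ratio = spec$hazard_ratio))
}
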