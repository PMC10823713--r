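# Mean normalized expression of selected genes per cluster, given a label
# assignment: genes x clusters dense matrix. Shared by the observed score
# and every permutation round.
cluster_means <- function(norm_expr, labels, cl_names) {
  ind <- Matrix::sparseMatrix(
    i = seq_along(labels),
    j = match(labels, cl_names),
    x = 1, dims = c(length(labels), length(cl_names)))
  n <- Matrix::colSums(ind)
  m <- as.matrix(norm_expr %*% ind)
  colnames(m) <- cl_names
  sweep(m, 2, pmax(n, 1), "/")
}

#' Score ligand-receptor pair candidates between cell-type pairs
#'
#' For every ordered cell-type pair (A, B) and ligand-receptor pair, the
#' interaction score is the product of the ligand's mean normalized
#' expression in A and the receptor's mean normalized expression in B. A
#' candidate is only scored if the ligand is detected (count > 0) in at
#' least \code{config$lr_expr_ratio} (default 10%) of A's cells and the
#' receptor likewise in B; pairs failing the gate are absent from the
#' result, not scored 0. Clusters with fewer than \code{min_cells} cells
#' are skipped.
#'
#' @param norm_expr Genes x cells normalized expression matrix.
#' @param clusters Per-cell cluster labels.
#' @param lr_table Data.frame with \code{ligand}, \code{receptor} columns
#'   (see [read_lr_table()]).
#' @param config An [nc_config()] object.
#' @param min_cells Minimum cluster size considered (default 10).
#' @return A data.frame of candidates: \code{ligand}, \code{receptor},
#'   \code{cell_type_a}, \code{cell_type_b}, \code{expr_ratio_ligand},
#'   \code{expr_ratio_receptor}, \code{mean_ligand_a},
#'   \code{mean_receptor_b}, \code{score}.
#' @export
lr_score <- function(norm_expr, clusters, lr_table, config = nc_config(),
                     min_cells = 10) {
  clusters <- as.character(clusters)
  stopifnot(ncol(norm_expr) == length(clusters))
  sizes <- table(clusters)
  cl_names <- sort(names(sizes)[sizes >= min_cells])
  skipped <- setdiff(names(sizes), cl_names)
  if (length(skipped) > 0) {
    nc_msg("clusters skipped (<", min_cells, " cells): ",
           paste(skipped, collapse = ", "))
  }
  if (length(cl_names) < 1) stop("no cluster large enough to score")
  genes_needed <- unique(c(lr_table$ligand, lr_table$receptor))
  absent <- setdiff(genes_needed, rownames(norm_expr))
  if (length(absent) > 0) {
    nc_msg(length(absent), " ligand/receptor genes absent from matrix; ",
           "their pairs skipped")
  }
  lr <- lr_table[lr_table$ligand %in% rownames(norm_expr) &
                   lr_table$receptor %in% rownames(norm_expr), ,
                 drop = FALSE]
  if (nrow(lr) == 0) stop("no ligand-receptor pair with both genes present")
  genes <- unique(c(lr$ligand, lr$receptor))
  keep <- clusters %in% cl_names
  sub <- norm_expr[genes, keep, drop = FALSE]
  labs <- clusters[keep]
  means <- cluster_means(sub, labs, cl_names)
  det <- cluster_means(as_dgc(sub > 0) * 1, labs, cl_names)  # detection ratio

  out <- list()
  for (k in seq_len(nrow(lr))) {
    lg <- lr$ligand[k]; rc <- lr$receptor[k]
    for (a in cl_names) {
      if (det[lg, a] < config$lr_expr_ratio) next
      for (b in cl_names) {
        if (det[rc, b] < config$lr_expr_ratio) next
        out[[length(out) + 1]] <- data.frame(
          ligand = lg, receptor = rc, cell_type_a = a, cell_type_b = b,
          expr_ratio_ligand = det[lg, a], expr_ratio_receptor = det[rc, b],
          mean_ligand_a = means[lg, a], mean_receptor_b = means[rc, b],
          score = means[lg, a] * means[rc, b],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    nc_msg("no candidate passed the expression-ratio gate")
    return(data.frame(ligand = character(0), receptor = character(0),
                      cell_type_a = character(0), cell_type_b = character(0),
                      expr_ratio_ligand = numeric(0),
                      expr_ratio_receptor = numeric(0),
                      mean_ligand_a = numeric(0),
                      mean_receptor_b = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Permutation test for ligand-receptor interaction scores
#'
#' Builds the null by shuffling the cluster labels of all cells jointly --
#' one shuffle per round, reused for every candidate -- and recomputing
#' each candidate's score, for \code{config$lr_n_perm} rounds (default
#' 1000). The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{score_{perm} \ge score_{obs}\}) / (B + 1)}, so p is
#' never 0 and is at least 1/(B+1). A candidate passes when
#' p <= \code{config$lr_p}.
#'
#' @param norm_expr Genes x cells normalized expression matrix.
#' @param clusters Per-cell cluster labels (same clustering the candidates
#'   were scored on).
#' @param candidates Result of [lr_score()].
#' @param config An [nc_config()] object.
#' @param seed Seed for the label shuffles (default \code{config$seed}).
#' @return \code{candidates} with columns \code{p} and \code{passes_perm}
#'   appended.
#' @export
lr_permutation_test <- function(norm_expr, clusters, candidates,
                                config = nc_config(), seed = NULL) {
  clusters <- as.character(clusters)
  if (nrow(candidates) == 0) {
    candidates$p <- numeric(0)
    candidates$passes_perm <- logical(0)
    return(candidates)
  }
  B <- config$lr_n_perm
  if (B < 100) warning("fewer than 100 permutations: p floor is unstable")
  # labels of all cells are shuffled jointly; means are read off for the
  # candidate cell types only
  cl_names <- sort(unique(clusters))
  genes <- unique(c(candidates$ligand, candidates$receptor))
  sub <- as_dgc(norm_expr[genes, , drop = FALSE])
  labs <- clusters
  li <- match(candidates$ligand, genes)
  ri <- match(candidates$receptor, genes)
  ai <- match(candidates$cell_type_a, cl_names)
  bi <- match(candidates$cell_type_b, cl_names)
  obs <- candidates$score
  exceed <- integer(nrow(candidates))
  set.seed(seed %||% config$seed)
  for (b in seq_len(B)) {
    perm <- sample(labs)
    m <- cluster_means(sub, perm, cl_names)
    sc <- m[cbind(li, ai)] * m[cbind(ri, bi)]
    exceed <- exceed + as.integer(sc >= obs)
  }
  candidates$p <- (1 + exceed) / (B + 1)
  candidates$passes_perm <- candidates$p <= config$lr_p
  candidates
}

#' Marker-Z screen of ligand-receptor interactions
#'
#' Intersects the permutation filter with a differential-expression screen:
#' the ligand must be a strong marker of the sender type (p-value-derived
#' Z strictly above \code{config$lr_ligand_z}, default 4) and the receptor
#' at least nominally elevated in the receiver type (Z strictly above
#' \code{config$lr_receptor_z}, default 0). Genes missing from the marker
#' table are treated as Z = 0 and logged (they fail both strict screens).
#'
#' @param lr_result Result of [lr_permutation_test()].
#' @param markers Marker table from [find_markers()] on the same
#'   clustering.
#' @param config An [nc_config()] object.
#' @return \code{lr_result} with \code{ligand_z}, \code{receptor_z},
#'   \code{passes_z} and \code{reported} (permutation AND Z screen)
#'   appended; attribute \code{"pair_counts"} holds the reported
#'   interaction count per (sender, receiver) cell-type pair.
#' @export
lr_z_screen <- function(lr_result, markers, config = nc_config()) {
  key <- paste(markers$gene, markers$cluster, sep = "\r")
  zmap <- setNames(markers$z, key)
  lig_key <- paste(lr_result$ligand, lr_result$cell_type_a, sep = "\r")
  rec_key <- paste(lr_result$receptor, lr_result$cell_type_b, sep = "\r")
  lz <- unname(zmap[lig_key])
  rz <- unname(zmap[rec_key])
  n_missing <- sum(is.na(lz)) + sum(is.na(rz))
  if (n_missing > 0) {
    nc_msg(n_missing, " ligand/receptor marker entries missing; Z taken as 0")
  }
  lz[is.na(lz)] <- 0
  rz[is.na(rz)] <- 0
  lr_result$ligand_z <- lz
  lr_result$receptor_z <- rz
  lr_result$passes_z <- lz > config$lr_ligand_z & rz > config$lr_receptor_z
  lr_result$reported <- lr_result$passes_perm & lr_result$passes_z
  rep_rows <- lr_result[lr_result$reported, , drop = FALSE]
  cl <- sort(unique(c(lr_result$cell_type_a, lr_result$cell_type_b)))
  attr(lr_result, "pair_counts") <- table(
    factor(rep_rows$cell_type_a, cl), factor(rep_rows$cell_type_b, cl))
  lr_result
}
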