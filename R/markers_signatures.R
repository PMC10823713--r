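#' One-vs-rest marker detection with p-value-derived Z scores
#'
#' For every cluster and gene, a two-sided Wilcoxon rank-sum test compares
#' the gene's normalized expression in the cluster against all other cells.
#' The test's p-value is converted to a signed Z score,
#' \deqn{z = \mathrm{sign}(\bar x_{in} - \bar x_{out}) \, \Phi^{-1}(1 - p/2),}
#' capped at |z| <= 37 so underflowing p-values stay finite. A gene passes
#' the marker filter when z strictly exceeds \code{config$marker_z}
#' (default 3). BH correction is applied across genes within each cluster.
#'
#' @param norm_expr Genes x cells normalized expression matrix (see
#'   [normalize_counts()]).
#' @param clusters Character/factor vector of cluster labels, one per cell.
#' @param config An [nc_config()] object.
#' @param genes Optional subset of genes to test (default all).
#' @param min_cells Clusters with fewer cells are skipped with a warning.
#' @return A data.frame with columns \code{gene}, \code{cluster},
#'   \code{mean_in}, \code{mean_out}, \code{p}, \code{padj}, \code{z},
#'   \code{passes}.
#' @export
find_markers <- function(norm_expr, clusters, config = nc_config(),
                         genes = NULL, min_cells = 3) {
  stopifnot(ncol(norm_expr) == length(clusters))
  clusters <- as.character(clusters)
  cl_names <- sort(unique(clusters))
  if (length(cl_names) < 2) stop("need at least 2 clusters")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(norm_expr))
    if (length(missing) > 0) {
      nc_msg(length(missing), " requested genes absent from matrix")
    }
    norm_expr <- norm_expr[intersect(genes, rownames(norm_expr)), ,
                           drop = FALSE]
  }
  m <- as.matrix(norm_expr)
  out <- vector("list", length(cl_names))
  for (k in seq_along(cl_names)) {
    cl <- cl_names[k]
    in_idx <- which(clusters == cl)
    if (length(in_idx) < min_cells) {
      warning("cluster '", cl, "' has fewer than ", min_cells,
              " cells; skipped")
      next
    }
    if (length(in_idx) == ncol(m)) next
    w <- wilcox_rows(m, in_idx)
    mean_in <- rowMeans(m[, in_idx, drop = FALSE])
    mean_out <- rowMeans(m[, -in_idx, drop = FALSE])
    z <- p_to_z(w$p, sign = mean_in - mean_out)
    out[[k]] <- data.frame(
      gene = rownames(m), cluster = cl,
      mean_in = mean_in, mean_out = mean_out,
      p = w$p, padj = p.adjust(w$p, "BH"), z = z,
      passes = z > config$marker_z,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no cluster had enough cells to test")
  res
}

#' Per-cell gene-set signature score
#'
#' The score of a cell is the unweighted mean of its normalized expression
#' over the signature genes present in the matrix. Genes absent from the
#' matrix are dropped with a message; if none remain, this is an error.
#' Duplicate genes in the set do not change the score.
#'
#' @param norm_expr Genes x cells normalized expression matrix.
#' @param signature Character vector of gene symbols (or one element of the
#'   list returned by [read_gmt()]).
#' @param cells Optional barcodes restricting the cells scored.
#' @return Named numeric vector of per-cell scores.
#' @export
score_signature <- function(norm_expr, signature, cells = NULL) {
  signature <- unique(signature)
  present <- intersect(signature, rownames(norm_expr))
  missing <- setdiff(signature, present)
  if (length(present) == 0) {
    stop("no signature gene present in matrix; missing: ",
         paste(missing, collapse = ", "))
  }
  if (length(missing) > 0) {
    nc_msg(length(missing), " of ", length(signature),
           " signature genes absent from matrix; dropped")
  }
  if (!is.null(cells)) norm_expr <- norm_expr[, cells, drop = FALSE]
  sub <- norm_expr[present, , drop = FALSE]
  setNames(as.numeric(Matrix::colMeans(sub)), colnames(sub))
}

#' Compare signature scores across conditions at the sample level
#'
#' Per-sample scores are the arithmetic mean of per-cell scores (optionally
#' restricted to one cell type). Each requested condition pair is tested
#' with a two-sided Wilcoxon rank-sum test on the sample scores, and BH
#' correction is applied across the pairs tested in one call.
#'
#' @param scores Named per-cell scores from [score_signature()].
#' @param cell_meta,sample_meta Cohort metadata.
#' @param cell_type Optional cluster label restricting the cells used.
#' @param condition_pairs List of length-2 character vectors (condition A,
#'   condition B), or a single pair.
#' @param min_samples Pairs where either condition has fewer qualifying
#'   samples are skipped with a warning (default 2).
#' @return A list with \code{sample_scores} (data.frame: sample_id,
#'   condition, n_cells, score) and \code{tests} (data.frame: condition_a,
#'   condition_b, n_a, n_b, median_a, median_b, p, padj).
#' @export
compare_signature_across_conditions <- function(scores, cell_meta,
                                                sample_meta,
                                                cell_type = NULL,
                                                condition_pairs,
                                                min_samples = 2) {
  if (!is.list(condition_pairs)) condition_pairs <- list(condition_pairs)
  meta <- cell_meta[match(names(scores), cell_meta$barcode), , drop = FALSE]
  if (anyNA(meta$barcode)) stop("scores contain barcodes absent from cell_meta")
  if (!is.null(cell_type)) {
    keep <- meta$cluster == cell_type
    meta <- meta[keep, , drop = FALSE]
    scores <- scores[keep]
  }
  agg <- tapply(scores, meta$sample_id, mean)
  n_cells <- tapply(scores, meta$sample_id, length)
  sample_scores <- data.frame(
    sample_id = names(agg),
    condition = sample_meta$condition[match(names(agg),
                                            sample_meta$sample_id)],
    n_cells = as.integer(n_cells),
    score = as.numeric(agg),
    stringsAsFactors = FALSE, row.names = NULL)

  rows <- lapply(condition_pairs, function(pr) {
    a <- sample_scores$score[sample_scores$condition == pr[1]]
    b <- sample_scores$score[sample_scores$condition == pr[2]]
    if (length(a) < min_samples || length(b) < min_samples) {
      warning("pair ", pr[1], " vs ", pr[2],
              " skipped: fewer than ", min_samples, " qualifying samples")
      return(data.frame(condition_a = pr[1], condition_b = pr[2],
                        n_a = length(a), n_b = length(b),
                        median_a = median(a), median_b = median(b),
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
    data.frame(condition_a = pr[1], condition_b = pr[2],
               n_a = length(a), n_b = length(b),
               median_a = median(a), median_b = median(b),
               p = p, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$padj <- NA_real_
  ok <- !is.na(tests$p)
  tests$padj[ok] <- p.adjust(tests$p[ok], "BH")
  list(sample_scores = sample_scores, tests = tests)
}
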