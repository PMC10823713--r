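#' Per-sample, per-subpopulation pseudobulk profiles
#'
#' Sums raw counts over each subpopulation's cells within each sample, then
#' library-size normalizes the sum (to 1e4) and applies log(1 + x). Pairs
#' with fewer than \code{min_cells} cells are dropped. The subpopulation
#' proportion (cells of the subpopulation / cells of the sample) is
#' recorded for use as a distance weight.
#'
#' @param counts Genes x cells raw count matrix.
#' @param cell_meta Cohort cell metadata (\code{barcode}, \code{sample_id},
#'   \code{cluster}).
#' @param min_cells Minimum cells per (sample, subpopulation) pair.
#' @return A list of class \code{nc_pseudobulk}: \code{profiles} (genes x
#'   pairs matrix), \code{pairs} (data.frame: sample_id, subpopulation,
#'   n_cells, proportion).
#' @export
pseudobulk_profiles <- function(counts, cell_meta, min_cells = 10) {
  counts <- as_dgc(counts)
  stopifnot(setequal(colnames(counts), cell_meta$barcode))
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ,
                         drop = FALSE]
  key <- paste(cell_meta$sample_id, cell_meta$cluster, sep = "\r")
  keys <- unique(key)
  # indicator matrix: cells x pairs, summing counts per pair
  ind <- Matrix::sparseMatrix(i = seq_along(key),
                              j = match(key, keys),
                              x = 1, dims = c(length(key), length(keys)))
  sums <- counts %*% ind
  n_cells <- as.integer(Matrix::colSums(ind))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  pairs <- data.frame(sample_id = parts[, 1], subpopulation = parts[, 2],
                      n_cells = n_cells, stringsAsFactors = FALSE)
  sample_tot <- tapply(pairs$n_cells, pairs$sample_id, sum)
  pairs$proportion <- pairs$n_cells / as.numeric(sample_tot[pairs$sample_id])
  keep <- pairs$n_cells >= min_cells
  sums <- sums[, keep, drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  lib <- Matrix::colSums(sums)
  lib[lib == 0] <- 1
  prof <- as.matrix(sums %*% Matrix::Diagonal(x = 1e4 / lib))
  prof <- log1p(prof)
  rownames(prof) <- rownames(counts)
  colnames(prof) <- paste(pairs$sample_id, pairs$subpopulation, sep = "|")
  rownames(pairs) <- NULL
  out <- list(profiles = prof, pairs = pairs)
  class(out) <- "nc_pseudobulk"
  out
}

#' Proportion-weighted expression distance between samples
#'
#' For each pair of samples and each subpopulation present in both, the
#' correlation distance \eqn{d_s = 1 - \mathrm{Pearson}(x_{i,s}, x_{j,s})}
#' between the two pseudobulk profiles is computed over the top
#' \code{n_top_genes} most variable genes across all pseudobulks. The
#' overall distance is the weighted sum \eqn{D_{ij} = \sum_s w_s d_s} with
#' \eqn{w_s} proportional to the mean of the subpopulation's cell
#' proportions in the two samples, renormalized over the shared
#' subpopulations (so the weights sum to 1 and \eqn{D \in [0, 2]}).
#'
#' @param pb An [pseudobulk_profiles()] result.
#' @param n_top_genes Number of most-variable genes used (default 2000; all
#'   genes if fewer).
#' @return A list of class \code{nc_expr_distance}: \code{D} (symmetric
#'   sample x sample matrix, NA where no subpopulation is shared),
#'   \code{detail} (per sample pair and subpopulation: distance and
#'   weight).
#' @export
expression_distance <- function(pb, n_top_genes = 2000) {
  stopifnot(inherits(pb, "nc_pseudobulk"))
  samples <- sort(unique(pb$pairs$sample_id))
  if (length(samples) < 2) stop("need >= 2 samples")
  v <- apply(pb$profiles, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(pb$profiles)))]
  prof <- pb$profiles[top, , drop = FALSE]
  D <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  diag(D) <- 0
  detail <- list()
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1L)) {
      pi <- pb$pairs[pb$pairs$sample_id == samples[i], , drop = FALSE]
      pj <- pb$pairs[pb$pairs$sample_id == samples[j], , drop = FALSE]
      shared <- intersect(pi$subpopulation, pj$subpopulation)
      if (length(shared) == 0) {
        nc_msg("samples ", samples[i], " and ", samples[j],
               " share no subpopulation; distance undefined")
        next
      }
      w <- vapply(shared, function(s) {
        mean(c(pi$proportion[pi$subpopulation == s],
               pj$proportion[pj$subpopulation == s]))
      }, numeric(1))
      w <- w / sum(w)
      d <- vapply(shared, function(s) {
        ci <- prof[, paste(samples[i], s, sep = "|")]
        cj <- prof[, paste(samples[j], s, sep = "|")]
        r <- suppressWarnings(cor(ci, cj))
        if (is.na(r)) r <- 0  # constant profile: no linear association
        1 - r
      }, numeric(1))
      D[i, j] <- D[j, i] <- sum(w * d)
      detail[[length(detail) + 1]] <- data.frame(
        sample_a = samples[i], sample_b = samples[j],
        subpopulation = shared, weight = unname(w), distance = unname(d),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(D = D,
              detail = if (length(detail)) do.call(rbind, detail) else NULL)
  class(out) <- "nc_expr_distance"
  out
}

#' Classical MDS projection of an expression distance matrix
#'
#' Torgerson's classical multidimensional scaling, centered at the origin.
#' Coordinates are determined only up to sign and rotation; compare
#' embedded pairwise distances, not raw coordinates. Samples with any
#' undefined distance are dropped with a warning.
#'
#' @param ed An [expression_distance()] result, or a symmetric distance
#'   matrix.
#' @param k Embedding dimension (default 2).
#' @return A samples x k coordinate matrix.
#' @export
mds_project <- function(ed, k = 2) {
  D <- if (inherits(ed, "nc_expr_distance")) ed$D else as.matrix(ed)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  incomplete <- rowSums(is.na(D)) > 0
  if (any(incomplete)) {
    warning(sum(incomplete), " samples with undefined distances dropped ",
            "from MDS")
    D <- D[!incomplete, !incomplete, drop = FALSE]
  }
  if (nrow(D) <= k) stop("need more than k samples for a k-dim projection")
  xy <- cmdscale(stats::as.dist(D), k = k)
  sweep(xy, 2, colMeans(xy))
}
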