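#' Cell-level quality-control filtering
#'
#' Removes cells with fewer than \code{min_umi} total UMI, more than
#' \code{max_mito} mitochondrial transcript fraction, or a doublet score
#' above \code{max_doublet}. Removal rules are strict inequalities, so
#' cells sitting exactly on a boundary are retained. A cell failing
#' several rules is attributed, for reporting only, to the first failing
#' rule in the fixed order UMI, mito, doublet; retention is the conjunction
#' of all three rules.
#'
#' The mitochondrial fraction is taken from \code{cell_meta$mito_frac} when
#' present; otherwise it is computed as the count fraction of genes whose
#' symbol starts with \code{"MT-"} (human convention).
#'
#' @param counts Genes x cells count matrix.
#' @param cell_meta Per-cell metadata with \code{barcode}, \code{sample_id},
#'   and (optionally) \code{total_umi}, \code{mito_frac},
#'   \code{doublet_score} columns. Missing \code{total_umi} is computed
#'   from column sums; missing \code{doublet_score} is treated as 0.
#' @param config An [nc_config()] object.
#' @return A list with \code{counts} and \code{cell_meta} restricted to
#'   retained cells, and \code{report}: per-sample counts of cells removed
#'   by each rule and retained, plus the thresholds used.
#' @export
apply_qc <- function(counts, cell_meta, config = nc_config()) {
  counts <- as_dgc(counts)
  if (!setequal(colnames(counts), cell_meta$barcode) ||
      ncol(counts) != nrow(cell_meta)) {
    stop("cell_meta barcodes do not match count matrix columns")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ,
                         drop = FALSE]
  total_umi <- cell_meta$total_umi %||% as.integer(Matrix::colSums(counts))
  mito <- cell_meta$mito_frac
  if (is.null(mito)) {
    mt <- grepl("^MT-", rownames(counts))
    tot <- Matrix::colSums(counts)
    mito <- ifelse(tot > 0, Matrix::colSums(counts[mt, , drop = FALSE]) / tot, 0)
  }
  doublet <- cell_meta$doublet_score %||% rep(0, ncol(counts))

  fail_umi <- total_umi < config$min_umi
  fail_mito <- mito > config$max_mito
  fail_dbl <- doublet > config$max_doublet
  keep <- !(fail_umi | fail_mito | fail_dbl)
  # first-failing-rule attribution in fixed order for the report
  rule <- ifelse(fail_umi, "low_umi",
                 ifelse(fail_mito, "high_mito",
                        ifelse(fail_dbl, "high_doublet", "retained")))

  samples <- unique(cell_meta$sample_id)
  report <- data.frame(
    sample_id = samples,
    n_input = as.integer(table(factor(cell_meta$sample_id, samples))),
    removed_low_umi = as.integer(table(factor(
      cell_meta$sample_id[rule == "low_umi"], samples))),
    removed_high_mito = as.integer(table(factor(
      cell_meta$sample_id[rule == "high_mito"], samples))),
    removed_high_doublet = as.integer(table(factor(
      cell_meta$sample_id[rule == "high_doublet"], samples))),
    retained = as.integer(table(factor(
      cell_meta$sample_id[keep], samples))),
    stringsAsFactors = FALSE
  )
  attr(report, "thresholds") <- c(min_umi = config$min_umi,
                                  max_mito = config$max_mito,
                                  max_doublet = config$max_doublet)
  list(counts = counts[, keep, drop = FALSE],
       cell_meta = cell_meta[keep, , drop = FALSE],
       report = report)
}
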