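#' Analysis configuration
#'
#' Collects every numeric threshold used by the pipeline in one place, with
#' defaults matching the protocol the package implements. All stochastic
#' operations draw their seed from this object unless given one explicitly.
#'
#' @param min_umi Minimum per-cell total UMI; cells with fewer are removed.
#' @param max_mito Maximum mitochondrial transcript fraction; cells with more
#'   are removed.
#' @param max_doublet Maximum doublet score; cells above are removed.
#' @param marker_z Marker filter: a gene passes when its signed
#'   p-value-derived Z exceeds this value (strictly).
#' @param min_cells_composition Minimum cells of a major population a sample
#'   must contribute to enter that population's subtype fraction tests.
#' @param grid Number of bins per axis for the cluster-free density grid.
#' @param de_min_cells,de_max_cells Per-sample cell-count gate for pseudobulk
#'   DE: samples with fewer cells of the target type are excluded, samples
#'   with more are downsampled to the maximum.
#' @param de_n_resamplings Number of leave-one-out resampling rounds.
#' @param de_padj,de_lfc Significance thresholds: adjusted p below
#'   \code{de_padj} and absolute log2 fold change above \code{de_lfc}.
#' @param de_indep_filter_min Genes with mean normalized pseudobulk count
#'   below this are excluded from the BH family (independent-filtering
#'   analogue).
#' @param lr_expr_ratio Minimum fraction of cells of a type expressing a
#'   ligand/receptor gene for the pair to be scored.
#' @param lr_n_perm Number of label permutations for the LR null.
#' @param lr_p Permutation p-value threshold (inclusive).
#' @param lr_ligand_z,lr_receptor_z Marker-Z screen: ligand Z must exceed
#'   \code{lr_ligand_z} and receptor Z must exceed \code{lr_receptor_z},
#'   both strictly.
#' @param surv_quantile Fraction of patients in each of the high and low
#'   signature strata.
#' @param surv_n_boot Number of gene-subset bootstrap rounds.
#' @param surv_boot_frac Fraction of signature genes sampled (without
#'   replacement) per bootstrap round.
#' @param surv_report_q Quantile of the bootstrap p-value vector reported as
#'   the stability p-value.
#' @param seed Integer seed used by stochastic operations.
#'
#' @return A list of class \code{nc_config}.
#' @export
nc_config <- function(min_umi = 700,
                      max_mito = 0.20,
                      max_doublet = 0.40,
                      marker_z = 3,
                      min_cells_composition = 50,
                      grid = 400,
                      de_min_cells = 10,
                      de_max_cells = 320,
                      de_n_resamplings = 100,
                      de_padj = 0.05,
                      de_lfc = 1.5,
                      de_indep_filter_min = 1,
                      lr_expr_ratio = 0.10,
                      lr_n_perm = 1000,
                      lr_p = 0.05,
                      lr_ligand_z = 4,
                      lr_receptor_z = 0,
                      surv_quantile = 0.25,
                      surv_n_boot = 200,
                      surv_boot_frac = 0.80,
                      surv_report_q = 0.90,
                      seed = 1L) {
  cfg <- list(
    min_umi = min_umi, max_mito = max_mito, max_doublet = max_doublet,
    marker_z = marker_z, min_cells_composition = min_cells_composition,
    grid = grid, de_min_cells = de_min_cells, de_max_cells = de_max_cells,
    de_n_resamplings = de_n_resamplings, de_padj = de_padj, de_lfc = de_lfc,
    de_indep_filter_min = de_indep_filter_min,
    lr_expr_ratio = lr_expr_ratio, lr_n_perm = lr_n_perm, lr_p = lr_p,
    lr_ligand_z = lr_ligand_z, lr_receptor_z = lr_receptor_z,
    surv_quantile = surv_quantile, surv_n_boot = surv_n_boot,
    surv_boot_frac = surv_boot_frac, surv_report_q = surv_report_q,
    seed = as.integer(seed)
  )
  stopifnot(
    min_umi > 0, max_mito > 0, max_mito < 1, max_doublet > 0,
    marker_z > 0, min_cells_composition > 0, grid > 0,
    de_min_cells > 0, de_max_cells >= de_min_cells, de_n_resamplings > 0,
    de_padj > 0, de_padj < 1, de_lfc > 0,
    lr_expr_ratio > 0, lr_expr_ratio < 1, lr_n_perm > 0,
    lr_p > 0, lr_p < 1,
    surv_quantile > 0, surv_quantile < 0.5,
    surv_n_boot > 0, surv_boot_frac > 0, surv_boot_frac <= 1,
    surv_report_q > 0, surv_report_q < 1
  )
  class(cfg) <- "nc_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [nc_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An \code{nc_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- read_yaml_simple(path)
  known <- names(formals(nc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(nc_config, vals)
}

# Minimal flat key: value YAML reader (the config schema is flat scalars).
read_yaml_simple <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    v <- m[3]
    num <- suppressWarnings(as.numeric(v))
    vals[[m[2]]] <- if (!is.na(num)) num else v
  }
  vals
}
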