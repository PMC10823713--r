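#' Cluster-based compositional shift testing
#'
#' Cell-type fractions are computed per sample within each major cell
#' population (the denominator is the sample's cells of that major
#' population, not the whole sample). A sample contributing fewer than
#' \code{config$min_cells_composition} cells (default 50) of a major
#' population is excluded from that population's subtype tests, so a few
#' sparse samples cannot skew the fractions. Each requested condition pair
#' is compared per cell type with a two-sided Wilcoxon rank-sum test on the
#' per-sample fractions, with BH correction across the cell types tested
#' within that pair.
#'
#' @param cell_meta,sample_meta Cohort metadata ([simulate_cohort()] layout).
#' @param major_population_map Named character vector mapping each cluster
#'   label to its major population; \code{NULL} treats every cluster as its
#'   own major population member of one whole-sample population.
#' @param condition_pairs List of length-2 character vectors.
#' @param config An [nc_config()] object.
#' @return A data.frame of class \code{nc_composition} with columns
#'   \code{cell_type}, \code{major_population}, \code{condition_a},
#'   \code{condition_b}, \code{n_a}, \code{n_b}, \code{frac_a_median},
#'   \code{frac_b_median}, \code{p}, \code{padj}, \code{tested}. Per-sample
#'   fractions are attached as attribute \code{"sample_fractions"}.
#' @export
composition_test <- function(cell_meta, sample_meta,
                             major_population_map = NULL,
                             condition_pairs, config = nc_config()) {
  if (!is.list(condition_pairs)) condition_pairs <- list(condition_pairs)
  types <- sort(unique(cell_meta$cluster))
  if (is.null(major_population_map)) {
    major_population_map <- setNames(rep("all", length(types)), types)
  }
  missing <- setdiff(types, names(major_population_map))
  if (length(missing) > 0) {
    stop("clusters missing from major_population_map: ",
         paste(missing, collapse = ", "))
  }
  cond_of <- setNames(sample_meta$condition, sample_meta$sample_id)
  samples <- sample_meta$sample_id

  # per (sample, cell type) counts and per (sample, major population) totals
  ct_counts <- table(factor(cell_meta$sample_id, samples),
                     factor(cell_meta$cluster, types))
  major_of <- major_population_map[types]
  frac <- matrix(NA_real_, length(samples), length(types),
                 dimnames = list(samples, types))
  for (mp in unique(major_of)) {
    cols <- which(major_of == mp)
    tot <- rowSums(ct_counts[, cols, drop = FALSE])
    ok <- tot >= config$min_cells_composition
    frac[ok, cols] <- ct_counts[ok, cols, drop = FALSE] / tot[ok]
  }

  rows <- list()
  for (pr in condition_pairs) {
    sa <- samples[cond_of[samples] == pr[1]]
    sb <- samples[cond_of[samples] == pr[2]]
    pvec <- rep(NA_real_, length(types))
    dfs <- vector("list", length(types))
    for (t in seq_along(types)) {
      fa <- frac[sa, t]; fa <- fa[!is.na(fa)]
      fb <- frac[sb, t]; fb <- fb[!is.na(fb)]
      tested <- length(fa) >= 2 && length(fb) >= 2
      if (tested) {
        pvec[t] <- suppressWarnings(
          wilcox.test(fa, fb, alternative = "two.sided")$p.value)
      }
      dfs[[t]] <- data.frame(
        cell_type = types[t], major_population = unname(major_of[t]),
        condition_a = pr[1], condition_b = pr[2],
        n_a = length(fa), n_b = length(fb),
        frac_a_median = if (length(fa)) median(fa) else NA_real_,
        frac_b_median = if (length(fb)) median(fb) else NA_real_,
        p = pvec[t], tested = tested,
        stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, dfs)
    block$padj <- NA_real_
    ok <- !is.na(block$p)
    block$padj[ok] <- p.adjust(block$p[ok], "BH")
    rows[[length(rows) + 1]] <- block
  }
  res <- do.call(rbind, rows)
  res <- res[, c("cell_type", "major_population", "condition_a",
                 "condition_b", "n_a", "n_b", "frac_a_median",
                 "frac_b_median", "p", "padj", "tested")]
  attr(res, "sample_fractions") <- frac
  class(res) <- c("nc_composition", class(res))
  res
}

#' Per-sample and per-condition embedding density maps
#'
#' A 2D Gaussian kernel density is estimated for each sample on a shared
#' grid (default 400 x 400 bins) covering the global embedding bounding box
#' plus 2% padding, with a per-sample, per-axis normal-reference bandwidth.
#' Each sample's map is renormalized to sum to 1 so samples with different
#' cell numbers are comparable; a condition's map is the mean of its
#' samples' maps.
#'
#' @param cell_meta,sample_meta Cohort metadata with \code{embed_x},
#'   \code{embed_y}.
#' @param conditions Conditions to average (default all present).
#' @param config An [nc_config()] object (\code{grid} sets bins per axis).
#' @param min_cells Samples with fewer cells are excluded with a warning.
#' @return A list of class \code{nc_density_maps}: \code{grid_x},
#'   \code{grid_y} (bin centers), \code{sample_maps} (named list of
#'   grid x grid matrices summing to 1), \code{condition_maps},
#'   \code{sample_condition} (named vector).
#' @export
density_maps <- function(cell_meta, sample_meta, conditions = NULL,
                         config = nc_config(), min_cells = 10) {
  stopifnot(all(c("embed_x", "embed_y") %in% names(cell_meta)))
  if (anyNA(cell_meta$embed_x) || anyNA(cell_meta$embed_y)) {
    stop("embedding coordinates missing for some cells")
  }
  conds <- conditions %||% unique(sample_meta$condition)
  keep_samples <- sample_meta$sample_id[sample_meta$condition %in% conds]
  cm <- cell_meta[cell_meta$sample_id %in% keep_samples, , drop = FALSE]
  rx <- range(cm$embed_x); ry <- range(cm$embed_y)
  pad <- 0.02
  lims <- c(rx[1] - pad * diff(rx) - 1e-9, rx[2] + pad * diff(rx) + 1e-9,
            ry[1] - pad * diff(ry) - 1e-9, ry[2] + pad * diff(ry) + 1e-9)
  n <- config$grid
  sample_maps <- list()
  for (s in keep_samples) {
    pts <- cm[cm$sample_id == s, , drop = FALSE]
    if (nrow(pts) < min_cells) {
      warning("sample '", s, "' has fewer than ", min_cells,
              " cells; excluded from density maps")
      next
    }
    h <- c(MASS::bandwidth.nrd(pts$embed_x), MASS::bandwidth.nrd(pts$embed_y))
    h[h <= 0] <- 1e-3 * c(diff(rx), diff(ry))[h <= 0]
    h[h <= 0] <- 1e-6
    kd <- MASS::kde2d(pts$embed_x, pts$embed_y, h = h, n = n, lims = lims)
    z <- kd$z / sum(kd$z)
    sample_maps[[s]] <- z
    grid_x <- kd$x; grid_y <- kd$y
  }
  if (length(sample_maps) == 0) stop("no sample with enough cells")
  cond_of <- setNames(sample_meta$condition, sample_meta$sample_id)
  condition_maps <- lapply(setNames(nm = conds), function(cd) {
    ss <- names(sample_maps)[cond_of[names(sample_maps)] == cd]
    if (length(ss) == 0) return(NULL)
    Reduce(`+`, sample_maps[ss]) / length(ss)
  })
  condition_maps <- condition_maps[!vapply(condition_maps, is.null,
                                           logical(1))]
  out <- list(grid_x = grid_x, grid_y = grid_y,
              sample_maps = sample_maps,
              condition_maps = condition_maps,
              sample_condition = cond_of[names(sample_maps)])
  class(out) <- "nc_density_maps"
  out
}

#' Per-bin density difference between two conditions
#'
#' For every grid bin, the per-sample densities of condition A are compared
#' with those of condition B by a standardized two-sided Wilcoxon rank-sum
#' statistic (tie-corrected normal standardization, no continuity
#' correction). Positive values mark bins where condition A is enriched;
#' bins where all samples are tied (e.g. empty regions) get statistic 0.
#' Swapping the two conditions negates the map.
#'
#' @param maps An [density_maps()] result.
#' @param condition_a,condition_b Condition names (each needs >= 2 samples).
#' @return A grid x grid matrix of standardized statistics.
#' @export
density_difference <- function(maps, condition_a, condition_b) {
  stopifnot(inherits(maps, "nc_density_maps"))
  sa <- names(maps$sample_maps)[maps$sample_condition == condition_a]
  sb <- names(maps$sample_maps)[maps$sample_condition == condition_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("need >= 2 samples per condition")
  }
  dens <- vapply(c(sa, sb), function(s) as.vector(maps$sample_maps[[s]]),
                 numeric(length(maps$grid_x)^2))
  w <- wilcox_rows(dens, seq_along(sa), correct = FALSE)
  matrix(w$z_raw, nrow = length(maps$grid_x),
         dimnames = dimnames(maps$sample_maps[[1]]))
}
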