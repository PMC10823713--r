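#' Read a 10x-style Matrix Market count triple
#'
#' Loads a sparse genes x cells raw UMI count matrix from an \code{.mtx}
#' file plus features and barcodes TSVs. Duplicate gene symbols are
#' disambiguated deterministically by suffixing \code{.1}, \code{.2}, ...
#' in file order (first occurrence keeps the bare symbol); duplicate
#' barcodes are an error.
#'
#' @param matrix_path Path to the Matrix Market file.
#' @param features_path Path to the features TSV; the gene symbol is taken
#'   from the last of the first two columns present (10x convention: id,
#'   symbol) or the only column.
#' @param barcodes_path Path to the barcodes TSV (one barcode per line).
#' @return A sparse \code{dgCMatrix} (genes x cells) with dimnames.
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("malformed MTX file '", matrix_path,
                                         "': ", conditionMessage(e)))
  m <- as_dgc(m)
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  barcodes <- readLines(barcodes_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(symbols) != nrow(m)) {
    stop("features file has ", length(symbols), " rows but matrix has ",
         nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("barcodes file has ", length(barcodes), " rows but matrix has ",
         ncol(m), " columns")
  }
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes in ", barcodes_path)
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("count matrix must contain non-negative integers")
  }
  rownames(m) <- make.unique(symbols, sep = ".")
  colnames(m) <- barcodes
  m
}

#' Write a count matrix as a 10x-style Matrix Market triple
#'
#' Inverse of [read_counts_mtx()]: integer round-trips are exact.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths written.
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- as_dgc(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  fp <- file.path(dir, "features.tsv")
  bp <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(counts, mp)
  write.table(data.frame(id = rownames(counts), symbol = rownames(counts)),
              fp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writeLines(colnames(counts), bp)
  invisible(c(matrix = mp, features = fp, barcodes = bp))
}

#' Read gene signatures from a GMT file
#'
#' One signature per tab-separated line: name, description (discarded),
#' then gene symbols. Duplicate genes within a set are removed.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT line ", i, " defines an empty set")
    out[[fields[1]]] <- genes
  }
  out
}

#' Read a ligand-receptor pair table
#'
#' CSV with ligand and receptor gene columns (CellPhoneDB-style single-gene
#' pairs). Duplicate pairs are dropped, keeping first-seen order.
#'
#' @param path Path to the CSV file.
#' @param ligand_col,receptor_col Column names holding the ligand and
#'   receptor gene symbols.
#' @return A data.frame with columns \code{ligand}, \code{receptor}.
#' @export
read_lr_table <- function(path, ligand_col = "ligand",
                          receptor_col = "receptor") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = ",", header = TRUE,
                    stringsAsFactors = FALSE, quote = "\"")
  for (col in c(ligand_col, receptor_col)) {
    if (!col %in% names(tab)) stop("missing required column '", col, "'")
  }
  out <- data.frame(ligand = as.character(tab[[ligand_col]]),
                    receptor = as.character(tab[[receptor_col]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    nc_msg("ligand-receptor table '", path, "' is empty")
    return(out)
  }
  if (any(!nzchar(out$ligand)) || any(!nzchar(out$receptor))) {
    stop("empty ligand or receptor gene symbol in ", path)
  }
  out[!duplicated(paste(out$ligand, out$receptor, sep = "\r")), ,
      drop = FALSE]
}

#' Write a result table as TSV
#'
#' Deterministic output for any tabular module result: floats are formatted
#' at 6 significant digits, rows are sorted by the given keys (default: all
#' non-numeric columns left to right, then the first numeric column), and a
#' header is always written.
#'
#' @param result A data.frame.
#' @param path Output file path.
#' @param sort_keys Character vector of column names to sort by; \code{NULL}
#'   uses the default described above; \code{NA} keeps row order.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(result, path, sort_keys = NULL) {
  stopifnot(is.data.frame(result))
  result <- result[, !vapply(result, is.list, logical(1)), drop = FALSE]
  if (is.null(sort_keys)) {
    chr <- names(result)[!vapply(result, is.numeric, logical(1))]
    num <- names(result)[vapply(result, is.numeric, logical(1))]
    sort_keys <- c(chr, head(num, 1))
  }
  if (nrow(result) > 1 && length(sort_keys) > 0 && !anyNA(sort_keys)) {
    ord <- do.call(order, unname(result[, sort_keys, drop = FALSE]))
    result <- result[ord, , drop = FALSE]
  }
  fmt <- result
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- signif(fmt[[j]], 6)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_result_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}
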