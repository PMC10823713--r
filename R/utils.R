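#' @importFrom methods as is
#' @importFrom stats pnorm qnorm p.adjust median quantile rnorm runif rexp
#'   rbinom rmultinom rnbinom rgamma var cor cmdscale wilcox.test ks.test
#'   pchisq rank sd setNames aggregate
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

nc_msg <- function(...) message("[nichecompare] ", ...)

#' Library-size normalize a count matrix
#'
#' Per-cell scaling to a fixed total followed by log(1 + x): the package-wide
#' convention for "normalized expression" (signature scores, LR averages,
#' pseudobulk profiles all use it).
#'
#' @param counts A genes x cells matrix (sparse \code{dgCMatrix} or dense)
#'   of raw counts.
#' @param scale_total Per-cell total after scaling (default 1e4).
#' @return A sparse genes x cells matrix of log-normalized expression.
#' @export
normalize_counts <- function(counts, scale_total = 1e4) {
  counts <- as_dgc(counts)
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1  # empty cells stay all-zero
  sf <- scale_total / totals
  out <- counts %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  as_dgc(out)
}

as_dgc <- function(m) {
  if (is(m, "dgCMatrix")) return(m)
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Vectorised two-sided Mann-Whitney/Wilcoxon rank-sum over the rows of a
# matrix, normal approximation with tie correction (and optional continuity
# correction, matching stats::wilcox.test(exact = FALSE)). Returns the
# standardized statistic for group `in_idx` (positive = in-group larger) and
# the two-sided p. Rows with zero rank-sum variance (all values tied) get
# statistic 0 and p 1.
wilcox_rows <- function(m, in_idx, correct = TRUE) {
  m <- as.matrix(m)
  n <- ncol(m)
  n1 <- length(in_idx)
  n2 <- n - n1
  stopifnot(n1 >= 1, n2 >= 1)
  stat <- numeric(nrow(m))
  p <- numeric(nrow(m))
  z_raw <- numeric(nrow(m))
  mu <- n1 * n2 / 2
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    r <- rank(x)
    U <- sum(r[in_idx]) - n1 * (n1 + 1) / 2
    ties <- rle(sort(x))$lengths
    tiecor <- sum(ties^3 - ties)
    sig2 <- (n1 * n2 / 12) * ((n + 1) - tiecor / (n * (n - 1)))
    if (sig2 <= 0) {
      stat[i] <- 0; p[i] <- 1; z_raw[i] <- 0
      next
    }
    sig <- sqrt(sig2)
    d <- U - mu
    z_raw[i] <- d / sig
    cc <- if (correct) sign(d) * 0.5 else 0
    zc <- (d - cc) / sig
    stat[i] <- zc
    p[i] <- min(1, 2 * pnorm(-abs(zc)))
  }
  list(stat = stat, z_raw = z_raw, p = p)
}

# Signed probit transform of a two-sided p-value: the "p-value determined Z
# score". |z| is capped so that underflowing p never yields Inf.
p_to_z <- function(p, sign, cap = 37) {
  p <- pmax(p, .Machine$double.xmin)
  z <- qnorm(1 - p / 2)
  z <- pmin(z, cap)
  z * ifelse(sign == 0, 0, sign(sign))
}

# Deterministic integer sub-seed derivation, kept within 32-bit range.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
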