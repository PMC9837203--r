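#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample normalization for count matrices.  The reference sample is
#' the library whose 75th-percentile count is closest to the mean of the
#' per-sample 75th percentiles.  For every other sample, genes expressed in
#' both libraries contribute an M-value (log2 ratio of library-scaled
#' abundances) and an A-value (mean log2 abundance); after two-sided trimming
#' (default 30% of M-values and 5% of A-values from each tail), the log2
#' normalization factor is the precision-weighted mean of the surviving
#' M-values, with weights the inverse binomial (delta-method) variances.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param logratio_trim fraction of M-values trimmed from each tail.
#' @param abundance_trim fraction of A-values trimmed from each tail.
#' @param ref_column optional explicit reference sample (index or name).
#' @return named numeric vector of per-sample normalization factors
#'   (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05,
                        ref_column = NULL) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2, "need at least 2 samples")
  assert_that(all(counts >= 0), "counts must be non-negative")
  zero_lib <- colSums(counts) == 0
  if (any(zero_lib)) {
    stop_("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[zero_lib] %||% which(zero_lib), collapse = ", "))
  }
  lib <- colSums(counts)
  if (is.null(ref_column)) {
    q75 <- apply(counts, 2, quantile, probs = 0.75, type = 7, names = FALSE)
    ref <- which.min(abs(q75 - mean(q75)))
  } else {
    ref <- if (is.character(ref_column)) match(ref_column, colnames(counts))
           else as.integer(ref_column)
  }
  yr <- counts[, ref]
  nr <- lib[ref]
  logf <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(0)
    yk <- counts[, k]
    nk <- lib[k]
    keep <- yk > 0 & yr > 0
    if (!any(keep)) return(0)
    y1 <- yk[keep]; y2 <- yr[keep]
    M <- log2((y1 / nk) / (y2 / nr))
    A <- 0.5 * log2((y1 / nk) * (y2 / nr))
    w <- 1 / ((nk - y1) / (nk * y1) + (nr - y2) / (nr * y2))
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1L
    hiM <- n + 1L - loM
    loA <- floor(n * abundance_trim) + 1L
    hiA <- n + 1L - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(0)
    sum(w[keep2] * M[keep2]) / sum(w[keep2])
  }, numeric(1))
  f <- 2^logf
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' TMM-normalized expression (counts per million on effective library sizes)
#'
#' @param counts gene x sample count matrix.
#' @param factors optional precomputed [tmm_factors()].
#' @return matrix of normalized expression values.
#' @export
tmm_normalize <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  f <- factors %||% tmm_factors(counts)
  eff <- colSums(counts) * f
  sweep(counts, 2, eff, "/") * 1e6
}
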