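#' Reads-per-million normalization of a count matrix
#'
#' @param counts gene x sample matrix of non-negative counts (e.g. 4sU reads
#'   in the TSS..+3 kb window).
#' @param library_sizes optional per-sample library sizes; defaults to the
#'   column sums.
#' @return matrix of RPM values.
#' @export
nascent_rpm <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "counts must be non-negative")
  lib <- library_sizes %||% colSums(counts)
  assert_that(all(lib > 0), "library sizes must be positive")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Box statistics and pairwise Mann-Whitney tests per group
#'
#' Boxes are median and Q1-Q3 (linear-interpolation quantiles); whiskers
#' extend to the most extreme values within 1.5 x IQR of the box.
#'
#' @param groups named list of numeric vectors (one per gene class / phase).
#' @return list with `stats` (`data.table`: group, n, median, q1, q3,
#'   whisker_lo, whisker_hi) and `mw_p` (`data.table`: group_a, group_b, p).
#' @export
group_boxstats <- function(groups) {
  assert_that(is.list(groups) && !is.null(names(groups)) && length(groups) > 0,
              "groups must be a non-empty named list")
  stats <- rbindlist(lapply(names(groups), function(g) {
    v <- groups[[g]][!is.na(groups[[g]])]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.table(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  }))
  pairs <- if (length(groups) > 1) t(utils::combn(names(groups), 2)) else
    matrix(character(), ncol = 2)
  mw <- rbindlist(lapply(seq_len(nrow(pairs)), function(i) {
    a <- groups[[pairs[i, 1]]]; b <- groups[[pairs[i, 2]]]
    p <- suppressWarnings(wilcox.test(a, b)$p.value)
    data.table(group_a = pairs[i, 1], group_b = pairs[i, 2], p = p)
  }))
  list(stats = stats, mw_p = mw)
}

#' MA statistics between two phases
#'
#' Per-gene log2 fold change (phase a over phase b, pseudocount in RPM) and
#' mean abundance, with the percentage of genes up (fold change strictly
#' above `threshold`) or down (strictly below `1/threshold`).
#'
#' @param rpm_a,rpm_b named numeric vectors of per-gene RPM (same genes).
#' @param threshold fold-change threshold (strict).
#' @param pseudocount pseudocount in RPM units.
#' @return list with `table` (`gene_id, log2fc, mean_abundance`),
#'   `pct_up`, `pct_down`.
#' @export
ma_stats <- function(rpm_a, rpm_b, threshold = 1.2, pseudocount = 0.5) {
  assert_that(identical(names(rpm_a), names(rpm_b)),
              "rpm_a and rpm_b must cover the same genes in the same order")
  assert_that(threshold > 1, "threshold must exceed 1")
  fa <- rpm_a + pseudocount
  fb <- rpm_b + pseudocount
  fc <- fa / fb
  tab <- data.table(gene_id = names(rpm_a), log2fc = log2(fc),
                    mean_abundance = (rpm_a + rpm_b) / 2)
  list(table = tab,
       pct_up = 100 * mean(fc > threshold),
       pct_down = 100 * mean(fc < 1 / threshold))
}

#' Select differentially expressed genes across contrasts
#'
#' Union over all supplied contrast tables of genes with fold change strictly
#' above `fc_cutoff` in either direction and FDR strictly below `fdr_cutoff`.
#'
#' @param de_tables named list of `data.table(gene_id, log2fc, fdr)`.
#' @param fc_cutoff fold-change cutoff (linear scale, strict).
#' @param fdr_cutoff FDR cutoff (strict).
#' @return sorted character vector of gene_ids.
#' @export
select_de_genes <- function(de_tables, fc_cutoff = 2, fdr_cutoff = 0.05) {
  assert_that(is.list(de_tables) && length(de_tables) > 0,
              "de_tables must be a non-empty list")
  hits <- lapply(de_tables, function(tab) {
    assert_that(all(c("gene_id", "log2fc", "fdr") %in% names(tab)),
                "DE tables need gene_id, log2fc, fdr")
    assert_that(all(tab$fdr >= 0 & tab$fdr <= 1), "fdr must lie in [0, 1]")
    tab$gene_id[abs(tab$log2fc) > log2(fc_cutoff) & tab$fdr < fdr_cutoff]
  })
  sort(unique(unlist(hits, use.names = FALSE)))
}

#' Per-gene expression relative to the gene's geometric mean
#'
#' `log2((x + 1) / geomean(x + 1))` across each gene's samples; every row of
#' the result has mean zero.
#'
#' @param normalized gene x sample matrix of normalized expression.
#' @return matrix of per-gene log2 ratios.
#' @export
relative_to_geomean <- function(normalized) {
  m <- log2(as.matrix(normalized) + 1)
  m - rowMeans(m)
}
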