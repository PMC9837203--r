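# Signed maximum deviation of the GSEA running sum for hits at the given
# 1-based positions of the ranked list (positions sorted increasing).
# Hit increments are |score|^p / sum(|score|^p over hits); misses decrement
# by 1/(N - n).  Only the points immediately before and after each hit can
# be extreme, so the walk is O(n) in the set size.
gsea_es <- function(positions, hit_weights, n_total) {
  n <- length(positions)
  miss_dec <- 1 / (n_total - n)
  wsum <- sum(hit_weights)
  inc <- if (wsum > 0) hit_weights / wsum else rep(1 / n, n)
  cum_inc <- cumsum(inc)
  before <- c(0, head(cum_inc, -1)) - (positions - seq_len(n)) * miss_dec
  after <- cum_inc - (positions - seq_len(n)) * miss_dec
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis with permutation NES
#'
#' Genes are ordered by decreasing score (ties broken by gene name for
#' determinism).  The enrichment score (ES) is the signed maximum deviation
#' of the running sum in which set members increment by
#' `|score|^weight_p / sum` and non-members decrement by `1/(N - n)`.  The
#' null is built by gene-label permutation: random (or, when requested,
#' exhaustive) placements of `n` labels among the `N` ranked genes, scored
#' with those genes' weights.  NES is the ES divided by the mean absolute
#' permutation ES of matching sign; the nominal p is
#' `(1 + #same-sign |ES_perm| >= |ES|) / (1 + #same-sign)`, and FDR across
#' gene sets is Benjamini-Hochberg on the nominal p values.
#'
#' @param scores named numeric vector, gene -> ranking score.
#' @param gene_sets named list of character vectors (each a subset of the
#'   ranked genes; a set with no ranked member is an error).
#' @param n_perm number of label permutations.
#' @param weight_p weighting exponent on |score| for hit increments.
#' @param seed integer seed for the permutations.
#' @param exhaustive if `TRUE`, enumerate every possible label placement
#'   instead of sampling (feasible for small universes).
#' @return `data.table(gene_set, size, ES, NES, p, fdr, n_perm)`.
#' @export
gsea_preranked <- function(scores, gene_sets, n_perm = 10000L, weight_p = 1,
                           seed = 1L, exhaustive = FALSE) {
  assert_that(!is.null(names(scores)) && !anyDuplicated(names(scores)),
              "scores must be uniquely named by gene")
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  ord <- order(-scores, names(scores), method = "radix")
  ranked <- names(scores)[ord]
  w_all <- abs(scores[ord])^weight_p
  N <- length(ranked)

  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], ranked)
    if (length(members) == 0L) {
      stop_("gene set '%s' has no member in the ranked universe", nm)
    }
    n <- length(members)
    assert_that(n < N, "gene set '%s' must be a proper subset of the universe", nm)
    pos <- sort(match(members, ranked))
    es <- gsea_es(pos, w_all[pos], N)

    if (exhaustive) {
      placements <- utils::combn(N, n)
      perm_es <- apply(placements, 2, function(p) gsea_es(p, w_all[p], N))
      np <- ncol(placements)
    } else {
      set.seed(as.integer(seed))
      perm_es <- vapply(seq_len(n_perm), function(i) {
        p <- sort(sample.int(N, n))
        gsea_es(p, w_all[p], N)
      }, numeric(1))
      np <- n_perm
    }
    same <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.table(gene_set = nm, size = n, ES = es, NES = nes, p = p,
               n_perm = np)
  })
  out <- rbindlist(rows)
  out[, fdr := bh_fdr(p)]
  setcolorder(out, c("gene_set", "size", "ES", "NES", "p", "fdr", "n_perm"))
  out[]
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param p_values numeric vector of p values.
#' @return adjusted values (monotone in p-rank, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  p.adjust(p_values, method = "BH")
}
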