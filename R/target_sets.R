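annotation_to_granges <- function(annotation) {
  validate_annotation(annotation)
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$tss + 1L, width = 1L),
    strand = annotation$strand,
    gene_id = annotation$gene_id
  )
}

#' Genes whose promoter window overlaps at least one peak
#'
#' A gene is a target of a peak set iff any peak overlaps its strand-aware
#' promoter window (default -500..+1500 bp around the TSS) by at least 1 bp.
#' Peak intervals are 0-based half-open (BED).
#'
#' @param peaks `data.table`/`data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `score`.
#' @param annotation TSS annotation table.
#' @param window promoter window in bp relative to the TSS.
#' @return character vector of target gene_ids (annotation order).
#' @export
assign_peaks_to_promoters <- function(peaks, annotation, window = c(-500, 1500)) {
  assert_that(all(c("chrom", "start", "end") %in% names(peaks)),
              "peaks need chrom, start, end")
  assert_that(all(peaks$start < peaks$end), "peak intervals need start < end")
  gr <- annotation_to_granges(annotation)
  prom <- GenomicRanges::promoters(gr, upstream = -window[1],
                                   downstream = window[2])
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  hits <- GenomicRanges::findOverlaps(prom, pk, minoverlap = 1L,
                                      ignore.strand = TRUE)
  annotation$gene_id[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Union of per-phase target sets for one factor
#' @param per_phase_sets list of character vectors of gene_ids.
#' @return character vector (sorted union).
#' @export
union_targets <- function(per_phase_sets) {
  sort(unique(unlist(per_phase_sets, use.names = FALSE)))
}

#' Partition polycomb targets into vPRC1/cPRC1/PRC2 vs vPRC1-only classes
#'
#' `vcp` = promoters bound by RING1B, RYBP, CBX7 and EZH2 (vPRC1 + cPRC1 +
#' PRC2); `v_only` = bound by RING1B and RYBP but by neither CBX7 nor EZH2.
#' Promoters bound by an intermediate combination fall into neither class,
#' so the two classes are always disjoint.
#'
#' @param ring1b,rybp,cbx7,ezh2 character vectors of target gene_ids.
#' @return list with `vcp_targets` and `v_only_targets` (sorted).
#' @export
classify_prc_classes <- function(ring1b, rybp, cbx7, ezh2) {
  core <- intersect(ring1b, rybp)
  vcp <- intersect(intersect(core, cbx7), ezh2)
  v_only <- setdiff(core, union(cbx7, ezh2))
  list(vcp_targets = sort(vcp), v_only_targets = sort(v_only))
}

#' Select unbound control genes
#'
#' Controls are genes outside the pooled target set whose nascent G1/G2
#' log2 fold change lies strictly inside the +-`band` window (phase-inert
#' unbound genes).
#'
#' @param all_genes character vector of all gene_ids.
#' @param target_union character vector of target gene_ids.
#' @param nascent_log2fc_g1_g2 named numeric, gene_id -> log2 FC (G1/G2).
#' @param band half-width of the acceptance window (strict inequality).
#' @return character vector of control gene_ids.
#' @export
select_unbound_controls <- function(all_genes, target_union,
                                    nascent_log2fc_g1_g2, band = 0.2) {
  unbound <- setdiff(all_genes, target_union)
  fc <- nascent_log2fc_g1_g2[unbound]
  sort(unbound[!is.na(fc) & abs(fc) < band])
}

#' Fraction of one gene set contained in another
#'
#' Reports the raw percentage `100 * |a intersect b| / |a|`, a one-decimal
#' round-half-up value, and a one-decimal truncated display value (the
#' convention under which 1575/1678 prints as 93.8).
#'
#' @param a,b character vectors of gene_ids; `a` must be non-empty.
#' @return list with `n_overlap`, `n_total`, `fraction` (raw percentage),
#'   `display_rounded` and `display_truncated`.
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(a); b <- unique(b)
  assert_that(length(a) > 0, "set a must be non-empty")
  n <- length(intersect(a, b))
  pct <- 100 * n / length(a)
  list(n_overlap = n, n_total = length(a), fraction = pct,
       display_rounded = round_half_up(pct, 1L),
       display_truncated = trunc_decimal(pct, 1L))
}
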