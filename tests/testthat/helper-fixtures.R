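library(data.table)

# small, fast simulation configurations used across tests
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chrom = 1L, chrom_length = 1e6, n_genes = 10L,
             depth = 20000, ...)
}

small_chip_config <- function(seed = 1L, chrom_length = 2e6, depth = 30000,
                              ...) {
  sim_config(seed = seed, n_chrom = 1L, chrom_length = chrom_length,
             n_genes = 60L,
             group_fractions = c(vcp = 0.3, v_only = 0.3, unbound = 0.4),
             depth = depth, ...)
}

# a constant-valued track over one chromosome
constant_track <- function(value, n_bins = 400L, chrom = "chr1",
                           normalized = TRUE, library_size = 1e6, ...) {
  bins <- setNames(list(rep(value, n_bins)), chrom)
  signal_track(bins, bin_size = 10L, normalized = normalized,
               library_size = library_size, ...)
}

# deterministic single-viewpoint capture fixture on a uniform fragment map:
# distance-decay background round(1000/d), a 3-fragment interaction at
# summit +- 1 with enrichment (2, 6, 2), G2 boost, knockout collapsed to
# background; scores are 2.5 x enrichment
toy_capture <- function(n_frag = 400L, frag_len = 100L, vp = 200L,
                        summit = 350L, boost = 2) {
  fragmap <- data.table(chrom = "chr1",
                        start = (seq_len(n_frag) - 1L) * frag_len,
                        end = seq_len(n_frag) * frag_len,
                        frag_index = seq_len(n_frag))
  enr <- function(idx, geno, phase) {
    e <- rep(1, length(idx))
    e[idx %in% (summit + c(-1L, 0L, 1L))] <- c(2, 6, 2)
    if (geno == "KO") e[] <- 1
    else if (phase == "G2") e[e > 1] <- e[e > 1] * boost
    e
  }
  rows <- lapply(c("G1_WT", "G2_WT", "G1_KO", "G2_KO"), function(cond) {
    ph <- sub("_.*", "", cond); geno <- sub(".*_", "", cond)
    d <- pmax(abs(fragmap$frag_index - vp), 1L)
    e <- enr(fragmap$frag_index, geno, ph)
    sc <- if (geno == "KO") rep(1, length(e)) else
      ifelse(e > 1 & ph == "G2", e / boost, e)
    data.table(viewpoint_id = "gene_v", chrom = "chr1",
               frag_index = fragmap$frag_index, frag_start = fragmap$start,
               frag_end = fragmap$end, condition = cond,
               counts = round(1000 / d) * e,
               score = 2.5 * sc)
  })
  list(table = rbindlist(rows), fragmap = fragmap,
       viewpoints = data.table(gene_id = "gene_v", vp_frag = vp),
       atac = data.table(chrom = "chr1",
                         start = (summit - 2L) * frag_len,
                         end = (summit + 1L) * frag_len, score = 100),
       summit = summit, vp = vp, boost = boost)
}

# mirror a toy capture dataset: reverse every chromosome coordinate-wise
mirror_capture <- function(fx) {
  n <- nrow(fx$fragmap)
  L <- max(fx$fragmap$end)
  tab <- copy(fx$table)
  tab[, `:=`(frag_index = n + 1L - frag_index,
             frag_start = L - frag_end, frag_end = L - frag_start)]
  setorder(tab, condition, frag_index)
  atac <- copy(fx$atac)[, `:=`(start = L - end, end = L - start)]
  list(table = tab, fragmap = NULL,
       viewpoints = data.table(gene_id = "gene_v", vp_frag = n + 1L - fx$vp),
       atac = atac, summit = n + 1L - fx$summit, vp = n + 1L - fx$vp,
       boost = fx$boost)
}
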