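chip_factors <- c("RING1B", "RYBP", "CBX7", "EZH2", "H2AK119ub1")
chip_phases <- c("G1", "S", "G2")

factor_phase_ratio <- function(config, factor) {
  switch(factor,
         RING1B = config$ring1b_phase_ratio,
         RYBP = config$rybp_phase_ratio,
         CBX7 = config$cbx7_phase_ratio,
         H2AK119ub1 = config$h2aub_phase_ratio,
         EZH2 = 1.0,
         stop_("unknown factor '%s'", factor))
}

#' Gene groups bound by a chromatin factor
#'
#' RING1B, RYBP and H2AK119ub1 mark all polycomb-bound promoters
#' (`vcp` and `v_only`); CBX7 and EZH2 mark the `vcp` class only.
#'
#' @param factor one of RING1B, RYBP, CBX7, EZH2, H2AK119ub1.
#' @return character vector of bound group labels.
#' @export
factor_bound_groups <- function(factor) {
  switch(factor,
         RING1B = c("vcp", "v_only"),
         RYBP = c("vcp", "v_only"),
         H2AK119ub1 = c("vcp", "v_only"),
         CBX7 = "vcp",
         EZH2 = "vcp",
         stop_("unknown factor '%s'", factor))
}

#' Ground-truth table for a simulated gene universe
#'
#' Assigns every gene a binding group (`vcp` = vPRC1+cPRC1+PRC2 target,
#' `v_only` = vPRC1-only target, `unbound`), the implied per-factor/per-phase
#' true occupancy multipliers, the true per-phase nascent-rate multipliers
#' (wild type, G1 baseline), and a retinoic-acid cluster label: bound genes
#' form the PRC1-repressed cluster II (half of them the G1-preferential
#' sub-cluster II-A), unbound genes cycle through cluster I (RA-induced),
#' cluster III (RA-repressed) and `none`.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @return `data.table`, one row per gene.
#' @export
make_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  n <- nrow(annotation)
  n_vcp <- round(config$group_fractions[["vcp"]] * n)
  n_vonly <- round(config$group_fractions[["v_only"]] * n)
  n_vcp <- min(n_vcp, n)
  n_vonly <- min(n_vonly, n - n_vcp)
  seed_stream(config$seed, "truth")
  idx <- sample.int(n)
  group <- rep("unbound", n)
  group[idx[seq_len(n_vcp)]] <- "vcp"
  if (n_vonly > 0) group[idx[n_vcp + seq_len(n_vonly)]] <- "v_only"

  truth <- data.table(gene_id = annotation$gene_id,
                      chrom = annotation$chrom, tss = annotation$tss,
                      strand = annotation$strand, group = group)

  # RA clusters are subsets: only some bound promoters respond to RA (and are
  # de-repressed by RING1B loss -> cluster II), and only some unbound genes are
  # RA-induced (I) or RA-repressed (III); the rest of the transcriptome is
  # inert and anchors between-sample normalization.
  bound <- which(group != "unbound")
  unb <- which(group == "unbound")
  cluster <- rep("none", n)
  rgc <- config$ra_genes_per_cluster
  n_sub <- min(rgc, floor(length(bound) / 2))
  if (n_sub > 0) {
    pick <- sample(bound, 2L * n_sub)
    cluster[pick[seq_len(n_sub)]] <- "II-A"
    cluster[pick[n_sub + seq_len(n_sub)]] <- "II-B"
  }
  n_ind <- min(rgc, floor(length(unb) / 4))
  if (n_ind > 0) {
    pick <- sample(unb, 2L * n_ind)
    cluster[pick[seq_len(n_ind)]] <- "I"
    cluster[pick[n_ind + seq_len(n_ind)]] <- "III"
  }
  truth[, cluster := cluster]

  for (f in chip_factors) {
    mult <- phase_multipliers(factor_phase_ratio(config, f))
    is_bound <- truth$group %in% factor_bound_groups(f)
    for (p in chip_phases) {
      truth[[paste("occ", f, p, sep = "_")]] <- ifelse(is_bound, mult[[p]], 0)
    }
  }
  r <- config$nascent_g1_over_g2
  nas <- c(G1 = r, S = sqrt(r), G2 = 1)   # G1-high repression pattern
  for (p in chip_phases) {
    truth[[paste0("nascent_", p)]] <-
      ifelse(truth$group == "unbound", 1, nas[[p]])
  }
  truth[]
}

triangular_kernel <- function(half_width_bins = 100L) {
  k <- seq.int(-half_width_bins, half_width_bins)
  w <- 1 - abs(k) / half_width_bins
  list(offsets = k, weights = w / sum(w))
}

#' Simulate cell-cycle-resolved ChIP-seq tracks, peaks and truth
#'
#' Per factor and phase, bin counts are Poisson with rate
#' `background + occupancy * kernel` around the TSS of bound genes; the
#' occupancy kernel is a symmetric triangle of half-width 1 kb.  Per-phase
#' occupancy follows the configured G2/G1 ratios (S at the geometric
#' midpoint).  Every library is sequenced to the same expected depth:
#' the per-gene expected signal at the G1 baseline is
#' `signal_fraction * depth / n_bound`, and the background rate absorbs the
#' remainder of the library.  Matched input tracks carry background only.
#' Peak intervals (TSS +- 1 kb) are emitted at true bound promoters.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @param factors,phases subsets of the simulated factors/phases (restricting
#'   them leaves the truth table and seeding of shared streams unchanged).
#' @param truth optional precomputed [make_truth()] table.
#' @return list with `tracks` (named `FACTOR_PHASE` -> raw [signal_track()]),
#'   `inputs` (named by phase), `peaks` (named `FACTOR_PHASE` -> sorted
#'   `data.table(chrom, start, end, score)`), and `truth`.
#' @export
simulate_chip <- function(config, annotation, factors = chip_factors,
                          phases = chip_phases, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  factors <- match.arg(factors, chip_factors, several.ok = TRUE)
  phases <- match.arg(phases, chip_phases, several.ok = TRUE)
  if (is.null(truth)) truth <- make_truth(config, annotation)

  bin <- 10L
  n_bins <- ceiling(config$chrom_length / bin)
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  kern <- triangular_kernel(1000L %/% bin)
  ann <- copy(as.data.table(annotation))
  ann[, bin_idx := tss %/% bin + 1L]

  seed_stream(config$seed, "chip")
  tracks <- list(); peaks <- list()
  for (f in factors) {
    mult <- phase_multipliers(factor_phase_ratio(config, f))
    is_bound <- truth$group %in% factor_bound_groups(f)
    bound_ids <- truth$gene_id[is_bound]
    n_bound <- length(bound_ids)
    e_base <- if (n_bound > 0) config$signal_fraction * config$depth / n_bound else 0
    for (p in phases) {
      occ <- e_base * mult[[p]]
      mass <- occ * n_bound
      bg <- (config$depth - mass) / (n_bins * config$n_chrom)
      assert_that(bg > 0, "signal mass exceeds depth for %s %s", f, p)
      bins <- list()
      for (ch in chroms) {
        rate <- rep(bg, n_bins)
        g <- ann[chrom == ch & gene_id %in% bound_ids]
        for (b in g$bin_idx) {
          pos <- b + kern$offsets
          ok <- pos >= 1L & pos <= n_bins
          rate[pos[ok]] <- rate[pos[ok]] + occ * kern$weights[ok]
        }
        bins[[ch]] <- rpois(n_bins, rate)
      }
      tr <- signal_track(bins, bin_size = bin, factor = f, phase = p,
                         library_size = sum(vapply(bins, sum, numeric(1))))
      tracks[[paste(f, p, sep = "_")]] <- tr
      pk <- ann[gene_id %in% bound_ids,
                .(chrom, start = pmax(tss - 1000L, 0L),
                  end = pmin(tss + 1000L, config$chrom_length),
                  score = occ)]
      setorder(pk, chrom, start)
      peaks[[paste(f, p, sep = "_")]] <- pk
    }
  }

  inputs <- list()
  for (p in phases) {
    bg <- config$depth / (n_bins * config$n_chrom)
    bins <- lapply(setNames(chroms, chroms), function(ch) rpois(n_bins, bg))
    inputs[[p]] <- signal_track(bins, bin_size = bin, factor = "input",
                                phase = p,
                                library_size = sum(vapply(bins, sum, numeric(1))))
  }
  list(tracks = tracks, inputs = inputs, peaks = peaks, truth = truth)
}
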