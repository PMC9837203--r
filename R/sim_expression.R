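rnb <- function(n, mu, dispersion) {
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate nascent-RNA (4sU-style) counts per phase and genotype
#'
#' Per-gene counts are negative binomial.  In wild type, bound genes follow
#' the configured G1/G2 nascent ratio (S at the geometric midpoint, G1 high);
#' unbound genes are phase-invariant.  The knockout genotype multiplies the
#' S and G2 means of bound genes by the configured derepression factors
#' (G1 multiplier 1 by default), modelling loss of PRC1-mediated repression
#' restricted to S/G2.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @param truth [make_truth()] table for the same genes.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (`data.table(sample_id, phase, genotype)`), `mu` (expected counts) and
#'   `truth`.
#' @export
simulate_nascent <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  assert_that(identical(truth$gene_id, annotation$gene_id),
              "truth and annotation must describe the same genes in order")
  seed_stream(config$seed, "nascent")
  n <- nrow(truth)
  base <- rlnorm(n, config$expr_base_meanlog, config$expr_base_sdlog)
  samples <- CJ(genotype = c("WT", "KO"), phase = chip_phases, sorted = FALSE)
  samples[, sample_id := paste(phase, genotype, sep = "_")]
  setcolorder(samples, c("sample_id", "phase", "genotype"))
  mu <- matrix(0, n, nrow(samples), dimnames = list(truth$gene_id, samples$sample_id))
  bound <- truth$group != "unbound"
  for (j in seq_len(nrow(samples))) {
    p <- samples$phase[j]
    m <- base * truth[[paste0("nascent_", p)]]
    if (samples$genotype[j] == "KO") {
      m[bound] <- m[bound] * config$ko_derepression[[p]]
    }
    mu[, j] <- m
  }
  counts <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                   nrow = n, dimnames = dimnames(mu))
  list(counts = counts, samples = samples, mu = mu, truth = truth)
}

ra_condition_mean <- function(config, cluster, treatment, phase) {
  fold <- config$ra_effect_fold
  pref <- phase_multipliers(config$ra_g1_pref)
  # pref is G2-high by construction; the II-A preference is G1-high -> invert
  g1pref <- c(G1 = pref[["G2"]], S = pref[["S"]], G2 = 1)
  if (treatment == "t0") return(1)
  switch(cluster,
         "I" = fold,
         "II-B" = if (treatment == "IAA6") fold^2 else fold,
         "II-A" = if (treatment == "IAA6") fold^2 else fold * g1pref[[phase]],
         "III" = 1 / fold,
         "none" = 1)
}

#' Simulate the retinoic-acid differentiation expression matrix
#'
#' Genes carry their truth cluster labels: cluster I responds to RA induction
#' only, cluster II responds to RA and is further amplified by RING1B
#' depletion (IAA), with sub-cluster II-A additionally preferring G1 over S
#' over G2 in the untreated 6 h samples; cluster III is repressed by RA;
#' `none` genes are flat.  Counts are negative binomial with `ra_n_rep`
#' replicate libraries per phase x treatment condition.  Per-contrast
#' differential-expression tables (log2 fold change from normalized means,
#' Welch t-test on log2 counts-per-million across replicates,
#' Benjamini-Hochberg FDR) are computed from the simulated counts.
#'
#' @param config a [sim_config()].
#' @param truth [make_truth()] table (cluster labels assigned).
#' @return list with `counts` (gene x sample matrix), `samples`
#'   (`sample_id, phase, treatment, replicate`), `de_tables` (named list of
#'   `data.table(gene_id, log2fc, fdr)`), `mu`, and `truth`.
#' @export
simulate_ra_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(all(c("gene_id", "cluster") %in% names(truth)),
              "truth must carry gene_id and cluster labels")
  seed_stream(config$seed, "ra")
  n <- nrow(truth)
  base <- rlnorm(n, config$expr_base_meanlog, config$expr_base_sdlog)
  conds <- CJ(treatment = c("t0", "UNT6", "IAA6"), phase = chip_phases,
              sorted = FALSE)
  samples <- conds[rep(seq_len(nrow(conds)), each = config$ra_n_rep)]
  samples[, replicate := rep(seq_len(config$ra_n_rep), nrow(conds))]
  samples[, sample_id := paste(phase, treatment, paste0("r", replicate), sep = "_")]
  setcolorder(samples, c("sample_id", "phase", "treatment", "replicate"))

  mult <- matrix(1, n, nrow(conds))
  for (j in seq_len(nrow(conds))) {
    mult[, j] <- vapply(truth$cluster, ra_condition_mean, numeric(1),
                        config = config, treatment = conds$treatment[j],
                        phase = conds$phase[j])
  }
  mu <- base * mult[, rep(seq_len(nrow(conds)), each = config$ra_n_rep)]
  dimnames(mu) <- list(truth$gene_id, samples$sample_id)
  counts <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                   nrow = n, dimnames = dimnames(mu))

  de_tables <- ra_de_tables(counts, samples)
  list(counts = counts, samples = samples, de_tables = de_tables, mu = mu,
       truth = truth)
}

# Row-wise Welch t-test on matrices of equal row count.
welch_row_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(abs(ma - mb)[degen] < 1e-12, 1, 0)
  p
}

de_contrast <- function(norm, samples, sel_a, sel_b) {
  a <- norm[, samples$sample_id[sel_a], drop = FALSE]
  b <- norm[, samples$sample_id[sel_b], drop = FALSE]
  lfc <- log2((rowMeans(a) + 0.5) / (rowMeans(b) + 0.5))
  p <- welch_row_p(log2(a + 1), log2(b + 1))
  data.table(gene_id = rownames(norm), log2fc = lfc,
             fdr = p.adjust(p, method = "BH"))
}

#' Differential-expression tables for the RA design
#'
#' Contrasts: per phase, 6 h untreated vs 0 h and 6 h IAA vs 0 h; plus the
#' phase contrasts G1 vs S and G1 vs G2 within the 6 h untreated samples
#' (the rankings used for phase-preference enrichment analysis).  Counts are
#' TMM-normalized before fold changes and tests, so strong induction of one
#' gene group does not masquerade as repression of the rest; fold changes
#' come from mean normalized expression (pseudocount 0.5) and p values from
#' Welch t-tests on log2 normalized expression across replicates, adjusted
#' by Benjamini-Hochberg within each contrast.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample sheet as produced by [simulate_ra_expression()].
#' @return named list of `data.table(gene_id, log2fc, fdr)`.
#' @export
ra_de_tables <- function(counts, samples) {
  counts <- tmm_normalize(counts)
  out <- list()
  for (p in unique(samples$phase)) {
    for (tr in c("UNT6", "IAA6")) {
      nm <- sprintf("%s_%s_vs_t0", p, tr)
      out[[nm]] <- de_contrast(counts, samples,
                               samples$phase == p & samples$treatment == tr,
                               samples$phase == p & samples$treatment == "t0")
    }
  }
  for (other in c("S", "G2")) {
    nm <- sprintf("G1_vs_%s_UNT6", other)
    out[[nm]] <- de_contrast(counts, samples,
                             samples$phase == "G1" & samples$treatment == "UNT6",
                             samples$phase == other & samples$treatment == "UNT6")
  }
  out
}
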