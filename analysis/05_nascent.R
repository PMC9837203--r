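#!/usr/bin/env Rscript
# Stage 5: nascent-RNA repression statistics.
#
# Quantifies the 4sU-style counts as reads per million, summarizes target
# versus control genes per phase (median/quartile boxes, 1.5 x IQR whiskers,
# pairwise Mann-Whitney tests) and computes the G1-vs-G2 MA statistics with
# the 1.2-fold threshold.  Because reads-per-million shares its denominator
# across genes, the repression recovery is also measured on a
# transcriptome-realistic universe (10,000 genes, 5% polycomb-bound) where
# bound promoters are a small fraction of the library.

suppressMessages({library(cyclechrom); library(data.table)})

stopifnot(file.exists("results/data/nascent_counts.tsv"))  # run 01 first
counts <- read_counts("results/data/nascent_counts.tsv")
truth <- fread("results/data/truth.tsv")
cfgp <- pipeline_config()
outdir <- "results/nascent"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rpm <- nascent_rpm(counts)
classes <- list(vcp = truth[group == "vcp", gene_id],
                v_only = truth[group == "v_only", gene_id],
                unbound = truth[group == "unbound", gene_id])
groups <- list()
for (cl in names(classes)) {
  for (p in c("G1", "S", "G2")) {
    groups[[paste(cl, p, sep = "_")]] <- rpm[classes[[cl]], paste0(p, "_WT")]
  }
}
bs <- group_boxstats(groups)
fwrite(bs$stats, file.path(outdir, "boxstats.tsv"), sep = "\t")
fwrite(bs$mw_p, file.path(outdir, "mann_whitney.tsv"), sep = "\t")
p_vcp <- bs$mw_p[group_a == "vcp_G1" & group_b == "vcp_G2", p]
cat(sprintf("vcp targets: G1 vs G2 Mann-Whitney p = %.3g\n", p_vcp))

ma <- ma_stats(rpm[, "G1_WT"], rpm[, "G2_WT"], threshold = cfgp$ma_threshold,
               pseudocount = cfgp$pseudocount)
fwrite(ma$table, file.path(outdir, "ma_table.tsv"), sep = "\t")
bound <- truth[group != "unbound", gene_id]
ma_b <- ma_stats(rpm[bound, "G1_WT"], rpm[bound, "G2_WT"],
                 threshold = cfgp$ma_threshold)
cat(sprintf("bound genes with G1/G2 fold change > 1.2: %.1f%% up, %.1f%% down\n",
            ma_b$pct_up, ma_b$pct_down))

# repression recovery at transcriptome-realistic composition
rcfg <- sim_config(seed = 2L, n_genes = 10000L, n_chrom = 4L,
                   chrom_length = 65e6, nascent_g1_over_g2 = 2.0,
                   group_fractions = c(vcp = 0.025, v_only = 0.025,
                                       unbound = 0.95))
rann <- generate_annotation(rcfg)
rtruth <- make_truth(rcfg, rann)
rrpm <- nascent_rpm(simulate_nascent(rcfg, rann, rtruth)$counts)
rbound <- rtruth$gene_id[rtruth$group != "unbound"]
med <- median(promoter_log2fc(rrpm[, "G1_WT"], rrpm[, "G2_WT"])[rbound])
med_ko <- median(promoter_log2fc(rrpm[, "G2_KO"], rrpm[, "G2_WT"])[rbound])
cat(sprintf("recovered median log2FC(G1/G2) at %d bound genes: %.3f (simulated: %.3f)\n",
            length(rbound), med, log2(2)))
cat(sprintf("knockout de-repression in G2, median log2FC(KO/WT): %.3f (simulated: %.3f)\n",
            med_ko, log2(3)))
fwrite(data.table(quantity = c("median_log2fc_g1_g2", "median_log2fc_ko_wt_g2"),
                  value = c(med, med_ko), simulated = c(log2(2), log2(3)),
                  n = length(rbound)),
       file.path(outdir, "recovery.tsv"), sep = "\t")
cat("done: results/nascent\n")
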