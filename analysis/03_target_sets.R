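#!/usr/bin/env Rscript
# Stage 3: polycomb target classification.
#
# Assigns peaks to strand-aware promoter windows, pools per-phase target sets
# per factor, partitions targets into the vPRC1/cPRC1/PRC2 class (bound by
# RING1B, RYBP, CBX7 and EZH2) versus the vPRC1-only class (RING1B and RYBP
# but neither CBX7 nor EZH2), picks phase-inert unbound control genes from
# the nascent data, and reports how well the recovered classes match the
# simulated truth.

suppressMessages({library(cyclechrom); library(data.table)})

stopifnot(file.exists("results/data/tss.bed"))  # run 01_simulate.R first
annotation <- read_tss_table("results/data/tss.bed")
truth <- fread("results/data/truth.tsv")
cfgp <- pipeline_config()
outdir <- "results/targets"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

factors <- c("RING1B", "RYBP", "CBX7", "EZH2", "H2AK119ub1")
sets <- list()
for (f in factors) {
  per_phase <- lapply(c("G1", "S", "G2"), function(p) {
    path <- sprintf("results/data/peaks_%s_%s.bed", f, p)
    assign_peaks_to_promoters(read_peaks(path), annotation,
                              window = cfgp$promoter_window)
  })
  sets[[f]] <- union_targets(per_phase)
  cat(sprintf("%-11s pooled targets: %d (per phase: %s)\n", f,
              length(sets[[f]]), paste(lengths(per_phase), collapse = "/")))
}

classes <- classify_prc_classes(sets$RING1B, sets$RYBP, sets$CBX7, sets$EZH2)
cat(sprintf("classes: %d vcp, %d v_only\n", length(classes$vcp_targets),
            length(classes$v_only_targets)))

nascent <- read_counts("results/data/nascent_counts.tsv")
rpm <- nascent_rpm(nascent)
nas_fc <- promoter_log2fc(rpm[, "G1_WT"], rpm[, "G2_WT"], cfgp$pseudocount)
controls <- select_unbound_controls(annotation$gene_id, union_targets(sets),
                                    nas_fc, band = cfgp$unbound_band)
cat(sprintf("unbound phase-inert controls: %d genes\n", length(controls)))

memb <- data.table(gene_id = annotation$gene_id)
for (f in factors) set(memb, j = f, value = memb$gene_id %in% sets[[f]])
set(memb, j = "vcp", value = memb$gene_id %in% classes$vcp_targets)
set(memb, j = "v_only", value = memb$gene_id %in% classes$v_only_targets)
set(memb, j = "unbound_control", value = memb$gene_id %in% controls)
fwrite(memb, file.path(outdir, "target_classes.tsv"), sep = "\t")

# recovery report: classified classes versus the simulated truth, plus the
# containment of true bound genes in the pooled RING1B target set
reports <- list(
  data.table(comparison = "vcp_vs_truth",
             agree = setequal(classes$vcp_targets,
                              truth[group == "vcp", gene_id])),
  data.table(comparison = "v_only_vs_truth",
             agree = setequal(classes$v_only_targets,
                              truth[group == "v_only", gene_id]))
)
ov <- overlap_fraction(truth[group != "unbound", gene_id], sets$RING1B)
cat(sprintf("true bound genes contained in RING1B targets: %d/%d (%.1f%%, display %s%%)\n",
            ov$n_overlap, ov$n_total, ov$fraction, ov$display_truncated))
fwrite(rbindlist(reports), file.path(outdir, "class_recovery.tsv"), sep = "\t")
fwrite(data.table(n_overlap = ov$n_overlap, n_total = ov$n_total,
                  fraction = ov$fraction, display = ov$display_truncated),
       file.path(outdir, "overlap_report.tsv"), sep = "\t")
cat("done: results/targets\n")
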