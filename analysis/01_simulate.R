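#!/usr/bin/env Rscript
# Stage 1: simulate the study datasets with known ground truth.
#
# One "chromatin" universe of 2000 genes (10% polycomb-bound: 5% bound by
# vPRC1+cPRC1+PRC2, 5% by vPRC1 only) carries the ChIP, peak, nascent-RNA and
# Capture-C arms: RING1B occupancy constant across G1/S/G2, RYBP/CBX7/
# H2AK119ub1 threefold higher in G2, bound genes transcribed twofold higher
# in G1 than G2 (knockout de-represses S/G2 only), and each vcp promoter has
# one homotypic partner contact, twofold stronger in G2 and absent in the
# knockout.  The retinoic-acid arm simulates its own transcriptome (4000
# genes, 200 per response cluster) in 06_ra_response.R.
#
# Writes the compact artifacts under results/data/; the dense ChIP tracks are
# regenerated in memory by 02_chip_signal.R from the same seed (every
# generator is a pure function of its configuration).

suppressMessages(library(cyclechrom))

main_config <- sim_config(
  seed = 1L, n_chrom = 2L, chrom_length = 25e6, n_genes = 2000L,
  group_fractions = c(vcp = 0.05, v_only = 0.05, unbound = 0.90),
  depth = 1e6
)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

annotation <- generate_annotation(main_config)
fragmap <- generate_fragment_map(main_config)
truth <- make_truth(main_config, annotation)
cat(sprintf("universe: %d genes (%d vcp, %d v_only, %d unbound), %d fragments\n",
            nrow(truth), sum(truth$group == "vcp"),
            sum(truth$group == "v_only"), sum(truth$group == "unbound"),
            nrow(fragmap)))

write_tss_table(annotation, file.path(outdir, "tss.bed"))
write_fragment_map(fragmap, file.path(outdir, "fragments.bed"))
data.table::fwrite(truth, file.path(outdir, "truth.tsv"), sep = "\t")

chip <- simulate_chip(main_config, annotation, truth = truth)
for (nm in names(chip$peaks)) {
  write_peaks(chip$peaks[[nm]], file.path(outdir, sprintf("peaks_%s.bed", nm)))
}
cat(sprintf("peaks written for %d factor x phase combinations\n",
            length(chip$peaks)))

nascent <- simulate_nascent(main_config, annotation, truth)
write_counts(nascent$counts, file.path(outdir, "nascent_counts.tsv"))

capture <- simulate_capture(main_config, annotation, fragmap, truth)
write_interaction_table(capture$table, file.path(outdir, "capture_table.tsv"))
write_peaks(capture$atac_peaks, file.path(outdir, "atac_peaks.bed"))
data.table::fwrite(capture$viewpoints, file.path(outdir, "viewpoints.tsv"),
                   sep = "\t")
data.table::fwrite(capture$truth_interactions,
                   file.path(outdir, "capture_truth.tsv"), sep = "\t")
cat(sprintf("capture arm: %d viewpoints, %d table rows\n",
            nrow(capture$viewpoints), nrow(capture$table)))
cat("done: results/data\n")
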