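#' Analysis thresholds and windows
#'
#' Collects every tunable threshold of the analysis stages, defaulting to the
#' published values: promoter window -500..+1500 bp, profile span +-10 kb at
#' 10-bp bins, heatmap trimming at the 5th/95th percentiles, nascent window
#' TSS..+3 kb, interaction score cutoff 5, metaprofile span +-40 fragments,
#' DE filter FC > 2 and FDR < 0.05, MA threshold FC > 1.2, unbound-control
#' band +-0.2 log2 units, fold-change pseudocount 0.5 RPM.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    promoter_window = c(-500, 1500),
    profile_span = 10000,
    bin_size = 10,
    trim_percentiles = c(5, 95),
    nascent_window = c(0, 3000),
    score_cutoff = 5,
    metaprofile_span = 40L,
    reference_phase = "G2",
    reference_condition = "G2_WT",
    de_fc_cutoff = 2,
    de_fdr_cutoff = 0.05,
    ma_threshold = 1.2,
    unbound_band = 0.2,
    pseudocount = 0.5,
    gsea_n_perm = 1000L,
    write_tracks = TRUE,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  assert_that(length(bad) == 0, "unknown pipeline option(s): %s",
              paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  assert_that(diff(cfg$promoter_window) > 0 && diff(cfg$nascent_window) > 0,
              "analysis windows must have positive length")
  assert_that(cfg$trim_percentiles[1] < cfg$trim_percentiles[2],
              "percentile_low must be < percentile_high")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every key overrides the corresponding [pipeline_config()] default;
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals %||% list())
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

norm_tracks_by_phase <- function(chip, factor, phases = chip_phases) {
  out <- list()
  for (p in phases) {
    key <- paste(factor, p, sep = "_")
    if (!key %in% names(chip$tracks)) next
    out[[p]] <- normalize_track(chip$tracks[[key]], chip$inputs[[p]])
  }
  out
}

#' Promoter coverage for one factor across phases
#'
#' Convenience wrapper: RPM/input-normalizes each phase track of a factor and
#' quantifies the promoter window per gene.
#'
#' @param chip output of [simulate_chip()] (or a list with the same shape).
#' @param factor factor name.
#' @param annotation TSS annotation table.
#' @param window promoter window in bp.
#' @param phases phases to quantify.
#' @return named list, phase -> named per-gene promoter means.
#' @export
promoter_signal_by_phase <- function(chip, factor, annotation,
                                     window = c(-500, 1500),
                                     phases = chip_phases) {
  tracks <- norm_tracks_by_phase(chip, factor, phases)
  lapply(tracks, promoter_coverage, annotation = annotation, window = window)
}

write_stage_table <- function(dt, outdir, name) {
  fwrite(dt, file.path(outdir, name), sep = "\t", scipen = 50L)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the stages in dependency order on a freshly simulated dataset:
#' simulation, ChIP promoter quantification, target classification, Capture-C
#' interaction metaprofiles, nascent-RNA statistics and the RA clustering /
#' enrichment analysis.  All stage outputs land under `outdir` as plain-text
#' tables, together with a run log recording package version, seed and
#' thresholds.  Re-running with identical inputs reproduces every file
#' byte-for-byte.
#'
#' @param sim a [sim_config()].
#' @param outdir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(sim, outdir, config = pipeline_config()) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ## stage: simulate
  annotation <- generate_annotation(sim)
  fragmap <- generate_fragment_map(sim)
  truth <- make_truth(sim, annotation)
  chip <- simulate_chip(sim, annotation, truth = truth)
  nascent <- simulate_nascent(sim, annotation, truth)
  capture <- simulate_capture(sim, annotation, fragmap, truth)
  ra <- simulate_ra_expression(sim, truth)

  write_tss_table(annotation, file.path(outdir, "tss.bed"))
  write_fragment_map(fragmap, file.path(outdir, "fragments.bed"))
  write_stage_table(truth, outdir, "truth.tsv")
  write_interaction_table(capture$table, file.path(outdir, "capture_table.tsv"))
  write_peaks(capture$atac_peaks, file.path(outdir, "atac_peaks.bed"))
  write_counts(nascent$counts, file.path(outdir, "nascent_counts.tsv"))
  write_counts(ra$counts, file.path(outdir, "ra_counts.tsv"))
  write_stage_table(ra$samples, outdir, "ra_samples.tsv")
  for (nm in names(ra$de_tables)) {
    write_de_table(ra$de_tables[[nm]], file.path(outdir, sprintf("de_%s.tsv", nm)))
  }
  if (isTRUE(config$write_tracks)) {
    for (nm in names(chip$tracks)) {
      write_bedgraph(chip$tracks[[nm]],
                     file.path(outdir, sprintf("track_%s.bedgraph", nm)))
    }
    for (nm in names(chip$peaks)) {
      write_peaks(chip$peaks[[nm]],
                  file.path(outdir, sprintf("peaks_%s.bed", nm)))
    }
  }

  ## stage: chip signal
  factors <- unique(sub("_[^_]+$", "", names(chip$tracks)))
  promoter <- list()
  anova_rows <- list()
  for (f in factors) {
    ps <- promoter_signal_by_phase(chip, f, annotation,
                                   window = config$promoter_window)
    promoter[[f]] <- ps
    bound <- truth$gene_id[truth$group %in% factor_bound_groups(f)]
    ps_bound <- lapply(ps, function(v) v[bound])
    aov <- profile_anova(ps_bound)
    anova_rows[[f]] <- data.table(factor = f, F = aov$F, p = aov$p,
                                  n_genes = length(bound))
    tab <- data.table(gene_id = names(ps[[1]]))
    for (p in names(ps)) tab[[p]] <- unname(ps[[p]])
    write_stage_table(tab, outdir, sprintf("promoter_signal_%s.tsv", f))
  }
  write_stage_table(rbindlist(anova_rows), outdir, "promoter_anova.tsv")

  ring1b_norm <- norm_tracks_by_phase(chip, "RING1B")
  mats <- lapply(ring1b_norm, profile_matrix, annotation = annotation,
                 span = config$profile_span)
  mats <- trim_percentiles(mats, config$trim_percentiles[1],
                           config$trim_percentiles[2])
  row_order <- rank_by_reference(promoter[["RING1B"]], config$reference_phase)
  writeLines(row_order, file.path(outdir, "ring1b_row_order.txt"))
  avg <- rbindlist(lapply(names(mats), function(p) {
    data.table(phase = p, position = attr(mats[[p]], "positions"),
               mean = average_profile(mats[[p]]))
  }))
  write_stage_table(avg, outdir, "ring1b_average_profile.tsv")

  ## stage: target sets
  per_factor_sets <- list()
  for (f in factors) {
    per_phase <- lapply(chip_phases, function(p) {
      key <- paste(f, p, sep = "_")
      if (!key %in% names(chip$peaks)) return(character())
      assign_peaks_to_promoters(chip$peaks[[key]], annotation,
                                window = config$promoter_window)
    })
    per_factor_sets[[f]] <- union_targets(per_phase)
  }
  classes <- classify_prc_classes(per_factor_sets[["RING1B"]] %||% character(),
                                  per_factor_sets[["RYBP"]] %||% character(),
                                  per_factor_sets[["CBX7"]] %||% character(),
                                  per_factor_sets[["EZH2"]] %||% character())
  nas_rpm <- nascent_rpm(nascent$counts)
  nas_fc <- promoter_log2fc(nas_rpm[, "G1_WT"], nas_rpm[, "G2_WT"],
                            config$pseudocount)
  target_union <- union_targets(per_factor_sets)
  controls <- select_unbound_controls(annotation$gene_id, target_union,
                                      nas_fc, band = config$unbound_band)
  memb <- data.table(gene_id = annotation$gene_id)
  for (f in factors) set(memb, j = f, value = memb$gene_id %in% per_factor_sets[[f]])
  set(memb, j = "vcp", value = memb$gene_id %in% classes$vcp_targets)
  set(memb, j = "v_only", value = memb$gene_id %in% classes$v_only_targets)
  set(memb, j = "unbound_control", value = memb$gene_id %in% controls)
  write_stage_table(memb, outdir, "target_classes.tsv")
  ov <- overlap_fraction(truth$gene_id[truth$group != "unbound"],
                         per_factor_sets[["RING1B"]] %||% character())
  write_stage_table(data.table(set_a = "true_bound", set_b = "ring1b_targets",
                               n_overlap = ov$n_overlap, n_total = ov$n_total,
                               fraction = ov$fraction,
                               display = ov$display_truncated),
                    outdir, "overlap_report.tsv")

  ## stage: capture
  ctab <- normalize_interaction_table(capture$table)
  vps <- capture$viewpoints[, .(gene_id, vp_frag)]
  interactions <- call_interactions(ctab, capture$atac_peaks, vps,
                                    reference_condition = config$reference_condition,
                                    score_cutoff = config$score_cutoff)
  meta <- build_metaprofile(interactions, ctab,
                            span = config$metaprofile_span,
                            reference_condition = config$reference_condition)
  ctrl <- distance_matched_controls(interactions, ctab,
                                    span = config$metaprofile_span,
                                    reference_condition = config$reference_condition)
  meta[, is_control := FALSE]
  ctrl$profile[, is_control := TRUE]
  write_stage_table(interactions, outdir, "interactions.tsv")
  write_stage_table(rbind(meta, ctrl$profile), outdir, "metaprofile.tsv")
  sums_wt <- sum_interval_counts(interactions, ctab, "G2_WT")
  sums_ko <- sum_interval_counts(interactions, ctab, "G2_KO")
  cmp <- compare_interaction_groups(sums_wt$sum_norm_counts,
                                    sums_ko$sum_norm_counts)
  write_stage_table(data.table(group_a = "G2_WT", group_b = "G2_KO",
                               mean_a = cmp$mean_a, sem_a = cmp$sem_a,
                               mean_b = cmp$mean_b, sem_b = cmp$sem_b,
                               U = cmp$U, p = cmp$p),
                    outdir, "interaction_comparison.tsv")

  ## stage: nascent statistics
  classes3 <- list(vcp = truth$gene_id[truth$group == "vcp"],
                   v_only = truth$gene_id[truth$group == "v_only"],
                   control = controls)
  classes3 <- classes3[lengths(classes3) > 0]
  box_groups <- list()
  for (cl in names(classes3)) {
    for (p in chip_phases) {
      box_groups[[paste(cl, p, sep = "_")]] <-
        nas_rpm[classes3[[cl]], paste(p, "WT", sep = "_")]
    }
  }
  bs <- group_boxstats(box_groups)
  write_stage_table(bs$stats, outdir, "nascent_boxstats.tsv")
  write_stage_table(bs$mw_p, outdir, "nascent_mw.tsv")
  ma <- ma_stats(nas_rpm[, "G1_WT"], nas_rpm[, "G2_WT"],
                 threshold = config$ma_threshold,
                 pseudocount = config$pseudocount)
  write_stage_table(ma$table, outdir, "nascent_ma.tsv")
  write_stage_table(data.table(pct_up = ma$pct_up, pct_down = ma$pct_down),
                    outdir, "nascent_ma_fractions.tsv")

  ## stage: RA response
  de_genes <- select_de_genes(ra$de_tables, config$de_fc_cutoff,
                              config$de_fdr_cutoff)
  ra_res <- ra_cluster_analysis(ra, de_genes, config)
  write_stage_table(data.table(gene_id = names(ra_res$labels),
                               cluster = unname(ra_res$labels)),
                    outdir, "ra_clusters.tsv")
  write_stage_table(ra_res$gsea, outdir, "ra_gsea.tsv")

  writeLines(c(
    sprintf("cyclechrom %s", as.character(packageVersion("cyclechrom"))),
    sprintf("seed: %d", sim$seed),
    sprintf("thresholds: promoter %s; score_cutoff %s; de FC>%s FDR<%s; ma %s; band %s",
            paste(config$promoter_window, collapse = ".."),
            config$score_cutoff, config$de_fc_cutoff, config$de_fdr_cutoff,
            config$ma_threshold, config$unbound_band)
  ), file.path(outdir, "run_log.txt"))

  invisible(list(annotation = annotation, fragmap = fragmap, truth = truth,
                 chip = chip, nascent = nascent, capture = capture, ra = ra,
                 promoter = promoter, targets = per_factor_sets,
                 classes = classes, controls = controls,
                 interactions = interactions, metaprofile = meta,
                 control_profile = ctrl$profile, ra_clusters = ra_res))
}

#' RA-differentiation clustering and enrichment analysis
#'
#' TMM-normalizes the RA count matrix, averages replicates per
#' phase x treatment condition, expresses each selected gene relative to its
#' geometric mean, clusters into three major groups (1 - Pearson distance,
#' average linkage, size-ordered labels), sub-cuts the IAA-derepressed
#' cluster (identified as the cluster with the largest mean IAA-minus-UNT
#' contrast) on the row-centred untreated phase profile (Euclidean, Ward),
#' and runs preranked enrichment of every recovered cluster against the
#' G1-vs-G2 untreated ranking.
#'
#' @param ra output of [simulate_ra_expression()] (counts, samples,
#'   de_tables).
#' @param de_genes character vector of genes to cluster.
#' @param config a [pipeline_config()].
#' @return list with `labels` (genes surviving the amplitude filter),
#'   `tree`, `condition_means`, `derepressed` (major label of the
#'   IAA-responsive cluster) and `gsea`.
#' @export
ra_cluster_analysis <- function(ra, de_genes, config = pipeline_config()) {
  assert_that(length(de_genes) >= 10, "too few DE genes to cluster")
  norm <- tmm_normalize(ra$counts)
  conds <- unique(ra$samples[, .(phase, treatment)])
  cm <- vapply(seq_len(nrow(conds)), function(j) {
    sel <- ra$samples$phase == conds$phase[j] &
      ra$samples$treatment == conds$treatment[j]
    rowMeans(norm[, ra$samples$sample_id[sel], drop = FALSE])
  }, numeric(nrow(norm)))
  colnames(cm) <- paste(conds$phase, conds$treatment, sep = "_")
  rel <- relative_to_geomean(cm[de_genes, , drop = FALSE])
  # correlation distance is undefined in spirit for genes with no reproducible
  # pattern: require the same 2-fold amplitude as the DE filter, relative to
  # the gene's own geometric mean, before clustering
  rel <- rel[apply(abs(rel), 1, max) >= log2(config$de_fc_cutoff), ,
             drop = FALSE]
  assert_that(nrow(rel) >= 10, "too few patterned genes to cluster")

  major <- hclust_genes(rel, k_major = 3L, min_frac = 0.05)
  iaa_cols <- grep("_IAA6$", colnames(rel), value = TRUE)
  unt_cols <- grep("_UNT6$", colnames(rel), value = TRUE)
  contrast <- vapply(split(names(major$labels), major$labels), function(ids) {
    mean(rel[ids, iaa_cols, drop = FALSE]) - mean(rel[ids, unt_cols, drop = FALSE])
  }, numeric(1))
  derep <- names(which.max(contrast))
  res <- hclust_genes(rel, k_major = 3L, min_frac = 0.05,
                      subcluster = list(cluster = derep, k = 2L,
                                        cols = unt_cols,
                                        distance = "euclidean",
                                        linkage = "ward.D2",
                                        row_center = TRUE,
                                        refine = TRUE))
  sets <- split(names(res$labels), res$labels)
  derep_all <- names(res$labels)[res$labels == derep |
                                   startsWith(res$labels, paste0(derep, "-"))]
  if (length(derep_all) > 0 && length(derep_all) < length(res$labels)) {
    sets[[derep]] <- derep_all
  }
  ranking <- ra$de_tables[["G1_vs_G2_UNT6"]]
  scores <- setNames(ranking$log2fc, ranking$gene_id)
  gs <- gsea_preranked(scores, sets, n_perm = config$gsea_n_perm,
                       seed = config$seed)
  list(labels = res$labels, tree = res$tree, condition_means = cm,
       derepressed = derep, gsea = gs)
}
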