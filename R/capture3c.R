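#' Capture-C count normalization
#'
#' `normCounts = raw * nprom * 100000 / cov`, where `cov` is the total read
#' count aligning to captured gene promoters in the sample and `nprom` the
#' number of promoters in the capture design.  Invariant to joint rescaling
#' of `raw` and `cov`.
#'
#' @param raw numeric vector of per-fragment read counts.
#' @param cov positive total captured read count of the sample.
#' @param nprom positive number of captured promoters.
#' @param scale constant multiplier (100,000).
#' @return numeric vector of normalized counts.
#' @export
norm_counts <- function(raw, cov, nprom, scale = 1e5) {
  assert_that(length(cov) == 1 && is.finite(cov) && cov > 0, "cov must be > 0")
  assert_that(length(nprom) == 1 && nprom > 0, "nprom must be > 0")
  raw * nprom * scale / cov
}

#' Normalize a long interaction table per condition
#'
#' Adds a `norm_counts` column: within each condition, `cov` is the summed
#' raw counts of that condition (reads aligning to captured promoters) and
#' `nprom` the number of distinct viewpoints.
#'
#' @param table long interaction `data.table` (see [simulate_capture()]).
#' @param nprom optional promoter count; defaults to the number of distinct
#'   viewpoints in the table.
#' @return a copy of the table with `norm_counts` added.
#' @export
normalize_interaction_table <- function(table, nprom = NULL) {
  validate_interaction_table(table)
  out <- copy(as.data.table(table))
  np <- nprom %||% uniqueN(out$viewpoint_id)
  out[, norm_counts := norm_counts(counts, cov = sum(counts), nprom = np),
      by = condition]
  out[]
}

validate_interaction_table <- function(table) {
  need <- c("viewpoint_id", "chrom", "frag_index", "frag_start", "frag_end",
            "condition", "counts", "score")
  miss <- setdiff(need, names(table))
  assert_that(length(miss) == 0, "interaction table lacks column(s): %s",
              paste(miss, collapse = ", "))
  bad <- setdiff(unique(table$condition), capture_conditions)
  assert_that(length(bad) == 0, "unknown condition label(s): %s",
              paste(bad, collapse = ", "))
  invisible(table)
}

fragments_overlapping_peaks <- function(frag_start, frag_end, frag_chrom, peaks) {
  ok <- logical(length(frag_start))
  sel <- which(peaks$chrom == frag_chrom[1])
  for (j in sel) {
    ok <- ok | (frag_start < peaks$end[j] & frag_end > peaks$start[j])
  }
  ok
}

#' Call promoter-ATAC interactions from scored fragments
#'
#' In the chosen reference condition, fragments with interaction score >=
#' `score_cutoff` that overlap an ATAC peak (and are not the viewpoint
#' fragment itself) are grouped into maximal runs of consecutive fragment
#' indices (gap tolerance 0); each run becomes one interaction.  The summit
#' is the run fragment with the highest normalized count in the reference
#' condition (ties broken toward the viewpoint).
#'
#' @param table normalized long interaction table
#'   (see [normalize_interaction_table()]).
#' @param atac_peaks `data.table` of ATAC peaks (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @param viewpoints `data.table` with `gene_id` and `vp_frag` (viewpoint
#'   fragment index); `vp_frag` may be derived with [position_to_fragment()].
#' @param reference_condition condition used for scores and summits.
#' @param score_cutoff minimum score (inclusive).
#' @return `data.table` of interactions: `viewpoint_id, chrom, vp_frag,
#'   i_lo, i_hi, summit, distance, side`.
#' @export
call_interactions <- function(table, atac_peaks, viewpoints,
                              reference_condition = "G2_WT",
                              score_cutoff = 5) {
  validate_interaction_table(table)
  assert_that(all(c("gene_id", "vp_frag") %in% names(viewpoints)),
              "viewpoints need gene_id and vp_frag")
  if (anyNA(viewpoints$vp_frag)) {
    stop_("viewpoint fragment unresolvable for: %s",
          paste(viewpoints$gene_id[is.na(viewpoints$vp_frag)], collapse = ", "))
  }
  val_col <- if ("norm_counts" %in% names(table)) "norm_counts" else "counts"
  ref <- as.data.table(table)[condition == reference_condition]
  out <- vector("list", nrow(viewpoints))
  for (i in seq_len(nrow(viewpoints))) {
    g <- viewpoints$gene_id[i]
    vf <- viewpoints$vp_frag[i]
    sub <- ref[viewpoint_id == g]
    if (nrow(sub) == 0L) next
    setorder(sub, frag_index)
    sig <- sub$score >= score_cutoff & sub$frag_index != vf &
      fragments_overlapping_peaks(sub$frag_start, sub$frag_end, sub$chrom,
                                  atac_peaks)
    if (!any(sig)) next
    idx <- sub$frag_index[sig]
    run_id <- cumsum(c(1L, diff(idx) != 1L))
    runs <- split(seq_along(idx), run_id)
    out[[i]] <- rbindlist(lapply(runs, function(r) {
      fr <- idx[r]
      vals <- sub[[val_col]][match(fr, sub$frag_index)]
      cand <- fr[vals == max(vals)]
      summit <- cand[order(abs(cand - vf), cand)][1]
      data.table(viewpoint_id = g, chrom = sub$chrom[1], vp_frag = vf,
                 i_lo = min(fr), i_hi = max(fr), summit = summit,
                 distance = abs(summit - vf),
                 side = if (summit > vf) "downstream" else "upstream")
    }))
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(viewpoint_id = character(), chrom = character(),
                      vp_frag = integer(), i_lo = integer(), i_hi = integer(),
                      summit = integer(), distance = integer(),
                      side = character()))
  }
  res[]
}

#' Summed normalized counts (and scores) over interaction intervals
#'
#' @param interactions output of [call_interactions()].
#' @param table normalized long interaction table.
#' @param condition condition to sum in.
#' @return the interactions table with `sum_norm_counts` and `sum_score`
#'   columns for the requested condition.
#' @export
sum_interval_counts <- function(interactions, table, condition) {
  validate_interaction_table(table)
  assert_that("norm_counts" %in% names(table),
              "table must be normalized first (normalize_interaction_table)")
  cond <- condition
  sub <- as.data.table(table)[condition == cond]
  out <- copy(as.data.table(interactions))
  sums <- vapply(seq_len(nrow(out)), function(i) {
    s <- sub[viewpoint_id == out$viewpoint_id[i] &
               frag_index >= out$i_lo[i] & frag_index <= out$i_hi[i]]
    c(sum(s$norm_counts), sum(s$score))
  }, numeric(2))
  out[, `:=`(sum_norm_counts = sums[1, ], sum_score = sums[2, ],
             condition = cond)]
  out[]
}

# Shared profile extraction: for each anchor (centre fragment, orientation
# sign, denominator), collect value(centre + p * sign) / denom for relative
# positions p in -span..span; positions without a fragment record are NA.
metaprofile_engine <- function(anchors, table, conditions, span, val_col) {
  positions <- seq.int(-span, span)
  tab <- as.data.table(table)
  setkeyv(tab, c("condition", "viewpoint_id", "frag_index"))
  res <- list()
  for (cond in conditions) {
    mat <- matrix(NA_real_, nrow(anchors), length(positions))
    for (i in seq_len(nrow(anchors))) {
      frs <- anchors$centre[i] + positions * anchors$sign[i]
      sub <- tab[.(cond, anchors$viewpoint_id[i], frs)]
      mat[i, ] <- sub[[val_col]] / anchors$denom[i]
    }
    n_ok <- colSums(!is.na(mat))
    mu <- ifelse(n_ok > 0, colMeans(mat, na.rm = TRUE), NA_real_)
    sdv <- apply(mat, 2, function(v) sd(v[!is.na(v)]))
    res[[cond]] <- data.table(condition = cond, position = positions,
                              mean = mu,
                              sem = ifelse(n_ok > 1, sdv / sqrt(n_ok), NA_real_),
                              n = n_ok)
  }
  rbindlist(res)
}

interaction_anchor_table <- function(interactions, table, reference_condition,
                                     val_col) {
  tab <- as.data.table(table)
  anchors <- copy(as.data.table(interactions))
  ref <- tab[condition == reference_condition]
  anchors[, denom := vapply(seq_len(.N), function(i) {
    v <- ref[viewpoint_id == anchors$viewpoint_id[i] &
               frag_index == anchors$summit[i]][[val_col]]
    if (length(v) == 0L) NA_real_ else v[1]
  }, numeric(1))]
  anchors[, sign := ifelse(vp_frag > summit, 1L, -1L)]
  anchors
}

#' Summit-anchored, G2-normalized, direction-flipped metaprofile
#'
#' For every interaction, per-fragment normalized counts at summit +- `span`
#' fragments are divided by that interaction's summit value in the G2
#' reference condition, and fragment offsets are flipped so that positive
#' relative positions always point toward the viewpoint promoter (proximal)
#' and negative positions away from it (distal): profiles run promoter-distal
#' (-span) to promoter-proximal (+span).  Positions beyond the recorded
#' fragments are excluded from the per-position means.  Interactions whose
#' G2 summit value is not positive are dropped with a warning.
#'
#' @param interactions output of [call_interactions()].
#' @param table normalized long interaction table.
#' @param conditions conditions to profile (default: all in the table).
#' @param span half-width in fragments.
#' @param reference_condition condition providing the summit denominator.
#' @return `data.table(condition, position, mean, sem, n)`; attribute
#'   `n_interactions` records how many interactions were retained.
#' @export
build_metaprofile <- function(interactions, table, conditions = NULL,
                              span = 40L, reference_condition = "G2_WT") {
  validate_interaction_table(table)
  val_col <- if ("norm_counts" %in% names(table)) "norm_counts" else "counts"
  conditions <- conditions %||% intersect(capture_conditions,
                                          unique(table$condition))
  assert_that(reference_condition %in% unique(table$condition),
              "reference condition '%s' absent from table", reference_condition)
  anchors <- interaction_anchor_table(interactions, table,
                                      reference_condition, val_col)
  bad <- is.na(anchors$denom) | anchors$denom <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d interaction(s) with non-positive %s summit value",
                    sum(bad), reference_condition), call. = FALSE)
    anchors <- anchors[!bad]
  }
  assert_that(nrow(anchors) > 0, "no interaction with positive summit value")
  anchors[, centre := summit]
  prof <- metaprofile_engine(anchors, table, conditions, span, val_col)
  setattr(prof, "n_interactions", nrow(anchors))
  prof
}

#' Distance-matched control sites and their metaprofile
#'
#' For an interaction whose summit lies `d` fragments from the viewpoint on
#' one side, the control site is the fragment at distance `d` on the opposite
#' side (reflection about the viewpoint, an involution).  Control windows are
#' normalized with the same denominator as their interaction (the G2 summit
#' value) and flipped with the same proximal/distal convention.  Controls
#' falling outside the recorded fragments contribute nothing at the missing
#' positions.
#'
#' @inheritParams build_metaprofile
#' @return list with `controls` (interactions plus `control_summit`) and
#'   `profile` (`data.table(condition, position, mean, sem, n)`).
#' @export
distance_matched_controls <- function(interactions, table, conditions = NULL,
                                      span = 40L,
                                      reference_condition = "G2_WT") {
  validate_interaction_table(table)
  val_col <- if ("norm_counts" %in% names(table)) "norm_counts" else "counts"
  conditions <- conditions %||% intersect(capture_conditions,
                                          unique(table$condition))
  anchors <- interaction_anchor_table(interactions, table,
                                      reference_condition, val_col)
  bad <- is.na(anchors$denom) | anchors$denom <= 0
  anchors <- anchors[!bad]
  assert_that(nrow(anchors) > 0, "no interaction with positive summit value")
  anchors[, control_summit := 2L * vp_frag - summit]
  anchors[, centre := control_summit]
  anchors[, sign := ifelse(vp_frag > centre, 1L, -1L)]
  prof <- metaprofile_engine(anchors, table, conditions, span, val_col)
  list(controls = anchors[, .(viewpoint_id, chrom, vp_frag, summit,
                              control_summit, distance, denom)],
       profile = prof)
}

#' Two-sided Mann-Whitney comparison of interaction-strength groups
#'
#' Exact null distribution when both groups have at most `exact_max`
#' observations and no ties; normal approximation with tie correction
#' otherwise.
#'
#' @param group_a,group_b numeric vectors of per-interaction summed
#'   normalized counts.
#' @param exact_max exact-test size threshold per group.
#' @return list with group means, SEMs, the U statistic and the two-sided p.
#' @export
compare_interaction_groups <- function(group_a, group_b, exact_max = 8L) {
  assert_that(length(group_a) > 0 && length(group_b) > 0,
              "both groups must be non-empty")
  use_exact <- max(length(group_a), length(group_b)) <= exact_max &&
    !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = use_exact, correct = !use_exact)
  )
  list(mean_a = mean(group_a), sem_a = sd(group_a) / sqrt(length(group_a)),
       mean_b = mean(group_b), sem_b = sd(group_b) / sqrt(length(group_b)),
       U = unname(wt$statistic), p = wt$p.value)
}
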