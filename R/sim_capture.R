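capture_conditions <- c("G1_WT", "G2_WT", "G1_KO", "G2_KO")

#' Simulate fragment-level Capture-C interaction tables
#'
#' Every vPRC1/cPRC1/PRC2 (`vcp`) target promoter that sits far enough from
#' its chromosome ends is a capture viewpoint.  Expected per-fragment counts
#' follow a power-law distance decay `c * d^-alpha` (`d` = fragment
#' separation from the viewpoint).  Each viewpoint has one homotypic partner
#' site at a distance drawn from `capture_partner_range` on a random side: at
#' the three partner fragments the expected count is `enrichment * background`
#' (enrichment 2, 6, 2 across the run), multiplied by `capture_g2_boost` in
#' G2 and collapsed to plain background in the knockout - so the expected
#' G2/G1 ratio at the summit equals the boost exactly.  Counts are Poisson.
#' The emitted per-fragment interaction score is a monotone function of the
#' expected enrichment over background (2.5 x enrichment), so the score-5
#' cutoff selects exactly the true interaction fragments.  ATAC peaks
#' covering every partner run plus non-interacting decoy sites are emitted
#' alongside.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @param fragmap output of [generate_fragment_map()].
#' @param truth [make_truth()] table.
#' @param n_viewpoints optional cap on the number of viewpoints used.
#' @return list with `table` (long `data.table`: `viewpoint_id, chrom,
#'   frag_index, frag_start, frag_end, condition, counts, score`),
#'   `viewpoints` (`gene_id, chrom, tss, vp_frag`), `atac_peaks`
#'   (`chrom, start, end, score`), and `truth_interactions`
#'   (`viewpoint_id, vp_frag, summit_frag, distance, side`).
#' @export
simulate_capture <- function(config, annotation, fragmap, truth,
                             n_viewpoints = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  span <- 40L
  win <- config$capture_window
  d_max <- config$capture_partner_range[2]
  need <- d_max + span

  vp <- as.data.table(annotation)[gene_id %in% truth[group == "vcp", gene_id]]
  vp[, vp_frag := position_to_fragment(fragmap, chrom, tss)]
  rng <- fragmap[, .(lo = min(frag_index), hi = max(frag_index)), by = chrom]
  vp <- merge(vp, rng, by = "chrom")
  vp <- vp[vp_frag - need >= lo & vp_frag + need <= hi]
  setorder(vp, chrom, tss)
  if (!is.null(n_viewpoints)) vp <- head(vp, n_viewpoints)
  n_per_chrom <- vp[, .N, by = chrom]
  if (nrow(vp) == 0L || any(n_per_chrom$N < 2L) ||
      nrow(n_per_chrom) < length(unique(annotation$chrom))) {
    stop_("need at least 2 eligible capture viewpoints per chromosome")
  }

  seed_stream(config$seed, "capture")
  enr <- c(2, 6, 2)
  alpha <- config$capture_decay_alpha
  boost <- config$capture_g2_boost

  tabs <- vector("list", nrow(vp))
  truths <- vector("list", nrow(vp))
  atacs <- vector("list", nrow(vp))
  for (i in seq_len(nrow(vp))) {
    v <- vp[i]
    D <- sample(seq(config$capture_partner_range[1], d_max), 1L)
    side <- sample(c(-1L, 1L), 1L)
    summit <- v$vp_frag + side * D
    idx <- seq(max(v$vp_frag - win, v$lo), min(v$vp_frag + win, v$hi))
    fm <- fragmap[.(idx), on = "frag_index"]
    d <- abs(fm$frag_index - v$vp_frag)
    bg_w <- pmax(d, 1)^(-alpha)
    cc <- config$depth / sum(bg_w)
    bg <- cc * bg_w
    e <- rep(1, length(idx))
    hit <- match(summit + c(-1L, 0L, 1L), fm$frag_index)
    e[hit] <- enr

    per_cond <- lapply(capture_conditions, function(cond) {
      ph <- sub("_.*", "", cond)
      geno <- sub(".*_", "", cond)
      ee <- if (geno == "KO") rep(1, length(e)) else
        e * ifelse(e > 1 & ph == "G2", boost, 1)
      mu <- bg * ee
      data.table(viewpoint_id = v$gene_id, chrom = v$chrom,
                 frag_index = fm$frag_index, frag_start = fm$start,
                 frag_end = fm$end, condition = cond,
                 counts = rpois(length(mu), mu),
                 score = 2.5 * ee)
    })
    tabs[[i]] <- rbindlist(per_cond)
    truths[[i]] <- data.table(viewpoint_id = v$gene_id, vp_frag = v$vp_frag,
                              summit_frag = summit, distance = D, side = side)
    decoy <- v$vp_frag + sample(c(-1L, 1L), 2L, replace = TRUE) *
      sample(seq(60L, 140L), 2L)
    peak_at <- function(fi) {
      fmk <- fragmap[.(fi + c(-1L, 0L, 1L)), on = "frag_index"]
      data.table(chrom = v$chrom, start = min(fmk$start), end = max(fmk$end),
                 score = 100)
    }
    atacs[[i]] <- rbindlist(lapply(c(summit, decoy), peak_at))
  }
  atac <- unique(rbindlist(atacs))
  setorder(atac, chrom, start)
  list(table = rbindlist(tabs),
       viewpoints = vp[, .(gene_id, chrom, tss, vp_frag)],
       atac_peaks = atac,
       truth_interactions = rbindlist(truths))
}
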