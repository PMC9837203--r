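#' RPM-normalize a ChIP track and subtract its matched input
#'
#' Each bin becomes `signal * 1e6 / signal_library - input * 1e6 /
#' input_library` (reads per million, input-subtracted); values may be
#' negative after subtraction.
#'
#' @param signal,input raw [signal_track()]s on identical binning.
#' @return a normalized [signal_track()].
#' @export
normalize_track <- function(signal, input) {
  stopifnot(inherits(signal, "signal_track"), inherits(input, "signal_track"))
  assert_that(!signal$normalized && !input$normalized,
              "normalize_track expects raw tracks")
  assert_that(signal$library_size > 0 && input$library_size > 0,
              "library sizes must be positive")
  assert_that(identical(names(signal$bins), names(input$bins)) &&
                signal$bin_size == input$bin_size &&
                all(lengths(signal$bins) == lengths(input$bins)),
              "signal and input tracks have mismatched chromosomes or binning")
  bins <- lapply(names(signal$bins), function(ch) {
    signal$bins[[ch]] * 1e6 / signal$library_size -
      input$bins[[ch]] * 1e6 / input$library_size
  })
  names(bins) <- names(signal$bins)
  signal_track(bins, bin_size = signal$bin_size, factor = signal$factor,
               phase = signal$phase, condition = signal$condition,
               library_size = signal$library_size, normalized = TRUE)
}

# Strand-aware promoter/profile bin window around the TSS bin.
# Windows are expressed in gene orientation; for minus-strand genes the
# genomic window is the bin-level mirror image of the plus-strand window.
gene_bin_window <- function(tss, strand, bin, up_bins, down_bins) {
  b <- tss %/% bin + 1L
  if (strand == "+") seq(b - up_bins, b + down_bins - 1L)
  else seq(b + up_bins, b - down_bins + 1L)   # decreasing: upstream -> downstream
}

#' Mean normalized signal over the promoter window per gene
#'
#' The promoter statistic is the strand-aware mean of bin values over the
#' window (default -500..+1500 bp relative to the TSS, in gene orientation).
#' Windows running past a chromosome end are truncated to in-bounds bins.
#'
#' @param track a normalized [signal_track()].
#' @param annotation TSS annotation table.
#' @param window length-2 numeric, window in bp relative to the TSS
#'   (multiples of the bin size).
#' @return named numeric vector, gene_id -> mean signal.
#' @export
promoter_coverage <- function(track, annotation, window = c(-500, 1500)) {
  stopifnot(inherits(track, "signal_track"))
  validate_annotation(annotation)
  bin <- track$bin_size
  assert_that(all(window %% bin == 0) && diff(window) > 0,
              "window bounds must be multiples of the bin size")
  missing_ch <- setdiff(unique(annotation$chrom), names(track$bins))
  if (length(missing_ch)) {
    stop_("annotation chromosome(s) absent from track: %s",
          paste(missing_ch, collapse = ", "))
  }
  up <- -window[1] %/% bin
  down <- window[2] %/% bin
  out <- numeric(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    v <- track$bins[[annotation$chrom[i]]]
    w <- gene_bin_window(annotation$tss[i], annotation$strand[i], bin, up, down)
    w <- w[w >= 1L & w <= length(v)]
    out[i] <- if (length(w)) mean(v[w]) else NA_real_
  }
  setNames(out, annotation$gene_id)
}

#' TSS-centred profile matrix
#'
#' One row per gene, one column per bin spanning TSS +- `span`, oriented
#' 5' to 3' of the gene (minus-strand rows are the mirrored window).
#' Out-of-bounds bins are 0 and counted in the `oob_bins` attribute.
#'
#' @param track a normalized [signal_track()].
#' @param annotation TSS annotation table.
#' @param span half-width in bp (multiple of the bin size).
#' @return numeric matrix (genes x `2*span/bin` positions) with attributes
#'   `positions` (bin-centre offsets in bp) and `oob_bins`.
#' @export
profile_matrix <- function(track, annotation, span = 10000) {
  stopifnot(inherits(track, "signal_track"))
  validate_annotation(annotation)
  bin <- track$bin_size
  assert_that(span %% bin == 0 && span > 0, "span must be a multiple of bin size")
  nb <- span %/% bin
  mat <- matrix(0, nrow(annotation), 2L * nb,
                dimnames = list(annotation$gene_id, NULL))
  oob <- 0L
  for (i in seq_len(nrow(annotation))) {
    v <- track$bins[[annotation$chrom[i]]]
    w <- gene_bin_window(annotation$tss[i], annotation$strand[i], bin, nb, nb)
    ok <- w >= 1L & w <= length(v)
    oob <- oob + sum(!ok)
    mat[i, ok] <- v[w[ok]]
  }
  attr(mat, "positions") <- (seq_len(2L * nb) - nb - 1L) * bin + bin / 2
  attr(mat, "oob_bins") <- oob
  attr(mat, "trimmed") <- FALSE
  mat
}

#' Winsorize profile values to joint percentiles
#'
#' Clips all values to the [low, high] percentiles computed jointly over every
#' entry of the matrices displayed together (so cross-phase heatmaps share a
#' single scale).  Percentiles use linear interpolation between order
#' statistics.  Matrices carry a `trimmed` flag: trimming an already-trimmed
#' matrix is a no-op, so the operation is idempotent.
#'
#' @param matrices a matrix or a list of matrices treated as one display set.
#' @param low,high percentile bounds in 0..100.
#' @return the same shape as the input, clipped, with `trimmed = TRUE`.
#' @export
trim_percentiles <- function(matrices, low = 5, high = 95) {
  assert_that(low < high, "percentile_low must be < percentile_high")
  single <- !is.list(matrices)
  mats <- if (single) list(matrices) else matrices
  already <- vapply(mats, function(m) isTRUE(attr(m, "trimmed")), logical(1))
  if (all(already)) return(matrices)
  all_values <- unlist(lapply(mats, as.vector), use.names = FALSE)
  q <- quantile(all_values, c(low, high) / 100, type = 7, names = FALSE)
  out <- lapply(mats, function(m) {
    a <- attributes(m)
    m <- pmin(pmax(m, q[1]), q[2])
    attributes(m) <- a
    attr(m, "trimmed") <- TRUE
    m
  })
  if (single) out[[1]] else out
}

#' Rank genes by their signal in a reference phase
#'
#' Returns the gene order used to draw cross-phase heatmaps: descending mean
#' promoter-window signal in the reference phase (G2 in the published
#' analysis), ties broken by gene identifier, and the same order applied to
#' every phase.
#'
#' @param promoter_by_phase named list, phase -> named vector of per-gene
#'   promoter means (as from [promoter_coverage()]).
#' @param reference_phase name of the reference phase.
#' @return character vector of gene_ids in display order.
#' @export
rank_by_reference <- function(promoter_by_phase, reference_phase = "G2") {
  assert_that(reference_phase %in% names(promoter_by_phase),
              "reference phase '%s' not supplied", reference_phase)
  ref <- promoter_by_phase[[reference_phase]]
  ids <- names(ref)
  ids[order(-ref, ids, method = "radix")]
}

#' Column-mean profile curve
#' @param matrix a [profile_matrix()].
#' @return numeric vector of per-position means (positions attribute kept).
#' @export
average_profile <- function(matrix) {
  out <- colMeans(matrix)
  attr(out, "positions") <- attr(matrix, "positions")
  out
}

#' One-way ANOVA of promoter signal across phases
#'
#' Groups are cell-cycle phases, observations the per-gene promoter-window
#' means.  With zero total variance the statistic is defined as F = 0,
#' p = 1.
#'
#' @param promoter_by_phase named list, phase -> numeric vector of per-gene
#'   promoter means.
#' @return list with `F` and `p`.
#' @export
profile_anova <- function(promoter_by_phase) {
  assert_that(length(promoter_by_phase) >= 2, "need at least 2 phases")
  assert_that(all(lengths(promoter_by_phase) >= 2), "need >= 2 genes per phase")
  value <- unlist(promoter_by_phase, use.names = FALSE)
  phase <- factor(rep(names(promoter_by_phase), lengths(promoter_by_phase)))
  if (var(value) < .Machine$double.eps) return(list(F = 0, p = 1))
  a <- anova(lm(value ~ phase))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1])
}

#' Per-gene log2 fold change of promoter signal
#'
#' Negative input-subtracted means are floored at 0 before the pseudocount so
#' logs are always defined: `log2((max(a,0)+pc) / (max(b,0)+pc))`.
#'
#' @param a,b named numeric vectors of per-gene promoter means (same genes).
#' @param pseudocount pseudocount in RPM units.
#' @return named numeric vector of log2 fold changes.
#' @export
promoter_log2fc <- function(a, b, pseudocount = 0.5) {
  assert_that(identical(names(a), names(b)),
              "a and b must cover the same genes in the same order")
  log2((pmax(a, 0) + pseudocount) / (pmax(b, 0) + pseudocount))
}
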