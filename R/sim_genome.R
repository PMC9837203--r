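#' Generate a synthetic TSS annotation
#'
#' Places `n_genes` transcription start sites across the configured
#' chromosomes with at least 25 kb spacing between neighbours (so that the
#' +-10 kb profile windows of adjacent genes never overlap), random strand and
#' unique identifiers.  Coordinates are 0-based.
#'
#' @param config a [sim_config()].
#' @return `data.table` with columns `chrom`, `tss`, `strand`, `gene_id`
#'   (one row per gene, sorted by genomic position).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  min_gap <- 25000L
  margin <- 12500L
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  usable <- config$chrom_length - 2L * margin
  need <- (max(per_chrom) - 1L) * min_gap
  if (max(per_chrom) < 1L || need > usable) {
    stop_("cannot place %d genes per chromosome of %d bp with >= %d bp spacing",
          max(per_chrom), config$chrom_length, min_gap)
  }
  seed_stream(config$seed, "annotation")
  recs <- vector("list", config$n_chrom)
  for (i in seq_len(config$n_chrom)) {
    n <- per_chrom[i]
    if (n == 0L) next
    slack <- usable - (n - 1L) * min_gap
    extra <- sort(floor(runif(n, 0, slack + 1)))
    tss <- margin + (seq_len(n) - 1L) * min_gap + extra
    recs[[i]] <- data.table(
      chrom = sprintf("chr%d", i),
      tss = as.integer(tss),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  }
  ann <- rbindlist(recs)
  ann[, gene_id := sprintf("gene_%05d", seq_len(.N))]
  validate_annotation(ann)
  ann[]
}

#' Validate a TSS annotation table
#' @param ann annotation `data.table`.
#' @return the annotation, invisibly.
#' @keywords internal
validate_annotation <- function(ann) {
  assert_that(is.data.frame(ann) &&
                all(c("chrom", "tss", "strand", "gene_id") %in% names(ann)),
              "annotation needs columns chrom, tss, strand, gene_id")
  assert_that(!anyDuplicated(ann$gene_id), "gene_id must be unique")
  assert_that(all(ann$tss >= 0), "tss must be >= 0")
  assert_that(all(ann$strand %in% c("+", "-")), "strand must be '+' or '-'")
  invisible(ann)
}

#' Generate a synthetic restriction-fragment map
#'
#' Tiles every chromosome contiguously with non-overlapping fragments whose
#' lengths are geometric with the configured mean (a memoryless cutter model);
#' the first fragment starts at 0 and the last ends exactly at the chromosome
#' length.  Fragments carry a global 1-based index that increases by 1 along
#' each chromosome in genomic order.
#'
#' @param config a [sim_config()].
#' @return `data.table` with columns `chrom`, `start`, `end`, `frag_index`.
#' @export
generate_fragment_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed_stream(config$seed, "fragmap")
  maps <- vector("list", config$n_chrom)
  for (i in seq_len(config$n_chrom)) {
    len <- config$chrom_length
    n_guess <- ceiling(1.3 * len / config$frag_mean_len) + 50L
    lens <- rgeom(n_guess, prob = 1 / config$frag_mean_len) + 1L
    while (sum(lens) < len) {
      lens <- c(lens, rgeom(n_guess, prob = 1 / config$frag_mean_len) + 1L)
    }
    ends <- cumsum(as.numeric(lens))
    k <- which(ends >= len)[1]
    ends <- ends[seq_len(k)]
    ends[k] <- len
    starts <- c(0, ends[-k])
    keep <- starts < ends   # guard against a zero-width trailing fragment
    maps[[i]] <- data.table(chrom = sprintf("chr%d", i),
                            start = as.integer(starts[keep]),
                            end = as.integer(ends[keep]))
  }
  fragmap <- rbindlist(maps)
  fragmap[, frag_index := seq_len(.N)]
  fragmap[]
}

#' Locate the fragment containing a genomic position
#'
#' @param fragmap fragment map from [generate_fragment_map()].
#' @param chroms,positions vectors of chromosome names and 0-based positions.
#' @return integer vector of global fragment indices (NA when not covered).
#' @export
position_to_fragment <- function(fragmap, chroms, positions) {
  stopifnot(length(chroms) == length(positions))
  out <- rep(NA_integer_, length(chroms))
  for (ch in unique(chroms)) {
    fm <- fragmap[chrom == ch]
    if (nrow(fm) == 0L) next
    sel <- which(chroms == ch)
    j <- findInterval(positions[sel], fm$start)
    ok <- j >= 1L & positions[sel] < fm$end[pmax(j, 1L)]
    out[sel[ok]] <- fm$frag_index[j[ok]]
  }
  out
}

#' Per-phase occupancy multipliers for a G2/G1 ratio
#'
#' G1 is the baseline, G2 carries the full ratio and S phase sits at the
#' geometric midpoint of the two.
#'
#' @param ratio positive G2/G1 ratio.
#' @return named numeric vector `c(G1, S, G2)`.
#' @export
phase_multipliers <- function(ratio) {
  stopifnot(is.numeric(ratio), ratio > 0)
  c(G1 = 1, S = sqrt(ratio), G2 = ratio)
}
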