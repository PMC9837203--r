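#' Fixed-bin genomic signal track
#'
#' A `signal_track` stores one factor/phase/condition signal as per-chromosome
#' numeric vectors of fixed-width bins (10 bp by default, the resolution at
#' which profiles are counted).  Raw tracks hold non-negative integer bin
#' counts; normalized tracks (reads-per-million, input-subtracted) hold reals
#' and may be negative.
#'
#' @param bins named list, chromosome -> numeric vector of bin values.
#' @param bin_size bin width in bp.
#' @param factor,phase,condition track metadata.
#' @param library_size total mapped reads of the library the track came from.
#' @param normalized logical; `TRUE` after RPM/input normalization.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(bins, bin_size = 10L, factor = NA_character_,
                         phase = NA_character_, condition = "WT",
                         library_size = NA_real_, normalized = FALSE) {
  assert_that(is.list(bins) && length(bins) > 0 && !is.null(names(bins)),
              "bins must be a named list of numeric vectors")
  assert_that(all(vapply(bins, is.numeric, logical(1))),
              "all bin vectors must be numeric")
  if (!normalized) {
    ok <- vapply(bins, function(v) all(v >= 0 & v == trunc(v)), logical(1))
    assert_that(all(ok), "raw tracks must have non-negative integer bin counts")
  }
  structure(list(bins = bins, bin_size = as.integer(bin_size), factor = factor,
                 phase = phase, condition = condition,
                 library_size = library_size, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s %s %s | %d chrom | bin %d bp | lib %s | %s\n",
              x$factor, x$phase, x$condition, length(x$bins), x$bin_size,
              format(x$library_size), if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Chromosome sizes of a track
#' @param track a [signal_track()].
#' @return named integer vector of chromosome lengths in bp.
#' @export
track_chrom_sizes <- function(track) {
  vapply(track$bins, function(v) length(v) * track$bin_size, numeric(1))
}

#' Write a track as bedGraph
#'
#' Adjacent bins with equal values are merged into one interval; zero-valued
#' runs are omitted (absent intervals read back as 0).
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  rows <- lapply(names(track$bins), function(ch) {
    v <- track$bins[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table(chrom = ch,
               start = starts[keep] * track$bin_size,
               end = pmin(ends[keep] * track$bin_size,
                          length(v) * track$bin_size),
               value = r$values[keep])
  })
  dt <- rbindlist(rows)
  fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' Read a bedGraph file into a track
#'
#' Intervals must be aligned to the bin grid (starts and ends multiples of
#' `bin_size`, except an end that equals the chromosome length); off-grid
#' intervals are an error.  Positions not covered by any interval are 0.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @param normalized whether the file holds normalized (real-valued) signal.
#' @param ... metadata passed to [signal_track()] (`factor`, `phase`, ...).
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 10L, normalized = TRUE,
                          ...) {
  assert_that(!is.null(names(chrom_sizes)), "chrom_sizes must be named")
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  assert_that(all(dt$chrom %in% names(chrom_sizes)),
              "bedGraph names a chromosome absent from chrom_sizes")
  assert_that(all(dt$start >= 0 & dt$start < dt$end), "invalid bedGraph interval")
  bins <- lapply(names(chrom_sizes), function(ch) {
    numeric(ceiling(chrom_sizes[[ch]] / bin_size))
  })
  names(bins) <- names(chrom_sizes)
  for (i in seq_len(nrow(dt))) {
    ch <- dt$chrom[i]; s <- dt$start[i]; e <- dt$end[i]
    L <- chrom_sizes[[ch]]
    if (s %% bin_size != 0 || (e %% bin_size != 0 && e != L) || e > L) {
      stop_("bedGraph line %d: interval [%d,%d) is off the %d-bp grid",
            i, s, e, bin_size)
    }
    b0 <- s %/% bin_size + 1L
    b1 <- ceiling(e / bin_size)
    bins[[ch]][b0:b1] <- dt$value[i]
  }
  signal_track(bins, bin_size = bin_size, normalized = normalized, ...)
}
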