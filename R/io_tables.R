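read_lines_table <- function(path, n_fields, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad)) {
    stop_("%s '%s': line %d has %d field(s), expected %d",
          what, path, bad[1], lengths(parts)[bad[1]], n_fields)
  }
  parts
}

#' Write / read a TSS annotation as BED6
#'
#' Each TSS is a 1-bp interval `[tss, tss+1)` with the gene id in the name
#' column; coordinates 0-based half-open on disk and in memory.
#'
#' @param annotation TSS annotation table.
#' @param path file path.
#' @return `write_tss_table`: `path` invisibly; `read_tss_table`: the
#'   annotation `data.table`.
#' @export
write_tss_table <- function(annotation, path) {
  validate_annotation(annotation)
  dt <- data.table(annotation$chrom, annotation$tss, annotation$tss + 1L,
                   annotation$gene_id, 0L, annotation$strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  parts <- read_lines_table(path, 6L, "TSS BED6")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e) {
      stop_("TSS BED6 '%s': line %d has invalid coordinates", path, i)
    }
    if (!p[6] %in% c("+", "-")) {
      stop_("TSS BED6 '%s': line %d has invalid strand '%s'", path, i, p[6])
    }
  }
  ann <- data.table(chrom = vapply(parts, `[`, "", 1L),
                    tss = vapply(parts, function(p) as.integer(p[2]), 0L),
                    strand = vapply(parts, `[`, "", 6L),
                    gene_id = vapply(parts, `[`, "", 4L))
  validate_annotation(ann)
  ann[]
}

#' Write / read peak calls as BED5
#' @param peaks `data.table(chrom, start, end, score)`.
#' @param path file path.
#' @return `read_peaks`: sorted `data.table(chrom, start, end, score)`.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table(peaks$chrom, peaks$start, peaks$end,
                   sprintf("peak_%d", seq_len(nrow(peaks))), peaks$score)
  fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  parts <- read_lines_table(path, 5L, "peak BED5")
  pk <- data.table(chrom = vapply(parts, `[`, "", 1L),
                   start = vapply(parts, function(p) as.integer(p[2]), 0L),
                   end = vapply(parts, function(p) as.integer(p[3]), 0L),
                   score = vapply(parts, function(p) as.numeric(p[5]), 0))
  bad <- which(is.na(pk$start) | is.na(pk$end) | pk$start < 0 | pk$start >= pk$end)
  if (length(bad)) stop_("peak BED5 '%s': line %d invalid interval", path, bad[1])
  setorder(pk, chrom, start)
  pk[]
}

#' Write / read a restriction-fragment map as BED4 (index in the name)
#' @param fragmap `data.table(chrom, start, end, frag_index)`.
#' @param path file path.
#' @return `read_fragment_map`: the fragment map `data.table`.
#' @export
write_fragment_map <- function(fragmap, path) {
  dt <- data.table(fragmap$chrom, fragmap$start, fragmap$end, fragmap$frag_index)
  fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  parts <- read_lines_table(path, 4L, "fragment BED4")
  fm <- data.table(chrom = vapply(parts, `[`, "", 1L),
                   start = vapply(parts, function(p) as.integer(p[2]), 0L),
                   end = vapply(parts, function(p) as.integer(p[3]), 0L),
                   frag_index = vapply(parts, function(p) as.integer(p[4]), 0L))
  setorder(fm, frag_index)
  for (ch in unique(fm$chrom)) {
    sub <- fm[chrom == ch]
    if (nrow(sub) > 1 && any(sub$start[-1] != sub$end[-nrow(sub)])) {
      stop_("fragment map '%s': fragments do not tile chromosome %s", path, ch)
    }
  }
  fm[]
}

#' Write / read the long Capture-C interaction table (TSV)
#' @param table long interaction `data.table` (see [simulate_capture()]).
#' @param path file path.
#' @return `read_interaction_table`: the validated `data.table`.
#' @export
write_interaction_table <- function(table, path) {
  validate_interaction_table(table)
  fwrite(table, path, sep = "\t", scipen = 50L)
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  tab <- fread(path, sep = "\t")
  validate_interaction_table(tab)
  tab[]
}

#' Write / read a gene x sample count matrix (TSV, first column gene_id)
#' @param counts matrix with gene rownames.
#' @param path file path.
#' @return `read_counts`: matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts), as.data.table(counts))
  fwrite(dt, path, sep = "\t", scipen = 50L)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  dt <- fread(path, sep = "\t")
  assert_that("gene_id" %in% names(dt), "counts file lacks column gene_id")
  if (anyDuplicated(dt$gene_id)) {
    stop_("counts file '%s': duplicated gene_id '%s'", path,
          dt$gene_id[anyDuplicated(dt$gene_id)])
  }
  m <- as.matrix(dt[, -"gene_id"])
  rownames(m) <- dt$gene_id
  assert_that(all(m >= 0), "counts must be non-negative")
  m
}

#' Write / read a differential-expression statistics table (TSV)
#' @param de `data.table(gene_id, log2fc, fdr)`.
#' @param path file path.
#' @return `read_de_table`: the validated `data.table`.
#' @export
write_de_table <- function(de, path) {
  fwrite(de[, .(gene_id, log2fc, fdr)], path, sep = "\t", scipen = 50L)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- fread(path, sep = "\t")
  miss <- setdiff(c("gene_id", "log2fc", "fdr"), names(de))
  assert_that(length(miss) == 0, "DE table '%s' lacks column(s): %s", path,
              paste(miss, collapse = ", "))
  assert_that(all(de$fdr >= 0 & de$fdr <= 1), "DE table '%s': fdr outside [0, 1]",
              path)
  de[]
}

#' Write / read a one-id-per-line gene list
#' @param genes character vector.
#' @param path file path.
#' @return `read_gene_list`: character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  out <- readLines(path)
  out[nzchar(out)]
}
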