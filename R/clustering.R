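roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))

cluster_dist <- function(mat, distance) {
  if (distance == "correlation") {
    as.dist(1 - cor(t(mat)))
  } else {
    dist(mat, method = distance)
  }
}

#' Hierarchical clustering of gene expression patterns
#'
#' Agglomerative clustering of gene rows (default distance 1 - Pearson
#' correlation, average linkage), with the tree cut into `k_major` clusters
#' labelled by decreasing size (largest = I).  A named cluster can be sub-cut
#' into `-A`/`-B`... sub-clusters, optionally on a column subset, with its own
#' distance/linkage and optional row-centring - useful when the sub-structure
#' lives on a few columns (e.g. a phase preference confined to one treatment)
#' that genome-wide correlation distance cannot see.
#'
#' Rows with zero variance (for which correlation is undefined) are held out
#' of the tree and assigned to the nearest cluster by Euclidean distance to
#' the cluster centroids, with a message.  With `min_frac > 0`, branches
#' smaller than that fraction of the rows are treated as outliers: they are
#' removed, the tree re-cut, and the outlier rows assigned to the nearest
#' surviving centroid in the same way - this keeps a handful of patternless
#' rows from usurping a whole cluster of the `k_major` cut.
#'
#' @param mat gene x sample numeric matrix with rownames.
#' @param k_major number of major clusters.
#' @param distance `"correlation"` (1 - Pearson) or a [stats::dist()] method.
#' @param linkage an [stats::hclust()] agglomeration method.
#' @param subcluster optional list with elements `cluster` (major label to
#'   split), `k`, and optionally `cols`, `distance`, `linkage`,
#'   `row_center`, and `refine` (when `TRUE`, the sub-cut is polished by a
#'   k-means step seeded with the sub-cluster centroids, which moves
#'   boundary genes to their nearest centre).
#' @param min_frac minimum cluster size of the major cut as a fraction of the
#'   clustered rows; smaller branches are outliers (see above).
#' @return list with `labels` (named character; sub-cut rows get
#'   `"<major>-A"`, `"<major>-B"`, ... by decreasing size), `tree` (the major
#'   [stats::hclust()] tree), and `sub_tree` (if a sub-cut was requested).
#' @export
hclust_genes <- function(mat, k_major = 3L, distance = "correlation",
                         linkage = "average", subcluster = NULL,
                         min_frac = 0) {
  mat <- as.matrix(mat)
  assert_that(!is.null(rownames(mat)), "mat must have gene rownames")
  assert_that(nrow(mat) >= k_major, "fewer rows than requested clusters")
  rv <- apply(mat, 1, var)
  flat <- distance == "correlation" & rv < .Machine$double.eps
  core <- mat[!flat, , drop = FALSE]
  assert_that(nrow(core) >= k_major,
              "too few non-constant rows for the requested clusters")
  min_size <- ceiling(min_frac * nrow(core))
  hc <- NULL
  repeat {
    hc <- hclust(cluster_dist(core, distance), method = linkage)
    raw <- cutree(hc, k = k_major)
    sizes <- table(raw)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0L || nrow(core) - sum(sizes[small]) <
          max(k_major, min_size * k_major)) break
    core <- core[!raw %in% as.integer(small), , drop = FALSE]
  }
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(roman_labels(k_major), names(sizes))
  labels <- setNames(unname(relabel[as.character(raw)]), rownames(core))

  held_out <- setdiff(rownames(mat), rownames(core))
  if (length(held_out)) {
    message(sprintf("%d row(s) assigned by Euclidean centroid fallback",
                    length(held_out)))
    cents <- do.call(rbind, lapply(split(rownames(core), labels), function(ids) {
      colMeans(core[ids, , drop = FALSE])
    }))
    for (g in held_out) {
      d2 <- rowSums(sweep(cents, 2, mat[g, ])^2)
      labels[g] <- names(which.min(d2))
    }
  }

  sub_tree <- NULL
  if (!is.null(subcluster)) {
    assert_that(all(c("cluster", "k") %in% names(subcluster)),
                "subcluster needs elements 'cluster' and 'k'")
    ids <- names(labels)[labels == subcluster$cluster]
    assert_that(length(ids) >= subcluster$k,
                "cluster '%s' too small to sub-cut", subcluster$cluster)
    sm <- mat[ids, subcluster$cols %||% seq_len(ncol(mat)), drop = FALSE]
    if (isTRUE(subcluster$row_center)) sm <- sm - rowMeans(sm)
    sub_tree <- hclust(cluster_dist(sm, subcluster$distance %||% distance),
                       method = subcluster$linkage %||% linkage)
    sraw <- cutree(sub_tree, k = subcluster$k)
    if (isTRUE(subcluster$refine)) {
      cents <- do.call(rbind, lapply(split(seq_along(sraw), sraw), function(ix) {
        colMeans(sm[ix, , drop = FALSE])
      }))
      km <- stats::kmeans(sm, centers = cents, iter.max = 25L)
      sraw <- setNames(km$cluster, names(sraw))
    }
    ssizes <- sort(table(sraw), decreasing = TRUE)
    srelabel <- setNames(paste0(subcluster$cluster, "-", LETTERS[seq_along(ssizes)]),
                         names(ssizes))
    labels[ids] <- unname(srelabel[as.character(sraw)])
  }
  labels <- labels[rownames(mat)]
  list(labels = labels, tree = hc, sub_tree = sub_tree)
}

#' Match recovered cluster labels to truth and score accuracy
#'
#' Greedy best-overlap matching between recovered and true labels (ties by
#' overlap size), then the fraction of genes whose matched label equals the
#' truth.
#'
#' @param recovered,truth named character vectors over the same genes.
#' @return list with `mapping` (recovered -> truth label) and `accuracy`.
#' @export
cluster_label_accuracy <- function(recovered, truth) {
  genes <- intersect(names(recovered), names(truth))
  assert_that(length(genes) > 0, "no shared genes")
  r <- recovered[genes]; tr <- truth[genes]
  tab <- table(r, tr)
  mapping <- character(0)
  free_r <- rownames(tab); free_t <- colnames(tab)
  while (length(free_r) && length(free_t)) {
    sub <- tab[free_r, free_t, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    mapping[free_r[ij[1]]] <- free_t[ij[2]]
    free_r <- setdiff(free_r, free_r[ij[1]])
    free_t <- setdiff(free_t, free_t[ij[2]])
  }
  mapped <- mapping[r]
  list(mapping = mapping,
       accuracy = mean(!is.na(mapped) & mapped == tr))
}
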