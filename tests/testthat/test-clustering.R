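block_matrix <- function(n_per = 10, p = 12, seed = 3) {
  set.seed(seed)
  up <- sin(seq_len(p))
  m <- rbind(
    t(replicate(n_per, up * 2 + rnorm(p, sd = 0.2))),
    t(replicate(n_per, -up * 2 + rnorm(p, sd = 0.2)))
  )
  rownames(m) <- sprintf("g%02d", seq_len(2 * n_per))
  m
}

test_that("well-separated correlated blocks split perfectly at k = 2", {
  m <- block_matrix()
  res <- hclust_genes(m, k_major = 2L)
  lab <- res$labels
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])
})

test_that("row permutation leaves the partition unchanged", {
  m <- block_matrix()
  res1 <- hclust_genes(m, k_major = 2L)
  perm <- sample(nrow(m))
  res2 <- hclust_genes(m[perm, ], k_major = 2L)
  acc <- cluster_label_accuracy(res2$labels, res1$labels)
  expect_equal(acc$accuracy, 1)
})

test_that("average-linkage merge heights match a naive O(n^3) oracle", {
  set.seed(9)
  m <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(letters[1:6], NULL))
  res <- hclust_genes(m, k_major = 2L)

  # naive average linkage on 1 - Pearson: repeatedly merge the closest pair,
  # recomputing every between-cluster distance as the mean pairwise distance
  d0 <- 1 - cor(t(m))
  clusters <- as.list(seq_len(6))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dd < best[1]) best <- c(dd, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(res$tree$height, sort(heights), tolerance = 1e-12)
})

test_that("constant rows fall back to nearest-centroid assignment", {
  m <- block_matrix()
  m <- rbind(m, flat = rep(3, ncol(m)))
  expect_message(res <- hclust_genes(m, k_major = 2L), "fallback")
  expect_true(res$labels[["flat"]] %in% c("I", "II"))
  expect_length(res$labels, nrow(m))
})

test_that("small outlier branches do not usurp a major cluster", {
  m <- block_matrix(n_per = 20)
  set.seed(4)
  m <- rbind(m, out1 = rnorm(ncol(m)))   # one patternless straggler
  res <- hclust_genes(m, k_major = 2L, min_frac = 0.05)
  lab <- res$labels
  # both true blocks survive as the two clusters despite the straggler
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_false(lab[1] == lab[21])
})

test_that("sub-clustering splits a named cluster on selected columns", {
  set.seed(5)
  p <- 9
  up <- rep(c(-1, 1, 1), each = 3)
  a <- t(replicate(15, up * 2 + c(0, 0, 0, 1, 0, -1, 0, 0, 0) + rnorm(p, sd = .15)))
  b <- t(replicate(15, up * 2 + rnorm(p, sd = .15)))
  dn <- t(replicate(15, -up * 2 + rnorm(p, sd = .15)))
  m <- rbind(a, b, dn)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  res <- hclust_genes(m, k_major = 2L,
                      subcluster = list(cluster = "I", k = 2L, cols = 4:6,
                                        distance = "euclidean",
                                        linkage = "ward.D2",
                                        row_center = TRUE, refine = TRUE))
  lab <- res$labels
  expect_setequal(unique(lab), c("I-A", "I-B", "II"))
  # the a-rows and b-rows end up in different sub-clusters
  expect_equal(length(unique(lab[1:15])), 1L)
  expect_equal(length(unique(lab[16:30])), 1L)
  expect_false(lab[1] == lab[16])
})

test_that("label accuracy matching is permutation-proof", {
  truth <- setNames(rep(c("x", "y"), each = 5), sprintf("g%02d", 1:10))
  rec <- setNames(rep(c("B", "A"), each = 5), names(truth))
  acc <- cluster_label_accuracy(rec, truth)
  expect_equal(acc$accuracy, 1)
  rec2 <- rec; rec2[1] <- "A"
  expect_equal(cluster_label_accuracy(rec2, truth)$accuracy, 0.9)
})
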