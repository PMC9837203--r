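test_that("peak-to-promoter assignment honours half-open windows", {
  ann <- data.table(chrom = "chr1", tss = 10000L, strand = "+",
                    gene_id = "g1")
  hit <- data.table(chrom = "chr1", start = 9900L, end = 10100L, score = 1)
  expect_equal(assign_peaks_to_promoters(hit, ann), "g1")
  # peak ending exactly at the window start (half-open abutting) is excluded
  abut <- data.table(chrom = "chr1", start = 9000L, end = 9500L, score = 1)
  expect_length(assign_peaks_to_promoters(abut, ann), 0)
  # one-bp overlap is enough
  graze <- data.table(chrom = "chr1", start = 9000L, end = 9501L, score = 1)
  expect_equal(assign_peaks_to_promoters(graze, ann), "g1")
})

test_that("interval-index assignment equals a quadratic all-pairs oracle", {
  set.seed(42)
  n <- 50
  ann <- data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                    tss = sample(5000:200000, n),
                    strand = sample(c("+", "-"), n, TRUE),
                    gene_id = sprintf("g%02d", 1:n))
  pk <- data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = sample(0:200000, n))
  pk[, end := start + sample(50:5000, n)]
  pk[, score := 1]
  got <- assign_peaks_to_promoters(pk, ann)
  # brute force in 0-based half-open coordinates; minus-strand window is
  # (tss - 1500, tss + 501) as half-open [tss - 1499, tss + 501)
  oracle <- vapply(seq_len(n), function(i) {
    t <- ann$tss[i]
    win <- if (ann$strand[i] == "+") c(t - 500, t + 1500) else
      c(t - 1499, t + 501)
    any(pk$chrom == ann$chrom[i] & pk$start < win[2] & pk$end > win[1])
  }, logical(1))
  expect_setequal(got, ann$gene_id[oracle])
})

test_that("union across phases behaves as set union", {
  expect_setequal(union_targets(list(c("a"), c("b"), c("c"))), c("a", "b", "c"))
  expect_setequal(union_targets(list(c("a", "b"), c("a", "b"))), c("a", "b"))
  expect_setequal(union_targets(list(c("a", "b"), character())), c("a", "b"))
  sets <- list(G1 = c("a", "b"), S = c("b", "c"), G2 = "d")
  expect_gte(length(union_targets(sets)), max(lengths(sets)))
})

test_that("PRC class partition matches its definition exhaustively", {
  # every membership combination of one gene across the four factor sets
  combos <- expand.grid(r = c(TRUE, FALSE), y = c(TRUE, FALSE),
                        c = c(TRUE, FALSE), e = c(TRUE, FALSE))
  for (i in seq_len(nrow(combos))) {
    g <- "gene"
    cl <- classify_prc_classes(ring1b = if (combos$r[i]) g else character(),
                               rybp = if (combos$y[i]) g else character(),
                               cbx7 = if (combos$c[i]) g else character(),
                               ezh2 = if (combos$e[i]) g else character())
    in_vcp <- combos$r[i] && combos$y[i] && combos$c[i] && combos$e[i]
    in_vonly <- combos$r[i] && combos$y[i] && !combos$c[i] && !combos$e[i]
    expect_equal(g %in% cl$vcp_targets, in_vcp)
    expect_equal(g %in% cl$v_only_targets, in_vonly)
  }
  # intermediate combination (ring1b + rybp + cbx7 only) joins neither class
  cl <- classify_prc_classes("g", "g", "g", character())
  expect_length(cl$vcp_targets, 0)
  expect_length(cl$v_only_targets, 0)

  # random universes: classes always disjoint subsets of ring1b & rybp
  set.seed(7)
  for (rep in 1:25) {
    u <- sprintf("g%02d", 1:20)
    pick <- function() sample(u, sample(0:20, 1))
    r <- pick(); y <- pick(); cb <- pick(); e <- pick()
    cl <- classify_prc_classes(r, y, cb, e)
    expect_length(intersect(cl$vcp_targets, cl$v_only_targets), 0)
    expect_true(all(cl$vcp_targets %in% intersect(r, y)))
    expect_true(all(cl$v_only_targets %in% intersect(r, y)))
  }
})

test_that("unbound controls use strict band inequalities", {
  genes <- c("a", "b", "c", "d", "e")
  fc <- c(a = 0.1, b = 0.2, c = -0.2, d = 0, e = 0.19999)
  got <- select_unbound_controls(genes, target_union = "d", fc, band = 0.2)
  # b and c sit exactly on the boundary -> excluded; d is bound -> excluded
  expect_setequal(got, c("a", "e"))
})

test_that("overlap fractions report raw, rounded and truncated values", {
  a <- sprintf("g%04d", 1:1678)
  b <- a[1:1575]
  ov <- overlap_fraction(a, b)
  expect_equal(ov$fraction, 100 * 1575 / 1678)
  expect_equal(ov$display_rounded, 93.9)
  expect_equal(ov$display_truncated, 93.8)
  expect_equal(overlap_fraction(c("x", "y"), c("x", "y", "z"))$fraction, 100)
  expect_equal(overlap_fraction("x", "z")$fraction, 0)
  expect_error(overlap_fraction(character(), "z"), "non-empty")
})
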