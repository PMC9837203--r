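test_that("RPM/input normalization follows the subtraction formula", {
  sig <- constant_track(10, normalized = FALSE, library_size = 1e6)
  inp <- constant_track(2, normalized = FALSE, library_size = 1e6)
  out <- normalize_track(sig, inp)
  expect_true(out$normalized)
  expect_equal(unique(out$bins$chr1), 8.0)

  # signal identical to input with equal library sizes -> all-zero track
  out0 <- normalize_track(sig, sig)
  expect_equal(unique(out0$bins$chr1), 0)

  # joint x10 rescaling of counts and library sizes leaves the output unchanged
  sig10 <- constant_track(100, normalized = FALSE, library_size = 1e7)
  inp10 <- constant_track(20, normalized = FALSE, library_size = 1e7)
  expect_equal(normalize_track(sig10, inp10)$bins, out$bins)

  bad <- constant_track(1, n_bins = 10L, normalized = FALSE, library_size = 10)
  expect_error(normalize_track(sig, bad), "mismatch")
})

make_ann <- function(tss, strand, gene_id = sprintf("g%02d", seq_along(tss))) {
  data.table(chrom = "chr1", tss = as.integer(tss), strand = strand,
             gene_id = gene_id)
}

test_that("promoter coverage is strand-aware with a mirror-exact window", {
  const <- constant_track(3.5)
  ann <- make_ann(c(2000, 2000), c("+", "-"))
  expect_equal(unname(promoter_coverage(const, ann)), c(3.5, 3.5))

  # + gene: value 1 only in [tss, tss+1000) -> window mean 0.5
  bins <- numeric(400); bins[201:300] <- 1   # bp [2000, 3000)
  tr <- signal_track(list(chr1 = bins), normalized = TRUE)
  plus <- promoter_coverage(tr, make_ann(2000, "+"))
  expect_equal(unname(plus), 0.5)

  # - gene mirror: reversing the track and flipping strand reproduces it
  trm <- signal_track(list(chr1 = rev(bins)), normalized = TRUE)
  minus <- promoter_coverage(trm, make_ann(4000 - 2000 - 1, "-"))
  expect_equal(unname(minus), unname(plus))

  expect_error(promoter_coverage(tr, data.table(chrom = "chr9", tss = 1L,
                                                strand = "+", gene_id = "x")),
               "absent")
})

test_that("profile matrices are oriented 5'->3' with the documented shape", {
  const <- constant_track(2, n_bins = 4000L)
  ann <- make_ann(c(20000, 20000), c("+", "-"))
  m <- profile_matrix(const, ann, span = 10000)
  expect_equal(ncol(m), 2000L)
  expect_true(all(m == 2))

  # a minus-strand profile equals the reversed plus-strand profile on the
  # mirrored track
  bins <- rnorm(4000)
  tr <- signal_track(list(chr1 = bins), normalized = TRUE)
  trm <- signal_track(list(chr1 = rev(bins)), normalized = TRUE)
  p_plus <- profile_matrix(tr, make_ann(20000, "+"), span = 2000)
  p_minus <- profile_matrix(trm, make_ann(40000 - 20000 - 1, "-"), span = 2000)
  expect_equal(unname(p_minus), unname(p_plus))

  # out-of-bounds bins are zero-filled and counted
  p_edge <- profile_matrix(tr, make_ann(100, "+"), span = 2000)
  expect_gt(attr(p_edge, "oob_bins"), 0)
})

test_that("percentile trimming winsorizes jointly and idempotently", {
  m <- matrix(1:100, nrow = 1)
  out <- trim_percentiles(m, 5, 95)
  # type-7 linear interpolation: h = (n-1) p + 1
  expect_equal(min(out), 5.95)
  expect_equal(max(out), 95.05)
  expect_equal(trim_percentiles(out, 5, 95), out)   # idempotent

  cm <- matrix(7, 3, 3)
  expect_equal(as.vector(trim_percentiles(cm)), as.vector(cm))

  # joint trimming: percentiles computed over the displayed set together
  lst <- list(a = matrix(1:50, 1), b = matrix(51:100, 1))
  joint <- trim_percentiles(lst)
  expect_equal(min(joint$a), 5.95)
  expect_equal(max(joint$b), 95.05)
})

test_that("reference-phase ranking is descending, stable and order-invariant", {
  pm <- list(G1 = c(a = 1, b = 9, c = 2),
             G2 = c(a = 5, b = 3, c = 5))
  expect_equal(rank_by_reference(pm, "G2"), c("a", "c", "b"))  # tie -> id order
  pm2 <- lapply(pm, function(v) v[c(3, 1, 2)])
  expect_equal(rank_by_reference(pm2, "G2"), c("a", "c", "b"))
  expect_error(rank_by_reference(pm, "G0"), "not supplied")
})

test_that("average profiles are column means", {
  m <- rbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(unname(average_profile(m)), c(2, 3, 4))
  expect_equal(unname(average_profile(m[1, , drop = FALSE])), c(1, 2, 3))
})

test_that("one-way ANOVA matches the textbook sums-of-squares and edge cases", {
  res <- profile_anova(list(G1 = c(1, 2, 3), S = c(4, 5, 6), G2 = c(7, 8, 9)))
  # by hand: SSB = 3((2-5)^2 + 0 + (8-5)^2) = 54 on 2 df; SSW = 6 on 6 df
  expect_equal(res$F, 27, tolerance = 1e-9)
  expect_equal(res$p, stats::pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-9)

  # location invariance
  res2 <- profile_anova(list(G1 = c(1, 2, 3) + 10, S = c(4, 5, 6) + 10,
                             G2 = c(7, 8, 9) + 10))
  expect_equal(res2$F, res$F)

  # identical groups / zero variance -> F = 0, p = 1
  expect_equal(profile_anova(list(a = c(2, 2), b = c(2, 2))), list(F = 0, p = 1))
})

test_that("promoter log2 fold changes floor negatives and use the pseudocount", {
  a <- c(g1 = 4, g2 = 0, g3 = 2)
  b <- c(g1 = 4, g2 = 0, g3 = 2)
  expect_equal(unname(promoter_log2fc(a, b)), c(0, 0, 0))
  expect_equal(unname(promoter_log2fc(c(x = 4), c(x = 2), pseudocount = 0)), 1)
  # negative normalized means are floored before the pseudocount
  expect_equal(unname(promoter_log2fc(c(x = -3), c(x = 0))), 0)
})
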