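test_that("capture normalization follows normCounts = raw * nprom * 1e5 / cov", {
  expect_equal(norm_counts(10, cov = 1e6, nprom = 122), 122.0)
  expect_equal(norm_counts(0, cov = 1e6, nprom = 122), 0)
  # joint rescaling of raw counts and cov cancels
  expect_equal(norm_counts(30, cov = 2e6, nprom = 122),
               norm_counts(300, cov = 2e7, nprom = 122))
  expect_error(norm_counts(1, cov = 0, nprom = 122), "cov")
})

test_that("interaction tables validate their schema and condition labels", {
  fx <- toy_capture()
  expect_silent(tab <- normalize_interaction_table(fx$table))
  expect_true("norm_counts" %in% names(tab))
  bad <- copy(fx$table)[1, condition := "G3_WT"]
  expect_error(normalize_interaction_table(bad), "unknown condition")
  expect_error(normalize_interaction_table(fx$table[, -"score"]), "score")
})

test_that("interaction calling applies the score cutoff, ATAC filter and gaps", {
  frag_len <- 100L
  base <- data.table(viewpoint_id = "v", chrom = "chr1",
                     frag_index = 10:17,
                     frag_start = (10:17 - 1L) * frag_len,
                     frag_end = (10:17) * frag_len,
                     condition = "G2_WT",
                     counts = c(5, 9, 8, 1, 2, 7, 6, 1))
  vp <- data.table(gene_id = "v", vp_frag = 1L)
  atac_all <- data.table(chrom = "chr1", start = 0L, end = 2000L, score = 1)

  # scores (4.9, 5.0, 6, 3) at fragments 10..13 -> one run spanning 11..12
  t1 <- copy(base)[, score := c(4.9, 5, 6, 3, 0, 0, 0, 0)]
  got <- call_interactions(t1, atac_all, vp)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$i_lo, got$i_hi), c(11L, 12L))
  expect_equal(got$summit, 11L)   # counts 9 > 8

  # two significant runs separated by one failing fragment -> two interactions
  t2 <- copy(base)[, score := c(6, 6, 6, 2, 6, 6, 0, 0)]
  got2 <- call_interactions(t2, atac_all, vp)
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$i_lo, c(10L, 14L))

  # a significant fragment with no ATAC overlap is never called
  atac_none <- data.table(chrom = "chr1", start = 5000L, end = 6000L, score = 1)
  expect_equal(nrow(call_interactions(t1, atac_none, vp)), 0L)

  # unresolvable viewpoint fragment is an explicit error
  expect_error(call_interactions(t1, atac_all,
                                 data.table(gene_id = "v", vp_frag = NA)),
               "unresolvable")
})

test_that("interval sums are additive over split intervals", {
  fx <- toy_capture()
  tab <- normalize_interaction_table(fx$table)
  ints <- call_interactions(tab, fx$atac, fx$viewpoints)
  expect_equal(nrow(ints), 1L)
  whole <- sum_interval_counts(ints, tab, "G1_WT")$sum_norm_counts
  left <- copy(ints)[, i_hi := summit]
  right <- copy(ints)[, i_lo := summit + 1L]
  expect_equal(sum_interval_counts(left, tab, "G1_WT")$sum_norm_counts +
                 sum_interval_counts(right, tab, "G1_WT")$sum_norm_counts,
               whole)
  single <- copy(ints)[, `:=`(i_lo = summit, i_hi = summit)]
  sv <- sum_interval_counts(single, tab, "G1_WT")$sum_norm_counts
  expect_equal(sv, tab[condition == "G1_WT" & frag_index == ints$summit,
                       norm_counts])
})

test_that("metaprofiles are G2-summit normalized and direction-flipped", {
  fx <- toy_capture()
  tab <- normalize_interaction_table(fx$table)
  ints <- call_interactions(tab, fx$atac, fx$viewpoints)
  expect_equal(ints$summit, fx$summit)
  prof <- build_metaprofile(ints, tab, span = 10L)
  # self-normalization: position 0 in the G2 reference is exactly 1
  expect_identical(prof[condition == "G2_WT" & position == 0, mean], 1)
  # G2/G1 at the summit equals the simulated boost exactly on this
  # noise-free fixture (up to the condition-wise cov scaling)
  r <- prof[condition == "G2_WT" & position == 0, mean] /
    prof[condition == "G1_WT" & position == 0, mean]
  covs <- fx$table[, sum(counts), by = condition]
  expect_equal(r, fx$boost * covs[condition == "G2_WT", V1] /
                 covs[condition == "G1_WT", V1] /
                 (covs[condition == "G2_WT", V1] / covs[condition == "G1_WT", V1])^2,
               tolerance = 1e-12)
  # the knockout profile shows no summit: flat at background/denominator
  ko <- prof[condition == "G2_KO"]
  expect_lt(max(ko$mean) / stats::median(ko$mean), 1.3)

  # orientation: the summit is downstream of the viewpoint, so positive
  # (promoter-proximal) positions point back toward the viewpoint, where the
  # decay background rises
  g1 <- prof[condition == "G1_KO"]
  expect_gt(g1[position == 10, mean], g1[position == -10, mean])
})

test_that("orientation flip is an involution", {
  # mapping offset k -> position k*s with s in {-1, +1}: applying it twice
  # restores the original offsets for either orientation
  for (s in c(-1L, 1L)) {
    k <- -40:40
    expect_equal((k * s) * s, k)
  }
  # and reflecting a summit about the viewpoint twice restores it
  vp <- 100L; summit <- 123L
  ctrl <- 2L * vp - summit
  expect_equal(2L * vp - ctrl, summit)
})

test_that("metaprofiles are invariant under genome mirroring, bit for bit", {
  fx <- toy_capture()
  fm <- mirror_capture(fx)
  t1 <- normalize_interaction_table(fx$table)
  t2 <- normalize_interaction_table(fm$table)
  i1 <- call_interactions(t1, fx$atac, fx$viewpoints)
  i2 <- call_interactions(t2, fm$atac, fm$viewpoints)
  expect_identical(i2$distance, i1$distance)
  p1 <- build_metaprofile(i1, t1, span = 15L)
  p2 <- build_metaprofile(i2, t2, span = 15L)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$sem, p2$sem)
  c1 <- distance_matched_controls(i1, t1, span = 15L)
  c2 <- distance_matched_controls(i2, t2, span = 15L)
  expect_identical(c1$profile$mean, c2$profile$mean)
})

test_that("distance-matched controls reflect about the viewpoint", {
  fx <- toy_capture(vp = 200L, summit = 350L)
  tab <- normalize_interaction_table(fx$table)
  ints <- call_interactions(tab, fx$atac, fx$viewpoints)
  ctrl <- distance_matched_controls(ints, tab, span = 10L)
  expect_equal(ctrl$controls$control_summit, 50L)
  # control profile is flat: no peak at position 0
  cp <- ctrl$profile[condition == "G2_WT"]
  expect_lt(max(cp$mean) / stats::median(cp$mean), 1.3)
  expect_lt(cp[position == 0, mean], 0.5)
})

test_that("interactions with non-positive G2 summit values are dropped", {
  fx <- toy_capture()
  tab <- normalize_interaction_table(fx$table)
  ints <- call_interactions(tab, fx$atac, fx$viewpoints)
  tab0 <- copy(tab)[condition == "G2_WT" & frag_index == ints$summit,
                    norm_counts := 0]
  expect_warning(expect_error(build_metaprofile(ints, tab0), "no interaction"),
                 "dropping")
})

test_that("Mann-Whitney group comparison matches exact enumeration", {
  # all 20 rank assignments of {1,2,3} vs {4,5,6}: U = 0, two-sided p = 0.1
  res <- compare_interaction_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  # identical groups (exact, no ties across groups is violated -> approx path)
  same <- compare_interaction_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)
  # rank invariance under positive scaling
  res2 <- compare_interaction_groups(c(1, 2, 3) * 17, c(4, 5, 6) * 17)
  expect_equal(res2$p, res$p)
  expect_equal(res2$U, res$U)
})
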