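test_that("truth table encodes the configured occupancy structure", {
  cfg <- small_chip_config(seed = 5, ring1b_phase_ratio = 1.0,
                           rybp_phase_ratio = 3.0)
  ann <- generate_annotation(cfg)
  truth <- make_truth(cfg, ann)
  expect_setequal(unique(truth$group), c("vcp", "v_only", "unbound"))
  # RING1B at ratio 1: occupancy identical across phases for every gene
  expect_equal(truth$occ_RING1B_G1, truth$occ_RING1B_G2)
  expect_equal(truth$occ_RING1B_G1, truth$occ_RING1B_S)
  # RYBP at ratio 3: G2/G1 = 3 at every bound gene, S at geometric midpoint
  bnd <- truth$group != "unbound"
  expect_equal(truth$occ_RYBP_G2[bnd] / truth$occ_RYBP_G1[bnd],
               rep(3, sum(bnd)))
  expect_equal(truth$occ_RYBP_S[bnd] / truth$occ_RYBP_G1[bnd],
               rep(sqrt(3), sum(bnd)))
  # CBX7/EZH2 bind only the vcp class
  expect_true(all(truth$occ_CBX7_G1[truth$group == "v_only"] == 0))
  expect_true(all(truth$occ_EZH2_G1[truth$group == "vcp"] > 0))
  expect_true(all(truth$occ_RING1B_G1[truth$group == "unbound"] == 0))
})

test_that("simulated chip output is deterministic and conserves counts", {
  cfg <- small_chip_config(seed = 6)
  ann <- generate_annotation(cfg)
  c1 <- simulate_chip(cfg, ann, factors = "RING1B", phases = c("G1", "G2"))
  c2 <- simulate_chip(cfg, ann, factors = "RING1B", phases = c("G1", "G2"))
  expect_identical(c1$tracks$RING1B_G1$bins, c2$tracks$RING1B_G1$bins)
  tr <- c1$tracks$RING1B_G1
  # library size records the total emitted reads
  expect_equal(tr$library_size, sum(vapply(tr$bins, sum, numeric(1))))
  expect_false(tr$normalized)
  # peaks sit at bound promoters only
  pk <- c1$peaks$RING1B_G1
  bound <- c1$truth$gene_id[c1$truth$group != "unbound"]
  expect_equal(nrow(pk), length(bound))
})

test_that("nascent simulation follows the phase and knockout structure", {
  cfg <- small_chip_config(seed = 7, nascent_g1_over_g2 = 2,
                           ko_derepression = c(G1 = 1, S = 1.5, G2 = 3))
  ann <- generate_annotation(cfg)
  truth <- make_truth(cfg, ann)
  nas <- simulate_nascent(cfg, ann, truth)
  unb <- truth$gene_id[truth$group == "unbound"]
  bnd <- truth$gene_id[truth$group != "unbound"]
  # unbound wild type: identical expected counts in all phases
  expect_equal(nas$mu[unb, "G1_WT"], nas$mu[unb, "S_WT"])
  expect_equal(nas$mu[unb, "G1_WT"], nas$mu[unb, "G2_WT"])
  # bound wild type: G1/G2 expected ratio is the configured value
  expect_equal(nas$mu[bnd, "G1_WT"] / nas$mu[bnd, "G2_WT"],
               setNames(rep(2, length(bnd)), bnd))
  # knockout with G1 multiplier 1: G1 means unchanged; G2 multiplied by 3
  expect_equal(nas$mu[, "G1_KO"], nas$mu[, "G1_WT"])
  expect_equal(nas$mu[bnd, "G2_KO"] / nas$mu[bnd, "G2_WT"],
               setNames(rep(3, length(bnd)), bnd))
  expect_equal(nas$mu[unb, "G2_KO"], nas$mu[unb, "G2_WT"])
})

test_that("RA simulation encodes cluster structure and DE tables", {
  cfg <- small_chip_config(seed = 8, ra_genes_per_cluster = 6L)
  ann <- generate_annotation(cfg)
  truth <- make_truth(cfg, ann)
  ra <- simulate_ra_expression(cfg, truth)
  mu0 <- function(cl, cond) {
    ids <- truth$gene_id[truth$cluster == cl]
    rowMeans(ra$mu[ids, grep(cond, colnames(ra$mu)), drop = FALSE])
  }
  # cluster III: repressed at 6 h under both treatments
  expect_true(all(mu0("III", "UNT6") < mu0("III", "t0")))
  expect_true(all(mu0("III", "IAA6") < mu0("III", "t0")))
  # cluster II-A: G1 > S > G2 in untreated 6 h
  iia <- truth$gene_id[truth$cluster == "II-A"]
  expect_true(all(ra$mu[iia, "G1_UNT6_r1"] > ra$mu[iia, "S_UNT6_r1"]))
  expect_true(all(ra$mu[iia, "S_UNT6_r1"] > ra$mu[iia, "G2_UNT6_r1"]))
  # cluster II: IAA amplification on top of RA induction
  iib <- truth$gene_id[truth$cluster == "II-B"]
  expect_true(all(ra$mu[iib, "G1_IAA6_r1"] > ra$mu[iib, "G1_UNT6_r1"]))
  # DE tables cover every gene with valid FDRs
  expect_named(ra$de_tables[1:2], c("G1_UNT6_vs_t0", "G1_IAA6_vs_t0"))
  d <- ra$de_tables[["G1_UNT6_vs_t0"]]
  expect_equal(nrow(d), nrow(truth))
  expect_true(all(d$fdr >= 0 & d$fdr <= 1))
})
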