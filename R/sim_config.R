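#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators.  The defaults encode
#' the effect structure the downstream analyses are designed to detect:
#' constant RING1B occupancy across interphase with G2-enriched RYBP, CBX7 and
#' H2AK119ub1 at polycomb-bound promoters (S phase at the geometric midpoint),
#' lower nascent transcription of bound genes in S/G2 than G1 that is reversed
#' by RING1B loss in S/G2 only, fragment-level 3C counts with power-law
#' distance decay plus a G2-boosted, knockout-ablated homotypic contact, and a
#' retinoic-acid response matrix with cluster I / II (II-A) / III structure.
#'
#' @param seed integer master seed; with the seed fixed every generator is a
#'   pure function of the configuration.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes number of genes; genes are placed with >= 25 kb spacing.
#' @param frag_mean_len mean restriction-fragment length in bp (DpnII-like
#'   four-cutter digests average ~256 bp); fragment lengths are geometric.
#' @param group_fractions named fractions (`vcp`, `v_only`, `unbound`) of genes
#'   bound by vPRC1+cPRC1+PRC2, by vPRC1 only, or unbound; must sum to 1.
#' @param ring1b_phase_ratio,rybp_phase_ratio,cbx7_phase_ratio,h2aub_phase_ratio
#'   G2/G1 promoter occupancy ratios per factor; S phase sits at the geometric
#'   midpoint of G1 and G2.
#' @param nascent_g1_over_g2 G1/G2 ratio of the true nascent transcription rate
#'   at bound genes in wild type.
#' @param ko_derepression named multipliers (`G1`, `S`, `G2`) applied to the
#'   nascent rate of bound genes in the knockout genotype.
#' @param capture_decay_alpha exponent of the 3C distance decay
#'   (expected background ~ d^-alpha in fragment units).
#' @param capture_g2_boost multiplier on the homotypic interaction component in
#'   G2 relative to G1.
#' @param depth expected reads per library (each simulated library is sequenced
#'   to this fixed expected depth; background absorbs the complement of the
#'   signal mass).
#' @param signal_fraction fraction of a ChIP library falling into promoter
#'   signal at the G1 baseline; must satisfy
#'   `signal_fraction * max(phase ratio) < 0.97`.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param expr_base_meanlog,expr_base_sdlog lognormal parameters of per-gene
#'   baseline expression means.
#' @param ra_effect_fold multiplicative retinoic-acid induction/repression
#'   effect used by [simulate_ra_expression()].
#' @param ra_g1_pref G1/G2 preference (fold) of sub-cluster II-A in untreated
#'   6 h samples; S phase at the geometric midpoint.
#' @param ra_n_rep replicate libraries per RA condition.
#' @param ra_genes_per_cluster target size of the RA response clusters: up to
#'   this many unbound genes each join clusters I and III, and up to this many
#'   bound genes each join sub-clusters II-A and II-B; all remaining genes are
#'   RA-inert (`none`), so most of the transcriptome anchors the
#'   between-sample normalization.
#' @param capture_window fragments emitted on either side of each viewpoint.
#' @param capture_partner_range integer range (fragments) from which each
#'   viewpoint's homotypic partner distance is drawn.
#'
#' @return object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, n_chrom = 1, chrom_length = 1e6)
#' cfg$rybp_phase_ratio
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 8e6,
                       n_genes = 500L,
                       frag_mean_len = 250L,
                       group_fractions = c(vcp = 0.2, v_only = 0.4, unbound = 0.4),
                       ring1b_phase_ratio = 1.0,
                       rybp_phase_ratio = 3.0,
                       cbx7_phase_ratio = 3.0,
                       h2aub_phase_ratio = 3.0,
                       nascent_g1_over_g2 = 2.0,
                       ko_derepression = c(G1 = 1.0, S = 1.5, G2 = 3.0),
                       capture_decay_alpha = 1.0,
                       capture_g2_boost = 2.0,
                       depth = 1e6,
                       signal_fraction = 0.30,
                       nb_dispersion = 0.1,
                       expr_base_meanlog = log(100),
                       expr_base_sdlog = 0.5,
                       ra_effect_fold = 4.0,
                       ra_g1_pref = 2.0,
                       ra_n_rep = 4L,
                       ra_genes_per_cluster = 200L,
                       capture_window = 600L,
                       capture_partner_range = c(150L, 400L)) {
  assert_that(is_count(seed, min = 0L), "seed must be a single non-negative integer")
  assert_that(is_count(n_chrom), "n_chrom must be a positive integer")
  assert_that(is_count(chrom_length, min = 1000L), "chrom_length must be >= 1000 bp")
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  assert_that(is_count(frag_mean_len, min = 50L), "frag_mean_len must be >= 50 bp")
  assert_that(length(group_fractions) == 3L &&
                setequal(names(group_fractions), c("vcp", "v_only", "unbound")),
              "group_fractions must be named vcp, v_only, unbound")
  assert_that(abs(sum(group_fractions) - 1) < 1e-9, "group_fractions must sum to 1")
  assert_that(all(group_fractions >= 0), "group_fractions must be non-negative")
  ratios <- c(ring1b_phase_ratio, rybp_phase_ratio, cbx7_phase_ratio,
              h2aub_phase_ratio, nascent_g1_over_g2, capture_decay_alpha,
              capture_g2_boost)
  assert_that(all(is.finite(ratios)) && all(ratios > 0), "all ratios must be > 0")
  assert_that(length(ko_derepression) == 3L &&
                setequal(names(ko_derepression), c("G1", "S", "G2")) &&
                all(ko_derepression > 0),
              "ko_derepression must be positive and named G1, S, G2")
  assert_that(is_count(depth, min = 100L), "depth must be an integer >= 100")
  max_ratio <- max(ring1b_phase_ratio, rybp_phase_ratio, cbx7_phase_ratio,
                   h2aub_phase_ratio, 1)
  assert_that(signal_fraction > 0 && signal_fraction * max_ratio < 0.97,
              "signal_fraction * max phase ratio must stay below 0.97")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(is_count(ra_n_rep), "ra_n_rep must be a positive integer")
  assert_that(is_count(ra_genes_per_cluster),
              "ra_genes_per_cluster must be a positive integer")
  assert_that(ra_effect_fold > 1 && ra_g1_pref >= 1,
              "ra_effect_fold must be > 1 and ra_g1_pref >= 1")
  assert_that(is_count(capture_window, min = 50L), "capture_window must be >= 50")
  assert_that(length(capture_partner_range) == 2L &&
                capture_partner_range[1] >= 1 &&
                capture_partner_range[2] >= capture_partner_range[1],
              "capture_partner_range must be an increasing pair of indices")
  assert_that(capture_partner_range[2] + capture_window <= 4 * capture_window,
              "partner range must fit inside the emitted capture window")

  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    frag_mean_len = as.integer(frag_mean_len),
    group_fractions = group_fractions[c("vcp", "v_only", "unbound")],
    ring1b_phase_ratio = ring1b_phase_ratio,
    rybp_phase_ratio = rybp_phase_ratio,
    cbx7_phase_ratio = cbx7_phase_ratio,
    h2aub_phase_ratio = h2aub_phase_ratio,
    nascent_g1_over_g2 = nascent_g1_over_g2,
    ko_derepression = ko_derepression[c("G1", "S", "G2")],
    capture_decay_alpha = capture_decay_alpha,
    capture_g2_boost = capture_g2_boost,
    depth = as.numeric(depth),
    signal_fraction = signal_fraction,
    nb_dispersion = nb_dispersion,
    expr_base_meanlog = expr_base_meanlog,
    expr_base_sdlog = expr_base_sdlog,
    ra_effect_fold = ra_effect_fold,
    ra_g1_pref = ra_g1_pref,
    ra_n_rep = as.integer(ra_n_rep),
    ra_genes_per_cluster = as.integer(ra_genes_per_cluster),
    capture_window = as.integer(capture_window),
    capture_partner_range = as.integer(capture_partner_range)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_chrom, "chrom x",
      x$chrom_length, "bp |", x$n_genes, "genes | depth", x$depth, "\n")
  invisible(x)
}
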