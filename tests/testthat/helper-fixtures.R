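# Shared fixtures and independent oracles used across the suite.

# Strip file-level bookkeeping attributes before identity comparisons.
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "n_skipped") <- NULL
  attr(x, "rejections") <- NULL
  x
}

toy_calls <- function() {
  variant_calls(
    chrom = "chr6", pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    ad_ref_p1 = c(5L, 12L, 5L), ad_alt_p1 = c(15L, 8L, 15L),
    ad_ref_p2 = c(20L, 19L, 10L), ad_alt_p2 = c(0L, 1L, 10L),
    mq = c(60, 60, 60), bq = c(37, 37, 37))
}

# Hand-built F2 population (bypasses the simulator) for degenerate cases.
manual_pop <- function(dosage, causal_dosage, positions = NULL, chrom = "chr1") {
  n <- nrow(dosage)
  if (is.null(positions)) positions <- seq_len(ncol(dosage)) * 1000
  cfg <- f2_sim_config(chrom, max(positions) + 1000, n,
                       snp_positions = positions, causal_pos_bp = 1,
                       seed = 1L)
  structure(list(id = sprintf("F2_%04d", seq_len(n)), dosage = dosage,
                 snp_positions = positions, causal_dosage = causal_dosage,
                 phenotype = factor(ifelse(causal_dosage > 0, "prickly",
                                           "prickleless"),
                                    c("prickly", "prickleless")),
                 config = cfg),
            class = "f2_population")
}

# Independent Fisher oracle: direct enumeration of all tables with the
# observed margins, probabilities from factorials (no logs, no shortcuts).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  prob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(c) - lfactorial(d))
  }
  p_obs <- prob(tab[1, 1])
  support <- 0:min(r1, c1)
  sum(vapply(support, function(a) {
    p <- prob(a); if (p <= p_obs * (1 + 1e-7)) p else 0
  }, 1))
}

# Stated world of the fine-mapping experiment: 1109 F2 plants screened at
# two flanking markers 1.37 Mb (~1.67 cM) apart, 10 internal markers,
# causal locus midway between markers M08 and M09.
finemap_world <- function(seed) {
  marker_pos <- round(seq(315000, 1685000, length.out = 12))
  causal <- (marker_pos[8] + marker_pos[9]) / 2
  cfg <- f2_sim_config("chr6", 2e6, 1109L, snp_positions = marker_pos,
                       causal_pos_bp = causal,
                       recomb_rate_cM_per_Mb = 1.67 / 1.37, seed = seed)
  pop <- simulate_f2(cfg)
  list(table = as_marker_table(pop), causal = causal,
       marker_pos = marker_pos)
}

recombinant_subtable <- function(tab, ids) {
  sub <- tab[tab$id %in% ids, , drop = FALSE]
  marker_table(sub, attr(tab, "positions"))
}

# Scaled-down genome scan world: one 10 Mb chromosome, 2000 SNPs, causal
# locus at 7 Mb, bulks of 30 read at depth 40.
scan_world <- function(seed, causal = 7e6, n_snps = 2000L,
                       unlinked = is.null(causal)) {
  cfg <- f2_sim_config("chr6", 10e6, 200L,
                       snp_positions = round(seq(1, 10e6, length.out = n_snps)),
                       causal_pos_bp = causal, causal_unlinked = unlinked,
                       seed = seed)
  pop <- simulate_f2(cfg)
  calls <- simulate_bulk_reads(pop, bulk_read_config(30L, 40L, seed = seed + 1L))
  snp_index(filter_variants(calls))
}
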