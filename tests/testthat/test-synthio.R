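test_that("identical config and seed reproduce identical output", {
  cfg <- f2_sim_config("chr1", 1e6, 50L, snp_positions = c(1e5, 5e5, 9e5),
                       causal_pos_bp = 5e5, seed = 42L)
  p1 <- simulate_f2(cfg); p2 <- simulate_f2(cfg)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$phenotype, p2$phenotype)

  bc <- bulk_read_config(10L, 30L, seed = 7L)
  expect_identical(plain(simulate_bulk_reads(p1, bc)),
                   plain(simulate_bulk_reads(p2, bc)))

  pc <- panel_sim_config(seed = 3L)
  expect_identical(simulate_panel(pc), simulate_panel(pc))
})

test_that("phenotypes segregate 3:1 under dominance", {
  cfg <- f2_sim_config("chr1", 5e6, 4000L, snp_positions = c(1e6, 4e6),
                       causal_pos_bp = 2.5e6, seed = 11L)
  pop <- simulate_f2(cfg)
  frac <- mean(pop$phenotype == "prickly")
  se <- sqrt(0.75 * 0.25 / 4000)
  expect_lt(abs(frac - 0.75), 3 * se)
  # causal genotypes converge to 1:2:1
  expect_gt(stats::chisq.test(table(factor(pop$causal_dosage, 0:2)),
                              p = c(1, 2, 1) / 4)$p.value, 1e-4)
})

test_that("zero recombination gives constant genotype vectors", {
  cfg <- f2_sim_config("chr1", 1e6, 30L,
                       snp_positions = seq(1e5, 9e5, by = 1e5),
                       causal_pos_bp = 5e5, recomb_rate_cM_per_Mb = 0,
                       seed = 5L)
  pop <- simulate_f2(cfg)
  expect_true(all(apply(pop$dosage, 1, function(g) length(unique(g)) == 1L)))
})

test_that("phenotype without a causal locus errors", {
  cfg <- f2_sim_config("chr1", 1e6, 10L, snp_positions = 5e5, seed = 1L)
  expect_error(simulate_f2(cfg), "no causal locus")
  expect_silent(p <- simulate_f2(cfg, phenotype = FALSE))
  expect_null(p$phenotype)
})

test_that("recombinant count between markers 1.67 cM apart matches 2Nr", {
  # Haldane: r = (1 - exp(-2 * 0.0167)) / 2; crossovers per meiosis are
  # Binomial(2N, r) over the two gametes of each plant
  r <- (1 - exp(-2 * 0.0167)) / 2
  world <- finemap_world(202L)
  rec <- find_recombinants(world$table, "M01", "M12")
  expected <- 2 * 1109 * r
  expect_lt(abs(length(rec) - expected), 3 * sqrt(expected * (1 - r)) + 1)
})

test_that("bulk allele frequencies follow conditional genotype expectations", {
  # monomorphic bulk: all plants AA at the SNP -> alt depth 0
  pop <- manual_pop(dosage = matrix(0L, 40, 3),
                    causal_dosage = rep(c(0L, 1L), each = 20))
  calls <- simulate_bulk_reads(pop, bulk_read_config(20L, 20L, seed = 1L))
  expect_true(all(calls$ad_alt_p1 == 0))
  expect_true(all(calls$ad_alt_p2 == 0))

  # causal SNP: prickly F2 are 1/3 BB + 2/3 AB -> bulk B frequency 2/3,
  # prickleless bulk is all AA -> 0
  cfg <- f2_sim_config("chr1", 1e6, 3000L, snp_positions = 5e5,
                       causal_pos_bp = 5e5, seed = 21L)
  pop <- simulate_f2(cfg)
  calls <- simulate_bulk_reads(pop, bulk_read_config(600L, 4000L, seed = 22L))
  idx <- snp_index(calls)
  expect_lt(abs(idx$index_pool1 - 2 / 3), 0.04)
  expect_lt(idx$index_pool2, 0.02)
})

test_that("unlinked SNPs have mean index 1/2 in both bulks", {
  # a very high map rate makes adjacent SNPs mutually unlinked, so the
  # standard error of the mean over SNPs is the iid one
  cfg <- f2_sim_config("chr1", 10e6, 200L,
                       snp_positions = round(seq(1, 10e6, length.out = 1000)),
                       recomb_rate_cM_per_Mb = 5000, causal_unlinked = TRUE,
                       seed = 31L)
  pop <- simulate_f2(cfg)
  calls <- simulate_bulk_reads(pop, bulk_read_config(30L, 40L, seed = 32L))
  rec <- snp_index(filter_variants(calls))
  se <- sd(rec$index_pool1) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$index_pool1) - 0.5), 4 * se)
  expect_lt(abs(mean(rec$index_pool2) - 0.5), 4 * se)
})

test_that("insufficient bulk members error", {
  pop <- manual_pop(matrix(0L, 10, 2), causal_dosage = rep(c(0L, 2L), 5))
  expect_error(simulate_bulk_reads(pop, bulk_read_config(6L, 20L, seed = 1L)),
               "insufficient")
})

test_that("decoy records receive sub-threshold qualities", {
  cfg <- f2_sim_config("chr1", 1e6, 200L,
                       snp_positions = seq(1e4, 99e4, length.out = 400),
                       causal_pos_bp = 5e5, seed = 8L)
  pop <- simulate_f2(cfg)
  calls <- simulate_bulk_reads(
    pop, bulk_read_config(30L, 40L, decoy_fraction = 0.2, seed = 9L))
  n_low <- sum(calls$mq < 20 | calls$bq < 20)
  expect_gt(n_low, 0)
  expect_identical(nrow(filter_variants(calls)), nrow(calls) - n_low)
})

test_that("panel marginals match the configured design", {
  panel <- simulate_panel(panel_sim_config(seed = 14L))
  expect_equal(nrow(panel), 190L)
  expect_equal(sum(panel$phenotype == "prickly" & panel$genotype %in% c("D", "H")), 18L)
  expect_equal(sum(panel$phenotype == "prickleless" & panel$genotype == "R"), 166L)
  expect_equal(sum(panel$phenotype == "prickleless" & panel$genotype == "D"), 6L)
  # no discordance -> perfect association
  perfect <- simulate_panel(panel_sim_config(n_discordant_prickleless_D = 0L,
                                             seed = 15L))
  expect_equal(fisher_exact(carrier_table(perfect)),
               fisher_enum(carrier_table(perfect)), tolerance = 1e-10)
})

test_that("promoter haplotype fixtures match the published 31-mers", {
  fx <- fixture_sequences()
  expect_equal(nchar(fx$prickly), 31L)
  expect_equal(nchar(fx$prickleless), 31L)
  diff_at <- which(strsplit(fx$prickly, "")[[1]] != strsplit(fx$prickleless, "")[[1]])
  expect_identical(diff_at, 16L)
  expect_identical(fx$snp_offset_in_haplotype, 16L)
})

test_that("build_amplicon embeds the haplotype with the SNP at the offset", {
  fx <- fixture_sequences()
  amp <- fx$build_amplicon("prickly", 391L, 153L)
  expect_equal(nchar(amp), 391L)
  expect_identical(substr(amp, 138, 168), fx$prickly)
  # SNP base at the requested offset
  expect_identical(substr(amp, 153, 153), "A")
  ampR <- fx$build_amplicon("prickleless", 391L, 153L)
  expect_identical(substr(ampR, 153, 153), "G")
  # determinism and no stray SspI site in the padding
  expect_identical(amp, fx$build_amplicon("prickly", 391L, 153L))
  expect_identical(gregexpr("AATATT", amp)[[1]][1], 150L)
  expect_identical(gregexpr("AATATT", ampR)[[1]][1], -1L)
  expect_error(fx$build_amplicon("prickly", 31L, 5L), "incompatible")
})
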