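toy_table <- function() {
  df <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    m1 = c("A", "H", "B", "A"),
    m2 = c("A", "A", "H", NA),
    m3 = c("A", "A", "H", "H"),
    phenotype = c("prickleless", "prickleless", "prickly", "prickly"),
    stringsAsFactors = FALSE)
  marker_table(df, positions = c(m1 = 100, m2 = 500, m3 = 900))
}

test_that("marker_table validates codes, phenotypes, and positions", {
  expect_s3_class(toy_table(), "marker_table")
  df <- data.frame(id = "x", m1 = "Z", phenotype = "prickly",
                   stringsAsFactors = FALSE)
  expect_error(marker_table(df, c(m1 = 1)), "genotype codes")
  df$m1 <- "A"; df$phenotype <- "spiky"
  expect_error(marker_table(df, c(m1 = 1)), "phenotype")
  df$phenotype <- "prickly"
  expect_error(marker_table(df, c(m9 = 1)), "marker columns")
})

test_that("segregation_chi2 reproduces textbook Pearson statistics", {
  fit <- segregation_chi2(c(75, 25), c(3, 1))
  expect_equal(fit$chi2, 0)
  expect_equal(fit$p, 1)
  expect_equal(segregation_chi2(c(90, 10), c(3, 1))$chi2, 12.0)
  expect_identical(segregation_chi2(c(90, 10), c(3, 1))$df, 1L)
  expect_equal(segregation_chi2(c(60, 40), c(1, 1))$chi2, 4.0)
  # agrees with stats::chisq.test on a 3-class table
  obs <- c(24, 53, 23)
  expect_equal(segregation_chi2(obs, c(1, 2, 1))$p,
               suppressWarnings(stats::chisq.test(obs, p = c(1, 2, 1) / 4)$p.value))
  expect_error(segregation_chi2(c(1, 2), c(1, 1, 1)), "length")
})

test_that("find_recombinants compares flanking genotypes", {
  tab <- toy_table()
  rec <- find_recombinants(tab, "m1", "m3")
  # (H,A), (B,H), (A,H) differ across the flanks; (A,A) does not
  expect_identical(sort(as.character(rec)), c("r2", "r3", "r4"))
  expect_identical(attr(rec, "n_missing"), 0L)
  # missing genotype excluded and logged
  rec2 <- find_recombinants(tab, "m1", "m2")
  expect_identical(attr(rec2, "n_missing"), 1L)
  expect_false("r4" %in% rec2)
  # symmetric in left/right and invariant to row order
  expect_identical(sort(as.character(find_recombinants(tab, "m3", "m1"))),
                   sort(as.character(rec)))
  shuf <- marker_table(as.data.frame(tab)[c(3, 1, 4, 2), ],
                       attr(tab, "positions"))
  expect_identical(sort(as.character(find_recombinants(shuf, "m1", "m3"))),
                   sort(as.character(rec)))
  expect_error(find_recombinants(tab, "m1", "zz"), "unknown marker")
})

test_that("a single prickleless recombinant (H,A,A) sets the left bound", {
  df <- data.frame(id = "r1", m1 = "H", m2 = "A", m3 = "A",
                   phenotype = "prickleless", stringsAsFactors = FALSE)
  tab <- marker_table(df, c(m1 = 100, m2 = 500, m3 = 900))
  iv <- delimit_interval(tab)
  expect_identical(iv$left_marker, "m1")
  expect_false(iv$left_at_edge)
  expect_identical(iv$right_marker, "m3")
  expect_true(iv$right_at_edge)   # no inconsistent marker on the right
  expect_identical(iv$supporting_recombinants, "r1")
})

test_that("all-consistent recombinants leave the interval at the edges", {
  df <- data.frame(id = c("r1", "r2"), m1 = c("A", "H"), m2 = c("A", "H"),
                   phenotype = c("prickleless", "prickly"),
                   stringsAsFactors = FALSE)
  tab <- marker_table(df, c(m1 = 100, m2 = 900))
  iv <- delimit_interval(tab)
  expect_true(iv$left_at_edge && iv$right_at_edge)
  expect_identical(c(iv$left_marker, iv$right_marker), c("m1", "m2"))
})

test_that("an unlinked trait is reported as such", {
  # prickleless plant that is B everywhere: no marker can host the locus
  df <- data.frame(id = "r1", m1 = "B", m2 = "B",
                   phenotype = "prickleless", stringsAsFactors = FALSE)
  tab <- marker_table(df, c(m1 = 100, m2 = 900))
  expect_error(delimit_interval(tab), "not linked")
})

test_that("two-recombinant support requirement widens the interval", {
  df <- data.frame(id = c("r1", "r2", "r3"),
                   m1 = c("H", "H", "H"), m2 = c("H", "A", "A"),
                   m3 = c("A", "A", "A"),
                   phenotype = "prickleless", stringsAsFactors = FALSE)
  tab <- marker_table(df, c(m1 = 100, m2 = 500, m3 = 900))
  # single-recombinant evidence moves the left bound to m2 (r1)
  expect_identical(delimit_interval(tab)$left_marker, "m2")
  # requiring two independent recombinants falls back to m1 (r2, r3)
  iv2 <- delimit_interval(tab, min_support = 2L)
  expect_identical(iv2$left_marker, "m1")
  expect_identical(sort(iv2$supporting_recombinants), c("r2", "r3"))
})

test_that("fine-mapping recovery brackets the causal locus (fixed seed)", {
  world <- finemap_world(777L)
  rec <- find_recombinants(world$table, "M01", "M12")
  iv <- delimit_interval(recombinant_subtable(world$table, rec))
  expect_lte(iv$left_pos, world$causal)
  expect_gte(iv$right_pos, world$causal)
  # frozen outcome for this seed: the right bound is the marker adjacent
  # to the causal gap; no recombinant fell between M07/M08 and the locus,
  # so the left bound stays one marker out
  expect_identical(c(iv$left_marker, iv$right_marker), c("M07", "M09"))
})

test_that("the interval never excludes the causal position across seeds", {
  ok <- 0L
  for (s in 1:30) {
    world <- finemap_world(1000L + s)
    rec <- find_recombinants(world$table, "M01", "M12")
    if (!length(rec)) { ok <- ok + 1L; next }
    iv <- suppressWarnings(
      delimit_interval(recombinant_subtable(world$table, rec)))
    if (iv$left_pos <= world$causal && iv$right_pos >= world$causal)
      ok <- ok + 1L
  }
  expect_identical(ok, 30L)
})

test_that("interval_width is the anchored marker distance", {
  expect_identical(interval_width(86160000, 87530000), 1370000)
  expect_identical(interval_width(5, 6), 1)
  world <- finemap_world(5L)
  expect_identical(interval_width(world$marker_pos[1], world$marker_pos[2]),
                   world$marker_pos[2] - world$marker_pos[1])
  expect_error(interval_width(10, 10), "must be <")
})

test_that("marker tables round-trip through TSV", {
  tab <- toy_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(tab, f)
  back <- read_marker_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "positions"), attr(tab, "positions"))
  writeLines("id\tm1\tphenotype", f)
  expect_error(read_marker_table(f), "#positions")
})
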