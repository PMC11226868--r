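# Synthetic-data generators: F2 crosses, pooled bulk read counts, germplasm
# panels, and the promoter-haplotype sequence fixtures. Everything is seeded
# and deterministic: identical config + seed => identical output.

# Run `code` under a temporary RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration for simulating an F2 population
#'
#' Describes one chromosome of an F2 cross between an inbred recurrent parent
#' P1 (allele A, recessive phenotype class) and a donor parent P2 (allele B,
#' dominant phenotype class). Crossovers follow an interference-free Haldane
#' model: the number of crossovers per gamete is Poisson with mean equal to
#' the map length in Morgans, and crossover positions are uniform.
#'
#' @param chrom_name Chromosome label used in all emitted tables.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param n_individuals Number of F2 plants to simulate.
#' @param snp_positions Sorted 1-based positions of the SNPs to genotype.
#' @param causal_pos_bp 1-based position of the causal locus, or `NULL` for a
#'   null (no-locus) chromosome.
#' @param causal_unlinked If `TRUE`, the causal locus segregates on another,
#'   unlinked chromosome: phenotypes follow 3:1 but are independent of every
#'   SNP here. Used to generate fully null scan data.
#' @param recomb_rate_cM_per_Mb Recombination rate in centiMorgan per
#'   megabase; `0` disables crossovers.
#' @param seed Integer seed; the generator is byte-reproducible given it.
#' @return An object of class `f2_sim_config`.
#' @export
f2_sim_config <- function(chrom_name = "chr6",
                          chrom_length_bp = 10e6,
                          n_individuals = 200L,
                          snp_positions = integer(),
                          causal_pos_bp = NULL,
                          recomb_rate_cM_per_Mb = 3,
                          causal_unlinked = FALSE,
                          seed = 1L) {
  chrom_length_bp <- as.numeric(chrom_length_bp)
  snp_positions <- as.numeric(snp_positions)
  stopifnot(chrom_length_bp >= 1, n_individuals >= 1,
            recomb_rate_cM_per_Mb >= 0)
  if (length(snp_positions) &&
      (is.unsorted(snp_positions, strictly = TRUE) ||
       min(snp_positions) < 1 || max(snp_positions) > chrom_length_bp))
    stop_bsr("snp_positions must be strictly increasing within [1, %d]",
             chrom_length_bp)
  if (!is.null(causal_pos_bp)) {
    causal_pos_bp <- as.numeric(causal_pos_bp)
    if (causal_pos_bp < 1 || causal_pos_bp > chrom_length_bp)
      stop_bsr("causal_pos_bp outside the chromosome")
  }
  structure(list(chrom_name = chrom_name,
                 chrom_length_bp = chrom_length_bp,
                 n_individuals = as.integer(n_individuals),
                 snp_positions = snp_positions,
                 causal_pos_bp = causal_pos_bp,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 causal_unlinked = isTRUE(causal_unlinked),
                 seed = as.integer(seed)),
            class = "f2_sim_config")
}

# One recombinant gamete: matrix of parental-origin alleles (0 = A, 1 = B)
# at `positions`, for `n` independent gametes. Interference-free: crossover
# count ~ Poisson(map length in Morgans), breakpoints uniform.
sim_gametes <- function(n, positions, chrom_length_bp, rate_cM_per_Mb) {
  morgans <- rate_cM_per_Mb * (chrom_length_bp / 1e6) / 100
  out <- matrix(0L, nrow = n, ncol = length(positions))
  ncx <- stats::rpois(n, morgans)
  start <- stats::rbinom(n, 1L, 0.5)
  for (i in seq_len(n)) {
    if (ncx[i] == 0L) {
      out[i, ] <- start[i]
    } else {
      brk <- sort(stats::runif(ncx[i], 0, chrom_length_bp))
      # allele flips at each breakpoint: parity of breakpoints left of pos
      flips <- findInterval(positions, brk)
      out[i, ] <- bitwXor(start[i], flips %% 2L)
    }
  }
  out
}

#' Simulate an F2 population segregating a single dominant locus
#'
#' Each individual is the union of two independent recombinant gametes. When
#' a causal position is configured, phenotypes follow complete dominance of
#' the P2 (B) allele: genotype AB or BB is scored as the dominant class
#' (`"prickly"`), AA as the recessive class (`"prickleless"`), so the
#' expected phenotype ratio is 3:1.
#'
#' @param config An [f2_sim_config()].
#' @param phenotype Score phenotypes? Requires a causal position.
#' @return An `f2_population`: list with `dosage` (individuals x SNPs matrix
#'   of B-allele counts 0/1/2), `causal_dosage`, `phenotype`, `id`, and the
#'   config. Genotype codes AA/AB/BB correspond to dosage 0/1/2.
#' @export
simulate_f2 <- function(config, phenotype = TRUE) {
  stopifnot(inherits(config, "f2_sim_config"))
  if (phenotype && is.null(config$causal_pos_bp) && !config$causal_unlinked)
    stop_bsr("no causal locus: causal_pos_bp absent but phenotype requested")
  with_seed(config$seed, {
    pos <- c(config$snp_positions, config$causal_pos_bp)
    n <- config$n_individuals
    g1 <- sim_gametes(n, pos, config$chrom_length_bp,
                      config$recomb_rate_cM_per_Mb)
    g2 <- sim_gametes(n, pos, config$chrom_length_bp,
                      config$recomb_rate_cM_per_Mb)
    dose <- g1 + g2
    k <- length(config$snp_positions)
    causal_dosage <- if (!is.null(config$causal_pos_bp)) dose[, k + 1L]
      else if (config$causal_unlinked) stats::rbinom(n, 2L, 0.5)  # 1:2:1
      else NULL
    dose <- dose[, seq_len(k), drop = FALSE]
    colnames(dose) <- if (k) paste0("snp", seq_len(k)) else NULL
    phen <- NULL
    if (phenotype)
      phen <- factor(ifelse(causal_dosage > 0L, "prickly", "prickleless"),
                     levels = c("prickly", "prickleless"))
    structure(list(id = sprintf("F2_%04d", seq_len(n)),
                   dosage = dose,
                   snp_positions = config$snp_positions,
                   causal_dosage = causal_dosage,
                   phenotype = phen,
                   config = config),
              class = "f2_population")
  })
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals, %d SNPs on %s (%.2f Mb)\n",
              length(x$id), ncol(x$dosage), x$config$chrom_name,
              x$config$chrom_length_bp / 1e6))
  if (!is.null(x$phenotype))
    print(table(x$phenotype))
  invisible(x)
}

#' Genotype codes of an F2 population
#'
#' @param pop An `f2_population`.
#' @return Character matrix with entries in `{"AA","AB","BB"}` (A = P1
#'   allele, B = P2 allele).
#' @export
genotype_codes <- function(pop) {
  stopifnot(inherits(pop, "f2_population"))
  m <- matrix(c("AA", "AB", "BB")[pop$dosage + 1L], nrow = nrow(pop$dosage),
              dimnames = dimnames(pop$dosage))
  rownames(m) <- pop$id
  m
}

#' Configuration for pooled bulk read sampling
#'
#' @param n_per_bulk Plants pooled per phenotype bulk (default 30).
#' @param mean_depth Mean sequencing depth per SNP per pool.
#' @param depth_dispersion Negative-binomial dispersion of per-SNP depth
#'   (variance = mu + dispersion * mu^2); `0` gives fixed depth.
#' @param decoy_fraction Fraction of SNPs emitted with sub-threshold mapping
#'   or base quality, to exercise the retention filter. Default 0.
#' @param seed Integer seed.
#' @return An object of class `bulk_read_config`.
#' @export
bulk_read_config <- function(n_per_bulk = 30L, mean_depth = 40L,
                             depth_dispersion = 0, decoy_fraction = 0,
                             seed = 1L) {
  stopifnot(n_per_bulk >= 1, mean_depth >= 1, depth_dispersion >= 0,
            decoy_fraction >= 0, decoy_fraction <= 1)
  structure(list(n_per_bulk = as.integer(n_per_bulk),
                 mean_depth = as.integer(mean_depth),
                 depth_dispersion = depth_dispersion,
                 decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "bulk_read_config")
}

#' Simulate pooled sequencing of two phenotype bulks
#'
#' Draws `n_per_bulk` plants of each phenotype without replacement and pools
#' them with equal weight. At each SNP the true bulk alternate-allele
#' frequency is the mean B-allele dosage over the pooled plants divided by
#' two; observed alternate depth is Binomial(d, p) with per-SNP depth d from
#' the configured depth law. Pool 1 is the dominant-phenotype (prickly)
#' bulk, pool 2 the recessive bulk. Reference allele = P1 (A) allele.
#'
#' @param pop An `f2_population` with phenotypes.
#' @param config A [bulk_read_config()].
#' @return A `variant_calls` data frame (see [variant_calls()]).
#' @export
simulate_bulk_reads <- function(pop, config) {
  stopifnot(inherits(pop, "f2_population"), inherits(config, "bulk_read_config"))
  if (is.null(pop$phenotype))
    stop_bsr("population has no phenotypes")
  n1 <- sum(pop$phenotype == "prickly")
  n2 <- sum(pop$phenotype == "prickleless")
  if (n1 < config$n_per_bulk || n2 < config$n_per_bulk)
    stop_bsr("insufficient individuals for bulks: %d prickly, %d prickleless, need %d each",
             n1, n2, config$n_per_bulk)
  with_seed(config$seed, {
    pick1 <- sample(which(pop$phenotype == "prickly"), config$n_per_bulk)
    pick2 <- sample(which(pop$phenotype == "prickleless"), config$n_per_bulk)
    p1 <- colMeans(pop$dosage[pick1, , drop = FALSE]) / 2
    p2 <- colMeans(pop$dosage[pick2, , drop = FALSE]) / 2
    k <- length(p1)
    draw_depth <- function() {
      if (config$depth_dispersion == 0) rep(config$mean_depth, k)
      else stats::rnbinom(k, mu = config$mean_depth,
                          size = 1 / config$depth_dispersion)
    }
    d1 <- draw_depth(); d2 <- draw_depth()
    a1 <- stats::rbinom(k, d1, p1)
    a2 <- stats::rbinom(k, d2, p2)
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    mq <- rep(60, k); bq <- rep(37, k)
    if (config$decoy_fraction > 0) {
      bad <- which(stats::runif(k) < config$decoy_fraction)
      which_field <- stats::runif(length(bad))
      mq[bad[which_field < 0.5]] <- stats::runif(sum(which_field < 0.5), 0, 19.5)
      bq[bad[which_field >= 0.5]] <- stats::runif(sum(which_field >= 0.5), 0, 19.5)
    }
    variant_calls(chrom = pop$config$chrom_name,
                  pos = pop$snp_positions,
                  ref = ref, alt = unname(alt),
                  ad_ref_p1 = d1 - a1, ad_alt_p1 = a1,
                  ad_ref_p2 = d2 - a2, ad_alt_p2 = a2,
                  mq = mq, bq = bq)
  })
}

#' Configuration for a germplasm association panel
#'
#' Defaults emulate a 190-accession collection with 18 prickly and 172
#' prickleless accessions, 6 of the prickleless ones carrying the
#' dominant-parent (D) marker genotype discordantly.
#'
#' @param n_prickly,n_prickleless Accessions per phenotype class.
#' @param n_discordant_prickleless_D Prickleless accessions scored D.
#' @param seed Integer seed.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_prickly = 18L, n_prickleless = 172L,
                             n_discordant_prickleless_D = 6L, seed = 1L) {
  stopifnot(n_prickly >= 0, n_prickleless >= 0,
            n_discordant_prickleless_D >= 0,
            n_discordant_prickleless_D <= n_prickleless)
  structure(list(n_prickly = as.integer(n_prickly),
                 n_prickleless = as.integer(n_prickleless),
                 n_discordant_prickleless_D = as.integer(n_discordant_prickleless_D),
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate a genotyped germplasm panel
#'
#' Genotype codes: D = homozygous like the dominant (prickly) parent, H =
#' heterozygous, R = homozygous like the recessive (prickleless) parent.
#' Prickly accessions draw D or H with equal probability; prickleless
#' accessions are R apart from the configured number of discordant D.
#'
#' @param config A [panel_sim_config()].
#' @return Data frame with columns `accession`, `phenotype`, `genotype`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  with_seed(config$seed, {
    g_prickly <- sample(c("D", "H"), config$n_prickly, replace = TRUE)
    g_pless <- c(rep("D", config$n_discordant_prickleless_D),
                 rep("R", config$n_prickleless - config$n_discordant_prickleless_D))
    df <- data.frame(
      accession = sprintf("ACC_%03d",
                          seq_len(config$n_prickly + config$n_prickleless)),
      phenotype = c(rep("prickly", config$n_prickly),
                    rep("prickleless", config$n_prickleless)),
      genotype = c(g_prickly, g_pless),
      stringsAsFactors = FALSE)
    df <- df[sample(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Promoter haplotype fixtures around the marker SNP
#'
#' The two 31-bp promoter haplotypes flanking the causal-candidate SNP
#' (15 bp each side). The dominant-allele (prickly) haplotype carries an
#' SspI recognition site (AATATT) created by the SNP; the recessive
#' haplotype does not. The returned `build_amplicon` closure embeds either
#' haplotype into a deterministic padded amplicon of requested length with
#' the SNP at a requested 1-based offset, guaranteeing that no additional
#' SspI site is introduced by the padding.
#'
#' @return List with `prickly`, `prickleless` (character sequences),
#'   `snp_offset_in_haplotype` (16), and `build_amplicon(allele, length,
#'   snp_offset)`.
#' @export
fixture_sequences <- function() {
  hap <- c(prickly     = "GAGTTTTTTTTCAATATTTAAAATAGTTGAA",
           prickleless = "GAGTTTTTTTTCAATGTTTAAAATAGTTGAA")
  build_amplicon <- function(allele = c("prickly", "prickleless"),
                             length, snp_offset) {
    allele <- match.arg(allele)
    h <- hap[[allele]]
    nh <- nchar(h)
    start <- snp_offset - 15L              # 1-based start of the haplotype
    if (start < 1L || start + nh - 1L > length)
      stop_bsr("snp_offset %d incompatible with amplicon length %d",
               snp_offset, length)
    with_seed(20240510L, {
      pad <- function(n) {
        if (n == 0L) return("")
        repeat {
          s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = "")
          if (!grepl("AATATT", s)) return(s)
        }
      }
      expected <- if (allele == "prickly") start + 12L else integer(0)
      repeat {
        amp <- paste0(pad(start - 1L), h, pad(length - (start - 1L) - nh))
        # padding must not create an SspI site across a junction
        hits <- gregexpr("AATATT", amp)[[1]]
        sites <- as.integer(hits[hits > 0])
        if (identical(sites, as.integer(expected))) break
      }
      amp
    })
  }
  list(prickly = unname(hap["prickly"]),
       prickleless = unname(hap["prickleless"]),
       snp_offset_in_haplotype = 16L,
       build_amplicon = build_amplicon)
}

#' Convert an F2 population to a fine-mapping marker table
#'
#' @param pop An `f2_population` with phenotypes.
#' @param marker_names Optional marker names (default `M01`, `M02`, ...).
#' @return A `marker_table`: data frame of genotype codes `{A,H,B}` per
#'   marker plus `phenotype`, with marker positions in
#'   `attr(x, "positions")`.
#' @export
as_marker_table <- function(pop, marker_names = NULL) {
  stopifnot(inherits(pop, "f2_population"))
  if (is.null(pop$phenotype)) stop_bsr("population has no phenotypes")
  k <- ncol(pop$dosage)
  if (is.null(marker_names)) marker_names <- sprintf("M%02d", seq_len(k))
  stopifnot(length(marker_names) == k)
  g <- matrix(c("A", "H", "B")[pop$dosage + 1L], nrow = nrow(pop$dosage))
  df <- as.data.frame(g, stringsAsFactors = FALSE)
  names(df) <- marker_names
  df <- cbind(data.frame(id = pop$id, stringsAsFactors = FALSE), df,
              data.frame(phenotype = as.character(pop$phenotype),
                         stringsAsFactors = FALSE))
  marker_table(df, positions = stats::setNames(pop$snp_positions, marker_names))
}
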