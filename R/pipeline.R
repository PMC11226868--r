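# Pipeline orchestration: a validated run configuration, per-stage seed
# fan-out, stable on-disk artifacts, and a small command-line front end
# (see inst/cli/bsrmap).

KNOWN_STAGES <- c("simulate-f2", "simulate-panel", "bsa", "caps", "finemap",
                  "associate")

stage_defaults <- function() list(
  `simulate-f2` = list(chrom_name = "chr6", chrom_length_bp = 10e6,
                       n_individuals = 200L, n_snps = 2000L,
                       causal_pos_bp = 7e6, recomb_rate_cM_per_Mb = 3,
                       n_per_bulk = 30L, mean_depth = 40L,
                       depth_dispersion = 0, decoy_fraction = 0),
  `simulate-panel` = list(n_prickly = 18L, n_prickleless = 172L,
                          n_discordant_prickleless_D = 6L),
  bsa = list(window_size_bp = 400000L, step_bp = 200000L,
             ci_replicates = 10000L, n_per_bulk = 30L,
             min_depth = 20L, min_mq = 20, min_bq = 20),
  caps = list(amplicon_length = 391L, snp_offset = 153L),
  finemap = list(left = NULL, right = NULL),
  associate = list())

#' Validate a pipeline run configuration
#'
#' @param config Named list (or path to a JSON file) with elements `stages`
#'   (subset of `simulate-f2`, `simulate-panel`, `bsa`, `caps`, `finemap`,
#'   `associate`), `seed`, `out_dir`, optional `log_level`, and one optional
#'   sub-list per stage overriding its defaults. Unknown keys are rejected.
#' @return The completed configuration, class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  known_top <- c("stages", "seed", "out_dir", "log_level", KNOWN_STAGES)
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop_bsr("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !all(config$stages %in% KNOWN_STAGES))
    stop_bsr("config$stages must be a subset of: %s",
             paste(KNOWN_STAGES, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "."
  config$log_level <- config$log_level %||% "info"
  defaults <- stage_defaults()
  for (st in KNOWN_STAGES) {
    given <- config[[st]] %||% list()
    unknown <- setdiff(names(given), names(defaults[[st]]))
    if (length(unknown))
      stop_bsr("unknown key(s) in config$`%s`: %s", st,
               paste(unknown, collapse = ", "))
    config[[st]] <- utils::modifyList(defaults[[st]], given)
  }
  # cross-field validation happens before any work
  bsa_config(config$bsa$window_size_bp, config$bsa$step_bp,
             config$bsa$ci_replicates, config$bsa$n_per_bulk, 1L)
  structure(config, class = "run_config")
}

pipe_log <- function(config, stage, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the configured pipeline stages
#'
#' Stages run in the order simulate -> filter/scan -> regions (or the
#' marker / association paths), each seeded from the global seed by a fixed
#' derivation so any stage can be re-run alone. Every run writes
#' `provenance.json` (config, seed, package version) next to its outputs.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  path <- function(f) file.path(config$out_dir, f)

  jsonlite::write_json(
    list(config = unclass(config), seed = config$seed,
         package = "bsrmap",
         version = as.character(utils::packageVersion("bsrmap"))),
    path("provenance.json"), auto_unbox = TRUE, pretty = TRUE, null = "null")
  out$provenance <- path("provenance.json")

  for (st in config$stages) {
    seed <- derive_seed(config$seed, st)
    p <- config[[st]]
    if (st == "simulate-f2") {
      snp_pos <- round(seq(1, p$chrom_length_bp, length.out = p$n_snps))
      cfg <- f2_sim_config(p$chrom_name, p$chrom_length_bp, p$n_individuals,
                           snp_positions = snp_pos,
                           causal_pos_bp = p$causal_pos_bp,
                           recomb_rate_cM_per_Mb = p$recomb_rate_cM_per_Mb,
                           seed = seed)
      pop <- simulate_f2(cfg)
      calls <- simulate_bulk_reads(
        pop, bulk_read_config(p$n_per_bulk, p$mean_depth, p$depth_dispersion,
                              p$decoy_fraction, seed = seed + 1L))
      write_variants(calls, path("variants.tsv"), "tsv")
      write_variants(calls, path("variants.vcf"), "vcf")
      out$variants_tsv <- path("variants.tsv")
      out$variants_vcf <- path("variants.vcf")
      # marker table on a thinned grid, for the fine-mapping path
      keep <- unique(round(seq(1, length(snp_pos),
                               length.out = min(12L, length(snp_pos)))))
      sub <- pop
      sub$dosage <- pop$dosage[, keep, drop = FALSE]
      sub$snp_positions <- pop$snp_positions[keep]
      write_marker_table(as_marker_table(sub), path("markers.tsv"))
      out$markers <- path("markers.tsv")
      pipe_log(config, st, "%d individuals, %d SNPs written", length(pop$id),
               nrow(calls))
    } else if (st == "simulate-panel") {
      panel <- simulate_panel(panel_sim_config(
        p$n_prickly, p$n_prickleless, p$n_discordant_prickleless_D,
        seed = seed))
      utils::write.table(panel, path("panel.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$panel <- path("panel.tsv")
      pipe_log(config, st, "%d accessions written", nrow(panel))
    } else if (st == "bsa") {
      if (!file.exists(path("variants.tsv")))
        stop_bsr("stage bsa: missing upstream file %s", path("variants.tsv"))
      calls <- read_variants(path("variants.tsv"), "tsv")
      filtered <- filter_variants(calls, p$min_depth, p$min_mq, p$min_bq)
      pipe_log(config, st, "%d/%d SNPs retained by filters", nrow(filtered),
               nrow(calls))
      records <- snp_index(filtered)
      cfg <- bsa_config(p$window_size_bp, p$step_bp, p$ci_replicates,
                        p$n_per_bulk, seed = seed)
      grid <- sort(unique(c(20L, 40L, 80L,
                            as.integer(stats::median(records$depth_pool1)))))
      ci <- null_ci(cfg, grid)
      wins <- sliding_windows(records, ci, cfg)
      regions <- call_regions(wins)
      b <- ci_bounds_for(records, ci)
      utils::write.table(cbind(records, b), path("snp_index.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(wins, path("windows.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_regions_bed(regions, path("regions.bed"))
      out$snp_index <- path("snp_index.tsv")
      out$windows <- path("windows.tsv")
      out$regions <- path("regions.bed")
      pipe_log(config, st, "%d windows, %d significant region(s)", nrow(wins),
               nrow(regions))
    } else if (st == "caps") {
      fx <- fixture_sequences()
      amp_D <- fx$build_amplicon("prickly", p$amplicon_length, p$snp_offset)
      amp_R <- fx$build_amplicon("prickleless", p$amplicon_length, p$snp_offset)
      assays <- design_caps(amp_D, amp_R, load_enzymes())
      write_fasta(c(allele_D = amp_D, allele_R = amp_R),
                  path("amplicons.fasta"))
      jsonlite::write_json(
        lapply(assays, function(a) list(
          enzyme = a$enzyme$name, recognition = a$enzyme$recognition,
          bands_D = a$bands_D, bands_R = a$bands_R, bands_H = a$bands_H)),
        path("caps_assays.json"), auto_unbox = TRUE, pretty = TRUE)
      out$amplicons <- path("amplicons.fasta")
      out$caps <- path("caps_assays.json")
      pipe_log(config, st, "%d assay(s) designed", length(assays))
    } else if (st == "finemap") {
      if (!file.exists(path("markers.tsv")))
        stop_bsr("stage finemap: missing upstream file %s", path("markers.tsv"))
      tab <- read_marker_table(path("markers.tsv"))
      pos <- marker_positions(tab)
      left <- p$left %||% names(pos)[1]
      right <- p$right %||% names(pos)[length(pos)]
      rec <- find_recombinants(tab, left, right)
      sub <- tab[tab$id %in% rec, , drop = FALSE]
      attr(sub, "positions") <- pos
      class(sub) <- c("marker_table", "data.frame")
      iv <- delimit_interval(sub)
      jsonlite::write_json(
        list(n_recombinants = length(rec), left_marker = iv$left_marker,
             right_marker = iv$right_marker, left_pos = iv$left_pos,
             right_pos = iv$right_pos,
             width_bp = interval_width(iv$left_pos, iv$right_pos),
             supporting_recombinants = iv$supporting_recombinants),
        path("interval.json"), auto_unbox = TRUE, pretty = TRUE)
      out$interval <- path("interval.json")
      pipe_log(config, st, "%d recombinants; interval %s..%s", length(rec),
               iv$left_marker, iv$right_marker)
    } else if (st == "associate") {
      if (!file.exists(path("panel.tsv")))
        stop_bsr("stage associate: missing upstream file %s", path("panel.tsv"))
      panel <- utils::read.delim(path("panel.tsv"), stringsAsFactors = FALSE)
      freq <- genotype_frequencies(panel)
      tab <- carrier_table(panel)
      p_val <- fisher_exact(tab)
      jsonlite::write_json(
        list(counts = freq,
             carrier_table = list(prickly = unname(tab[1, ]),
                                  prickleless = unname(tab[2, ])),
             fisher_p = p_val),
        path("association.json"), auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
      out$association <- path("association.json")
      pipe_log(config, st, "Fisher exact P = %.3g", p_val)
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Parses `bsrmap <stage...> --config <json> --seed <int> --out <dir>
#' [--log-level quiet|info]` and calls [run_pipeline()]. Used by the
#' `inst/cli/bsrmap` script.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, 0 on success.
#' @export
bsrmap_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  take <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1] == length(args)) stop_bsr("missing value for %s", flag)
    val <- args[i[1] + 1L]
    args <<- args[-(i[1] + 0:1)]
    val
  }
  config_path <- take("--config")
  seed <- take("--seed")
  out_dir <- take("--out", ".")
  log_level <- take("--log-level", "info")
  stages <- args[!startsWith(args, "--")]
  config <- if (!is.null(config_path))
    jsonlite::read_json(config_path, simplifyVector = TRUE) else list()
  if (length(stages)) config$stages <- stages
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config$out_dir <- out_dir
  config$log_level <- log_level
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
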