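# Variant table I/O and the SNP retention filter.
#
# The on-disk formats are a flat TSV (columns chrom, pos, ref, alt,
# ad_ref_p1, ad_alt_p1, ad_ref_p2, ad_alt_p2, mq, bq) and a two-sample VCF
# dialect with AD/DP per pool, MQ and BQ as INFO tags. VCF parsing is
# delegated to VariantAnnotation.

TSV_COLS <- c("chrom", "pos", "ref", "alt", "ad_ref_p1", "ad_alt_p1",
              "ad_ref_p2", "ad_alt_p2", "mq", "bq")

#' Construct a per-SNP variant table with two-pool allele depths
#'
#' @param chrom Chromosome labels (recycled).
#' @param pos 1-based positions.
#' @param ref,alt Single-base alleles, distinct per record.
#' @param ad_ref_p1,ad_alt_p1 Reference / alternate read depth in pool 1
#'   (dominant-phenotype bulk).
#' @param ad_ref_p2,ad_alt_p2 Same for pool 2 (recessive bulk).
#' @param mq,bq Mapping and base quality of the site.
#' @return A `variant_calls` data frame sorted by (chrom, pos).
#' @export
variant_calls <- function(chrom, pos, ref, alt,
                          ad_ref_p1, ad_alt_p1, ad_ref_p2, ad_alt_p2,
                          mq = 60, bq = 37) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   ref = toupper(ref), alt = toupper(alt),
                   ad_ref_p1 = as.integer(ad_ref_p1),
                   ad_alt_p1 = as.integer(ad_alt_p1),
                   ad_ref_p2 = as.integer(ad_ref_p2),
                   ad_alt_p2 = as.integer(ad_alt_p2),
                   mq = as.numeric(mq), bq = as.numeric(bq),
                   stringsAsFactors = FALSE)
  bad <- !(df$ref %in% c("A", "C", "G", "T")) |
    !(df$alt %in% c("A", "C", "G", "T")) | df$ref == df$alt
  if (any(bad))
    stop_bsr("invalid alleles at row %d (%s>%s)", which(bad)[1],
             df$ref[which(bad)[1]], df$alt[which(bad)[1]])
  if (any(df$ad_ref_p1 < 0 | df$ad_alt_p1 < 0 | df$ad_ref_p2 < 0 |
          df$ad_alt_p2 < 0))
    stop_bsr("negative allele depth")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Read a variant table
#'
#' Multi-allelic and non-SNP (indel) records are skipped; the skip count is
#' attached as `attr(x, "n_skipped")` and reported via message.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return A `variant_calls` data frame in (chrom, pos) order.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop_bsr("no such file: %s", path)
  switch(format, tsv = read_variants_tsv(path), vcf = read_variants_vcf(path))
}

read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TSV_COLS, names(df))
  if (length(missing_cols))
    stop_bsr("TSV is missing columns: %s", paste(missing_cols, collapse = ", "))
  snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L & !grepl(",", df$alt)
  n_skipped <- sum(!snp)
  if (n_skipped) message(sprintf("read_variants: skipped %d non-SNP record(s)",
                                 n_skipped))
  out <- do.call(variant_calls, as.list(df[snp, TSV_COLS]))
  attr(out, "n_skipped") <- n_skipped
  out
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_bsr("VariantAnnotation is required to read VCF")
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  if (ncol(vcf) != 2L)
    stop_bsr("expected exactly two pool samples, found %d", ncol(vcf))
  geno <- VariantAnnotation::geno(vcf)
  if (!all(c("AD", "DP") %in% names(geno)))
    stop_bsr("VCF is missing AD/DP FORMAT fields")
  info <- VariantAnnotation::info(vcf)
  if (!all(c("MQ", "BQ") %in% names(info)))
    stop_bsr("VCF is missing MQ/BQ INFO fields")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  snp <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped) message(sprintf("read_variants: skipped %d non-SNP record(s)",
                                 n_skipped))
  ad <- geno$AD
  get_ad <- function(sample_i, allele_i)
    vapply(ad[snp, sample_i], function(v) as.integer(v[allele_i]), 1L)
  out <- variant_calls(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[snp],
    pos = BiocGenerics::start(rr)[snp],
    ref = ref[snp], alt = alt1[snp],
    ad_ref_p1 = get_ad(1L, 1L), ad_alt_p1 = get_ad(1L, 2L),
    ad_ref_p2 = get_ad(2L, 1L), ad_alt_p2 = get_ad(2L, 2L),
    mq = as.numeric(info$MQ)[snp], bq = as.numeric(info$BQ)[snp])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a variant table
#'
#' @param calls A `variant_calls` data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(calls, "variant_calls"))
  if (format == "tsv") {
    utils::write.table(as.data.frame(calls)[TSV_COLS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=bsrmap",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
      "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Base quality\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "pool1", "pool2"), collapse = "\t")), con)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%g;BQ=%g\tAD:DP\t%d,%d:%d\t%d,%d:%d",
                    calls$chrom, calls$pos, calls$ref, calls$alt,
                    calls$mq, calls$bq,
                    calls$ad_ref_p1, calls$ad_alt_p1,
                    calls$ad_ref_p1 + calls$ad_alt_p1,
                    calls$ad_ref_p2, calls$ad_alt_p2,
                    calls$ad_ref_p2 + calls$ad_alt_p2)
    writeLines(body, con)
  }
  invisible(path)
}

#' Apply the SNP retention filter
#'
#' A record is retained when the total depth of EACH pool, the mapping
#' quality, and the base quality are all at or above their thresholds
#' (inclusive). Per-criterion rejection tallies are attached as
#' `attr(x, "rejections")`; a record failing several criteria is counted in
#' each tally.
#'
#' @param calls A `variant_calls` data frame.
#' @param min_depth,min_mq,min_bq Inclusive thresholds (defaults 20/20/20).
#' @return Filtered `variant_calls`, input order preserved.
#' @export
filter_variants <- function(calls, min_depth = 20L, min_mq = 20, min_bq = 20) {
  stopifnot(inherits(calls, "variant_calls"))
  d1 <- calls$ad_ref_p1 + calls$ad_alt_p1
  d2 <- calls$ad_ref_p2 + calls$ad_alt_p2
  fail_depth <- d1 < min_depth | d2 < min_depth
  fail_mq <- calls$mq < min_mq
  fail_bq <- calls$bq < min_bq
  keep <- !(fail_depth | fail_mq | fail_bq)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  attr(out, "rejections") <- c(depth = sum(fail_depth), mq = sum(fail_mq),
                               bq = sum(fail_bq), removed = sum(!keep))
  out
}
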