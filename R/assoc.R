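# Genotype-phenotype association on germplasm panels: genotype frequency
# summaries, the dominance-collapsed 2x2 carrier table, and an exact
# hypergeometric (Fisher) test evaluated in log-space so that extreme
# P-values (~1e-20) are computed accurately.

check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("accession", "phenotype", "genotype") %in% names(panel)))
  if (nrow(panel) == 0L) stop_bsr("empty panel")
  bad <- !panel$genotype %in% c("D", "H", "R")
  if (any(bad))
    stop_bsr("unknown genotype code '%s' for accession %s",
             panel$genotype[which(bad)[1]], panel$accession[which(bad)[1]])
  bad <- !panel$phenotype %in% c("prickly", "prickleless")
  if (any(bad))
    stop_bsr("unknown phenotype '%s' for accession %s",
             panel$phenotype[which(bad)[1]], panel$accession[which(bad)[1]])
  invisible(panel)
}

#' Genotype frequencies per phenotype class
#'
#' @param panel Data frame with `accession`, `phenotype`
#'   (prickly/prickleless), `genotype` (D/H/R).
#' @return Data frame with one row per phenotype x genotype: `count` and
#'   `percent` (share within the phenotype class, rounded half-up to two
#'   decimals).
#' @export
genotype_frequencies <- function(panel) {
  check_panel(panel)
  counts <- table(factor(panel$phenotype, c("prickly", "prickleless")),
                  factor(panel$genotype, c("D", "H", "R")))
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(df) <- c("phenotype", "genotype", "count")
  totals <- rowSums(counts)[df$phenotype]
  df$percent <- ifelse(totals > 0,
                       round_half_up(100 * df$count / totals, 2), NA_real_)
  df
}

#' Collapse a panel to the 2x2 carrier contingency table
#'
#' Rows: phenotype (prickly, prickleless); columns: carrier of the dominant
#' allele (genotype D or H) vs non-carrier (R). The dominant grouping
#' mirrors the trait's inheritance: one dose of the D allele suffices.
#'
#' @inheritParams genotype_frequencies
#' @return 2x2 integer matrix of class `carrier_table`.
#' @export
carrier_table <- function(panel) {
  check_panel(panel)
  carrier <- factor(ifelse(panel$genotype %in% c("D", "H"),
                           "carrier", "non-carrier"),
                    c("carrier", "non-carrier"))
  tab <- table(factor(panel$phenotype, c("prickly", "prickleless")), carrier)
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  class(m) <- c("carrier_table", class(m))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided P-value uses
#' the point-probability rule: it sums the probabilities of all tables with
#' the observed margins whose point probability does not exceed the
#' observed one (with a `1 + 1e-7` relative guard against floating-point
#' ties). All arithmetic is in log-space.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param sided `"two"` (default) or `"one"` (one-sided in the direction of
#'   the observed deviation, i.e. the smaller of the two tail sums; always
#'   at most the two-sided value).
#' @return The P-value.
#' @export
fisher_exact <- function(tab, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tab <- unclass(tab)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop_bsr("all-zero table")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  lp_obs <- logp[support == a_obs]
  if (sided == "one") {
    p <- exp(min(logsumexp(logp[support >= a_obs]),
                 logsumexp(logp[support <= a_obs])))
  } else {
    p <- exp(logsumexp(logp[logp <= lp_obs + log1p(1e-7)]))
  }
  min(p, 1)
}
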