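# Fine mapping on F2 marker tables: segregation tests, recombinant
# screening between flanking markers, and dominance-aware delimitation of
# the candidate interval.

#' Construct a marker genotype table
#'
#' @param df Data frame with an `id` column, one column per marker with
#'   genotype codes in `{A, H, B}` (`NA` = missing; A = homozygous P1,
#'   B = homozygous P2, H = heterozygous), and a `phenotype` column with
#'   values `"prickly"` / `"prickleless"`.
#' @param positions Named numeric vector of 1-based physical marker
#'   positions, strictly increasing, names matching the marker columns.
#' @return A `marker_table` data frame with positions attached.
#' @export
marker_table <- function(df, positions) {
  stopifnot(is.data.frame(df), all(c("id", "phenotype") %in% names(df)))
  markers <- names(positions)
  if (is.null(markers) || !all(markers %in% names(df)))
    stop_bsr("positions must be named after marker columns present in df")
  if (is.unsorted(positions, strictly = TRUE))
    stop_bsr("marker positions must be strictly increasing")
  codes <- unlist(df[markers], use.names = FALSE)
  if (!all(codes %in% c("A", "H", "B") | is.na(codes)))
    stop_bsr("genotype codes must be A, H, B, or NA")
  if (!all(df$phenotype %in% c("prickly", "prickleless")))
    stop_bsr("phenotype must be 'prickly' or 'prickleless'")
  attr(df, "positions") <- positions
  class(df) <- c("marker_table", "data.frame")
  df
}

marker_positions <- function(table) attr(table, "positions")

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Pearson statistic against expected class proportions (e.g. 3:1 for an F2
#' dominant trait, 1:1 for a backcross).
#'
#' @param observed Observed class counts.
#' @param expected_ratio Expected ratio terms (positive, same length).
#' @return List with `chi2`, `df`, `p`.
#' @export
segregation_chi2 <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio))
    stop_bsr("observed and expected_ratio differ in length")
  stopifnot(all(observed >= 0), sum(observed) > 0, all(expected_ratio > 0))
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Identify recombinants between two flanking markers
#'
#' An individual is recombinant when its non-missing genotype codes at the
#' two markers differ (a crossover lies between them). Individuals missing
#' either genotype are excluded; their count is attached as
#' `attr(x, "n_missing")`.
#'
#' @param table A [marker_table()].
#' @param left,right Marker names.
#' @return Character vector of recombinant individual ids.
#' @export
find_recombinants <- function(table, left, right) {
  stopifnot(inherits(table, "marker_table"))
  for (m in c(left, right))
    if (!m %in% names(marker_positions(table)))
      stop_bsr("unknown marker: %s", m)
  gl <- table[[left]]; gr <- table[[right]]
  ok <- !is.na(gl) & !is.na(gr)
  ids <- table$id[ok & gl != gr]
  attr(ids, "n_missing") <- sum(!ok)
  ids
}

# Trait-inferred causal genotype class under a dominant B allele:
# prickleless => must be A; prickly => must be H or B.
trait_consistent <- function(genotype, phenotype) {
  ifelse(is.na(genotype), NA,
         ifelse(phenotype == "prickleless", genotype == "A",
                genotype %in% c("H", "B")))
}

#' Delimit the candidate interval from recombinant genotypes
#'
#' Under a dominant trait allele (B), every recombinant's genotype at the
#' causal locus is fixed by its phenotype: prickleless plants must be A,
#' prickly plants H or B. A marker mismatching that class in some
#' recombinant cannot host the locus; with error-free single-crossover
#' data each recombinant's mismatching markers form a prefix or a suffix
#' of the marker order, and the interval is bounded by the innermost
#' mismatching marker on each side (or the table edge when a side has
#' none).
#'
#' @param table A [marker_table()] restricted to recombinants.
#' @param trait_model Only `"dominant_B"` is implemented.
#' @param min_support Number of independent recombinants required to move a
#'   bound inward (default 1, i.e. a single recombinant suffices).
#' @return List of class `interval_call`: `left_marker`, `right_marker`,
#'   `left_pos`, `right_pos`, `left_at_edge`, `right_at_edge`, and
#'   `supporting_recombinants` (ids that set each bound).
#' @export
delimit_interval <- function(table, trait_model = "dominant_B",
                             min_support = 1L) {
  stopifnot(inherits(table, "marker_table"))
  trait_model <- match.arg(trait_model, "dominant_B")
  pos <- marker_positions(table)
  markers <- names(pos)
  if (nrow(table) < 1L) stop_bsr("need at least one recombinant")
  if (length(markers) < 2L) stop_bsr("need at least two markers")

  cons <- sapply(markers, function(m)
    trait_consistent(table[[m]], table$phenotype))
  cons <- matrix(cons, nrow = nrow(table), dimnames = list(table$id, markers))

  k <- length(markers)
  left_edges <- integer(0); left_ids <- character(0)
  right_edges <- integer(0); right_ids <- character(0)
  for (i in seq_len(nrow(table))) {
    row <- cons[i, ]
    mm <- which(!row); ok <- which(row)
    if (!length(mm)) next
    if (!length(ok)) stop_bsr("trait not linked to this region")
    pre <- mm[mm < min(ok)]
    suf <- mm[mm > max(ok)]
    interior <- setdiff(mm, c(pre, suf))
    if (length(interior))
      warning(sprintf("recombinant %s mismatches interior marker(s) %s; ignored",
                      table$id[i], paste(markers[interior], collapse = ",")),
              call. = FALSE)
    if (length(pre)) {
      left_edges <- c(left_edges, max(pre)); left_ids <- c(left_ids, table$id[i])
    }
    if (length(suf)) {
      right_edges <- c(right_edges, min(suf)); right_ids <- c(right_ids, table$id[i])
    }
  }
  pick_bound <- function(edges, ids, inner_rank) {
    # move the bound inward only while >= min_support recombinants back it
    if (!length(edges)) return(list(idx = NA_integer_, ids = character(0)))
    ord <- order(inner_rank(edges))
    edges <- edges[ord]; ids <- ids[ord]
    counts <- stats::ave(edges, edges, FUN = length)
    keep <- counts >= min_support
    if (!any(keep)) return(list(idx = NA_integer_, ids = character(0)))
    bound <- edges[keep][1]
    list(idx = bound, ids = unique(ids[edges == bound]))
  }
  lb <- pick_bound(left_edges, left_ids, function(e) -e)   # innermost = max
  rb <- pick_bound(right_edges, right_ids, function(e) e)  # innermost = min
  li <- if (is.na(lb$idx)) 1L else lb$idx
  ri <- if (is.na(rb$idx)) k else rb$idx
  if (li >= ri) stop_bsr("trait not linked to this region")
  structure(list(left_marker = markers[li], right_marker = markers[ri],
                 left_pos = unname(pos[li]), right_pos = unname(pos[ri]),
                 left_at_edge = is.na(lb$idx), right_at_edge = is.na(rb$idx),
                 supporting_recombinants = unique(c(lb$ids, rb$ids))),
            class = "interval_call")
}

#' @export
print.interval_call <- function(x, ...) {
  cat(sprintf("candidate interval: %s (%s) .. %s (%s), width %d bp\n",
              x$left_marker, format(x$left_pos, big.mark = ","),
              x$right_marker, format(x$right_pos, big.mark = ","),
              interval_width(x$left_pos, x$right_pos)))
  if (length(x$supporting_recombinants))
    cat("supporting recombinants:",
        paste(x$supporting_recombinants, collapse = ", "), "\n")
  invisible(x)
}

#' Physical width between two marker anchor coordinates
#'
#' @param left_pos,right_pos 1-based positions, `left_pos < right_pos`.
#' @return `right_pos - left_pos` in bp.
#' @export
interval_width <- function(left_pos, right_pos) {
  if (left_pos >= right_pos) stop_bsr("left_pos must be < right_pos")
  right_pos - left_pos
}

#' Read / write marker tables
#'
#' TSV layout: header `id`, marker columns, `phenotype`; a required comment
#' line `#positions: m1=pos1,m2=pos2,...` carries the physical positions.
#'
#' @param path File path.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#positions:"))
    stop_bsr("marker table must start with a '#positions:' line")
  kv <- strsplit(trimws(sub("^#positions:", "", header)), ",")[[1]]
  parts <- strsplit(kv, "=")
  positions <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                               vapply(parts, `[`, "", 1L))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  marker_table(df, positions)
}

#' @rdname read_marker_table
#' @param table A [marker_table()].
#' @export
write_marker_table <- function(table, path) {
  stopifnot(inherits(table, "marker_table"))
  pos <- marker_positions(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#positions: %s",
                     paste(sprintf("%s=%d", names(pos), as.integer(pos)),
                           collapse = ",")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
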