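# Delta(SNP-index) bulked-segregant scan.
#
# SNP-index = alt depth / total depth per pool; delta = pool1 - pool2 with
# pool1 the dominant-phenotype bulk. Significance envelopes come from a
# Monte-Carlo simulation of the no-locus null: two bulks of n F2 plants
# drawn at an unlinked locus (genotype probabilities 1/4 : 1/2 : 1/4),
# binomial read sampling at the observed depth.

#' Scan configuration
#'
#' @param window_size_bp Sliding window width (default 400 kb).
#' @param step_bp Window step (default 200 kb); must not exceed the width.
#' @param ci_replicates Monte-Carlo replicates for the null envelope
#'   (default 10000).
#' @param n_per_bulk Plants per bulk assumed by the null (default 30).
#' @param seed Integer seed for the null simulation.
#' @return An object of class `bsa_config`.
#' @export
bsa_config <- function(window_size_bp = 400000L, step_bp = 200000L,
                       ci_replicates = 10000L, n_per_bulk = 30L, seed = 1L) {
  stopifnot(window_size_bp > 0, step_bp > 0, ci_replicates > 0, n_per_bulk > 0)
  if (step_bp > window_size_bp)
    stop_bsr("step_bp (%d) must be <= window_size_bp (%d)", step_bp,
             window_size_bp)
  structure(list(window_size_bp = as.integer(window_size_bp),
                 step_bp = as.integer(step_bp),
                 ci_replicates = as.integer(ci_replicates),
                 n_per_bulk = as.integer(n_per_bulk),
                 seed = as.integer(seed)),
            class = "bsa_config")
}

#' Per-SNP index and delta(SNP-index)
#'
#' @param calls Filtered `variant_calls`; every pool depth must be positive.
#' @return Data frame of class `snp_index_records` with `index_pool1`,
#'   `index_pool2`, `delta`, and per-pool depths.
#' @export
snp_index <- function(calls) {
  stopifnot(inherits(calls, "variant_calls"))
  d1 <- calls$ad_ref_p1 + calls$ad_alt_p1
  d2 <- calls$ad_ref_p2 + calls$ad_alt_p2
  zero <- d1 == 0L | d2 == 0L
  if (any(zero))
    stop_bsr("zero depth in a pool at %s:%d (run filter_variants first)",
             calls$chrom[which(zero)[1]], calls$pos[which(zero)[1]])
  out <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    index_pool1 = calls$ad_alt_p1 / d1,
                    index_pool2 = calls$ad_alt_p2 / d2,
                    depth_pool1 = d1, depth_pool2 = d2,
                    stringsAsFactors = FALSE)
  out$delta <- out$index_pool1 - out$index_pool2
  class(out) <- c("snp_index_records", "data.frame")
  out
}

# One batch of null delta draws at depth d: both bulks are independent
# samples of n unlinked F2 genotypes; p = mean B dosage / 2; reads binomial.
null_delta_draws <- function(n_rep, depth, n_per_bulk) {
  draw_index <- function() {
    dose <- stats::rbinom(n_rep * n_per_bulk, 2L, 0.5)  # 1/4 : 1/2 : 1/4
    p <- colMeans(matrix(dose, nrow = n_per_bulk)) / 2
    stats::rbinom(n_rep, depth, p) / depth
  }
  draw_index() - draw_index()
}

#' Monte-Carlo null confidence envelope for delta(SNP-index)
#'
#' Simulates the "no quantitative trait locus" null at each depth of a grid
#' and records the empirical 95% and 99% two-sided bounds of delta.
#'
#' @param config A [bsa_config()].
#' @param depth_grid Depths at which to tabulate bounds.
#' @return Data frame of class `null_ci_table` with columns `depth`, `lo95`,
#'   `hi95`, `lo99`, `hi99`.
#' @export
null_ci <- function(config, depth_grid = c(20L, 30L, 40L, 60L, 80L, 120L)) {
  stopifnot(inherits(config, "bsa_config"), length(depth_grid) > 0,
            all(depth_grid > 0))
  depth_grid <- sort(unique(as.integer(depth_grid)))
  with_seed(config$seed, {
    rows <- lapply(depth_grid, function(d) {
      delta <- null_delta_draws(config$ci_replicates, d, config$n_per_bulk)
      # inverse-ECDF quantiles: bounds are actual draw values, so that with
      # the discrete delta distribution (atoms at 1/depth) the exceedance
      # probability brackets the nominal level:
      # P(delta > hi) <= alpha/2 <= P(delta >= hi)
      q <- stats::quantile(delta, c(0.025, 0.975, 0.005, 0.995),
                           names = FALSE, type = 1)
      data.frame(depth = d, lo95 = q[1], hi95 = q[2], lo99 = q[3], hi99 = q[4])
    })
    out <- do.call(rbind, rows)
    out$n_replicates <- config$ci_replicates
    out$n_per_bulk <- config$n_per_bulk
    class(out) <- c("null_ci_table", "data.frame")
    out
  })
}

# Nearest-grid-depth lookup keyed on the harmonic mean of the pool depths
# (the depth whose binomial noise best matches the pair).
ci_bounds_for <- function(records, ci) {
  h <- 2 / (1 / records$depth_pool1 + 1 / records$depth_pool2)
  idx <- vapply(h, function(x) which.min(abs(ci$depth - x)), 1L)
  ci[idx, c("lo95", "hi95", "lo99", "hi99"), drop = FALSE]
}

#' Sliding-window averaging of delta(SNP-index) and its null bounds
#'
#' Windows tile each chromosome from position 0 at `step_bp` spacing and are
#' half-open: a SNP at 1-based position p falls in window `[start, start +
#' window)` when `start <= p - 1 < start + window`. Windows without SNPs are
#' omitted.
#'
#' @param records `snp_index_records`, sorted by (chrom, pos).
#' @param ci A `null_ci_table`.
#' @param config A [bsa_config()].
#' @return Data frame of class `window_stats` with per-window SNP counts,
#'   mean delta, and mean null bounds.
#' @export
sliding_windows <- function(records, ci, config) {
  stopifnot(inherits(records, "snp_index_records"),
            inherits(ci, "null_ci_table"), inherits(config, "bsa_config"))
  b <- ci_bounds_for(records, ci)
  w <- config$window_size_bp; s <- config$step_bp
  per_chrom <- lapply(split(seq_len(nrow(records)), records$chrom), function(ii) {
    pos0 <- records$pos[ii] - 1L        # 0-based
    first_win <- pmax(0, ceiling((pos0 - w + 1) / s))
    last_win <- floor(pos0 / s)
    n_wins <- last_win - first_win + 1L
    win_id <- unlist(mapply(seq.int, first_win, last_win, SIMPLIFY = FALSE))
    snp_id <- rep(ii, n_wins)
    agg <- lapply(split(snp_id, win_id), function(members) {
      data.frame(chrom = records$chrom[members[1]],
                 n_snps = length(members),
                 mean_delta = mean(records$delta[members]),
                 mean_lo95 = mean(b$lo95[members]),
                 mean_hi95 = mean(b$hi95[members]),
                 mean_lo99 = mean(b$lo99[members]),
                 mean_hi99 = mean(b$hi99[members]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out$start <- as.numeric(names(agg)) * s
    out$end <- out$start + w
    out[order(out$start), c("chrom", "start", "end", "n_snps", "mean_delta",
                            "mean_lo95", "mean_hi95", "mean_lo99", "mean_hi99")]
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Call significant regions from window statistics
#'
#' A window is significant at a level when its mean delta falls strictly
#' outside the averaged null bounds for that level. Overlapping or abutting
#' significant windows merge into one region spanning `[min start, max
#' end)`; `peak_delta` is the window mean of largest magnitude inside.
#'
#' @param windows A `window_stats` data frame.
#' @param levels Significance levels to call (default both).
#' @return Data frame of class `significant_regions` with `chrom`, `start`,
#'   `end`, `level` (`"p05"` or `"p01"`), `peak_delta`.
#' @export
call_regions <- function(windows, levels = c("p05", "p01")) {
  stopifnot(inherits(windows, "window_stats"))
  out <- list()
  for (lev in levels) {
    lo <- if (lev == "p05") windows$mean_lo95 else windows$mean_lo99
    hi <- if (lev == "p05") windows$mean_hi95 else windows$mean_hi99
    sig <- windows$mean_delta > hi | windows$mean_delta < lo
    for (ch in unique(windows$chrom)) {
      ii <- which(windows$chrom == ch & sig)
      if (!length(ii)) next
      ii <- ii[order(windows$start[ii])]
      cur_start <- windows$start[ii[1]]; cur_end <- windows$end[ii[1]]
      cur_peak <- windows$mean_delta[ii[1]]
      flush <- function() {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch, start = cur_start, end = cur_end, level = lev,
          peak_delta = cur_peak, stringsAsFactors = FALSE)
      }
      for (j in ii[-1]) {
        if (windows$start[j] <= cur_end) {
          cur_end <- max(cur_end, windows$end[j])
          if (abs(windows$mean_delta[j]) > abs(cur_peak))
            cur_peak <- windows$mean_delta[j]
        } else {
          flush()
          cur_start <- windows$start[j]; cur_end <- windows$end[j]
          cur_peak <- windows$mean_delta[j]
        }
      }
      flush()
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               level = character(), peak_delta = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("significant_regions", "data.frame")
  out
}

#' Write significant regions as BED (0-based half-open)
#'
#' @param regions A `significant_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(inherits(regions, "significant_regions"))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end),
                   regions$level, regions$peak_delta)
  writeLines(lines, path)
  invisible(path)
}

#' Plot a delta(SNP-index) scan with its null envelopes
#'
#' @param windows A `window_stats` data frame (one chromosome).
#' @param ... Passed to [plot()].
#' @return Invisibly, `windows`.
#' @export
plot_scan <- function(windows, ...) {
  stopifnot(inherits(windows, "window_stats"))
  mid <- (windows$start + windows$end) / 2 / 1e6
  plot(mid, windows$mean_delta, type = "l", ylim = c(-1, 1),
       xlab = "position (Mb)", ylab = expression(Delta * "(SNP-index)"), ...)
  graphics::lines(mid, windows$mean_hi95, col = "darkgreen", lty = 2)
  graphics::lines(mid, windows$mean_lo95, col = "darkgreen", lty = 2)
  graphics::lines(mid, windows$mean_hi99, col = "red", lty = 2)
  graphics::lines(mid, windows$mean_lo99, col = "red", lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(windows)
}
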