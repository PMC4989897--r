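# Binned mean-signal metaprofiles around region centers and per-region
# coverage summaries. Coverage is bedGraph-style: non-overlapping segments
# per chromosome; uncovered bases count as signal 0 but still contribute to
# bp-weighted denominators.

# Internal: sum of value * overlap-width of coverage over a set of query
# intervals, by chromosome. Returns one weighted sum per query row.
.coverage_sums <- function(queries, coverage) {
  out <- numeric(nrow(queries))
  if (nrow(coverage) == 0L || nrow(queries) == 0L) return(out)
  pairs <- .overlap_pairs(queries, coverage)
  if (!nrow(pairs)) return(out)
  ov <- pmin(queries$end[pairs[, 1L]], coverage$end[pairs[, 2L]]) -
    pmax(queries$start[pairs[, 1L]], coverage$start[pairs[, 2L]])
  sums <- rowsum(ov * coverage$value[pairs[, 2L]], group = pairs[, 1L])
  out[as.integer(rownames(sums))] <- sums[, 1L]
  out
}

#' Binned metaprofile of coverage around region centers
#'
#' For each region, takes the window `[center - flank, center + flank)`
#' with `center = floor((start + end) / 2)`, splits it into `n_bins` equal
#' bins, computes the bp-weighted mean coverage per bin, then averages
#' across regions. Windows clipped at chromosome start contribute only
#' their defined bases; bins with no defined base in any region are 0.
#'
#' @param regions Interval data frame (non-empty).
#' @param coverage bedGraph-style data frame (`chrom`, `start`, `end`,
#'   `value`), non-overlapping within chromosome.
#' @param flank Half-window in bp (default 5000).
#' @param n_bins Number of bins (default 200); `2 * flank` must be a
#'   multiple of `n_bins`.
#' @return List with `flank`, `n_bins`, `bin_width`, `offsets` (bin-center
#'   offset from region center, bp), `bin_values` (mean signal per bin) and
#'   `n_regions`.
#' @export
metaprofile <- function(regions, coverage, flank = 5000, n_bins = 200) {
  validate_intervals(regions, "region")
  if (nrow(regions) == 0L) stop("empty region list")
  stopifnot(flank > 0, n_bins > 0)
  if ((2 * flank) %% n_bins != 0)
    stop("2*flank must be a multiple of n_bins")
  w <- (2 * flank) / n_bins
  n_r <- nrow(regions)
  center <- floor((regions$start + regions$end) / 2)
  # one row per (region, bin)
  bin_idx <- rep(seq_len(n_bins), times = n_r)
  reg_idx <- rep(seq_len(n_r), each = n_bins)
  b_start <- center[reg_idx] - flank + (bin_idx - 1) * w
  b_end <- b_start + w
  defined <- pmax(0, b_end - pmax(b_start, 0))
  keep <- defined > 0
  sums <- numeric(n_r * n_bins)
  if (any(keep)) {
    q <- data.frame(chrom = regions$chrom[reg_idx[keep]],
                    start = pmax(b_start[keep], 0), end = b_end[keep],
                    stringsAsFactors = FALSE)
    sums[keep] <- .coverage_sums(q, coverage)
  }
  bin_mean <- ifelse(defined > 0, sums / defined, NA_real_)
  m <- matrix(bin_mean, nrow = n_bins, ncol = n_r)
  vals <- rowMeans(m, na.rm = TRUE)
  vals[is.nan(vals)] <- 0
  list(flank = flank, n_bins = n_bins, bin_width = w,
       offsets = -flank + (seq_len(n_bins) - 0.5) * w,
       bin_values = vals, n_regions = n_r)
}

#' Write a metaprofile as TSV
#' @param profile Result of [metaprofile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metaprofile <- function(profile, path) {
  utils::write.table(
    data.frame(bin_index = seq_len(profile$n_bins),
               offset_bp = profile$offsets,
               mean_signal = profile$bin_values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean coverage over each region's own span
#'
#' bp-weighted mean signal per region (no flank): the coverage mass inside
#' the region divided by the region width; uncovered bases count as 0.
#'
#' @inheritParams metaprofile
#' @return Numeric vector, one mean per region row.
#' @export
region_signal <- function(regions, coverage) {
  validate_intervals(regions, "region")
  if (nrow(regions) == 0L) return(numeric(0))
  .coverage_sums(regions, coverage) / (regions$end - regions$start)
}

#' Paired signal-loss test between conditions
#'
#' Computes per-region mean coverage in each condition, forms deltas
#' `tumor - normal` and applies the paired Wilcoxon signed-rank test
#' ([signed_rank_test()]): zero deltas dropped, exact enumeration for small
#' n, tie-corrected normal approximation otherwise. The one-sided p tests
#' for signal loss (deltas below zero), as expected at hypermethylated
#' enhancer CGIs in tumors.
#'
#' @param regions Interval data frame (>= 2 rows).
#' @param coverage_normal,coverage_tumor bedGraph-style data frames.
#' @return List with `deltas`, `statistic`, `p_value` (one-sided, loss),
#'   `p_two_sided`, `n_used` and `degenerate` (TRUE when all deltas are 0).
#' @export
signal_loss_test <- function(regions, coverage_normal, coverage_tumor) {
  if (nrow(regions) < 2L) stop("need at least 2 regions")
  deltas <- region_signal(regions, coverage_tumor) -
    region_signal(regions, coverage_normal)
  res <- signed_rank_test(deltas)
  list(deltas = deltas, statistic = res$statistic, p_value = res$p_less,
       p_two_sided = res$p_two_sided, n_used = res$n_used,
       degenerate = res$degenerate)
}
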