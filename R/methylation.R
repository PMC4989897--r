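# Differential DNA methylation: per-CpG beta differences between paired
# conditions, region-level aggregation, hypermethylated-region selection at
# the strict thresholds (> 0.5 cell-line, > 0.1 clinical), class contrasts
# and target-gene silencing.

#' Per-CpG differential methylation
#'
#' Matches the two beta tables by (chrom, position) and computes
#' `dm = beta_tumor - beta_normal` for every CpG present with a non-missing
#' beta in both conditions. Unmatched or NA sites are dropped and counted.
#'
#' @param sites_normal,sites_tumor Data frames with `chrom`, `position`,
#'   `beta` ([read_beta_table()]); betas must lie in \[0, 1\].
#' @return Data frame with `chrom`, `position`, `beta_normal`,
#'   `beta_tumor`, `dm`, plus attribute `n_dropped`.
#' @export
differential_methylation <- function(sites_normal, sites_tumor) {
  for (tbl in list(sites_normal, sites_tumor)) {
    bad <- which(!is.na(tbl$beta) & (tbl$beta < 0 | tbl$beta > 1))
    if (length(bad))
      stop("beta outside [0,1] at ", tbl$chrom[bad[1L]], ":",
           tbl$position[bad[1L]])
  }
  key_n <- paste(sites_normal$chrom, sites_normal$position)
  key_t <- paste(sites_tumor$chrom, sites_tumor$position)
  idx <- match(key_n, key_t)
  ok <- !is.na(idx) & !is.na(sites_normal$beta) & !is.na(sites_tumor$beta[idx])
  out <- data.frame(
    chrom = sites_normal$chrom[ok],
    position = sites_normal$position[ok],
    beta_normal = sites_normal$beta[ok],
    beta_tumor = sites_tumor$beta[idx[ok]],
    stringsAsFactors = FALSE
  )
  out$dm <- out$beta_tumor - out$beta_normal
  dropped <- (nrow(sites_normal) - sum(ok)) + (nrow(sites_tumor) - sum(ok))
  attr(out, "n_dropped") <- dropped
  message(dropped, " unmatched or missing-beta CpG record(s) dropped")
  out
}

#' Region-level mean differential methylation
#'
#' Per region, the mean `dm` over contained CpGs (a CpG at `position` is
#' inside `[start, end)`). Regions containing no CpG are excluded and
#' counted.
#'
#' @param sites Data frame from [differential_methylation()].
#' @param regions Interval data frame (region ids from `name`).
#' @return Data frame with `region_id`, `n_cpgs`, `mean_dm`, plus
#'   attribute `n_excluded` (regions without CpGs).
#' @export
aggregate_region_dm <- function(sites, regions) {
  ids <- .region_ids(regions)
  if (nrow(regions) == 0L)
    return(structure(data.frame(region_id = character(0), n_cpgs = integer(0),
                                mean_dm = numeric(0)), n_excluded = 0L))
  cpg_iv <- data.frame(chrom = sites$chrom, start = sites$position,
                       end = sites$position + 1, stringsAsFactors = FALSE)
  pairs <- .overlap_pairs(cpg_iv, regions)
  if (!nrow(pairs)) {
    message(nrow(regions), " region(s) without CpGs excluded")
    return(structure(data.frame(region_id = character(0), n_cpgs = integer(0),
                                mean_dm = numeric(0)),
                     n_excluded = nrow(regions)))
  }
  grp <- pairs[, 2L]
  n_cpg <- rowsum(rep(1L, length(grp)), grp)
  dm_sum <- rowsum(sites$dm[pairs[, 1L]], grp)
  ridx <- as.integer(rownames(n_cpg))
  out <- data.frame(region_id = ids[ridx], n_cpgs = as.integer(n_cpg[, 1L]),
                    mean_dm = dm_sum[, 1L] / n_cpg[, 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$region_id, ids)), , drop = FALSE]
  rownames(out) <- NULL
  n_excl <- nrow(regions) - nrow(out)
  if (n_excl > 0) message(n_excl, " region(s) without CpGs excluded")
  structure(out, n_excluded = n_excl)
}

#' Select hypermethylated regions
#'
#' Regions whose mean differential methylation strictly exceeds the
#' threshold (`mean_dm > threshold`): 0.5 for cell-line contrasts, 0.1 for
#' clinical (group-mean) contrasts. With `mode = "any_cpg"` a region
#' qualifies if any contained CpG exceeds the threshold; that mode requires
#' per-site input via the `sites`/`regions` arguments of [dm_matrix()] and
#' is exposed here through the `max_dm` column when present.
#'
#' @param region_dm Data frame from [aggregate_region_dm()].
#' @param threshold Strictly positive dm threshold in (0, 1].
#' @param mode `"mean"` (default) or `"any_cpg"` (uses column `max_dm` if
#'   present, else falls back to `mean_dm`).
#' @return Subset of `region_dm` with an added logical `hyper` column (all
#'   TRUE in the returned subset).
#' @export
select_hypermethylated <- function(region_dm, threshold = 0.5,
                                   mode = c("mean", "any_cpg")) {
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  crit <- if (mode == "any_cpg" && "max_dm" %in% names(region_dm))
    region_dm$max_dm else region_dm$mean_dm
  out <- region_dm[crit > threshold, , drop = FALSE]
  out$hyper <- TRUE
  rownames(out) <- NULL
  out
}

#' Contrast region-level dm between two CGI classes
#'
#' Two-sample rank test (shared with [compare_link_strength()]) on mean dm
#' values, e.g. eCGIs vs pCGIs, reporting class medians.
#'
#' @param ecgi_dm,pcgi_dm Data frames from [aggregate_region_dm()] (or
#'   numeric dm vectors), both non-empty.
#' @return List with `statistic`, `p_greater` (one-sided, first class more
#'   hypermethylated), `p_two_sided`, `median_a`, `median_b`, `exact`.
#' @export
class_dm_contrast <- function(ecgi_dm, pcgi_dm) {
  pick <- function(x) if (is.data.frame(x)) x$mean_dm else as.numeric(x)
  a <- pick(ecgi_dm); b <- pick(pcgi_dm)
  if (!length(a) || !length(b)) stop("both classes must be non-empty")
  res <- rank_sum_test(a, b)
  list(statistic = res$statistic, p_greater = res$p_greater,
       p_two_sided = res$p_two_sided, median_a = stats::median(a),
       median_b = stats::median(b), exact = res$exact)
}

#' Silencing of hypermethylated-region target genes
#'
#' For the target genes of hypermethylated regions, computes expression
#' fold changes `(tumor + pc) / (normal + pc)` and tests for
#' down-regulation: a one-sample signed-rank test that log fold changes lie
#' below 0, plus (when non-hyper regions have targets of their own) a
#' two-sample rank contrast of log folds between hyper-region targets and
#' targets exclusive to non-hyper regions.
#'
#' @param hyper_ids Character vector of hypermethylated region ids.
#' @param assignments Data frame with `region_id`, `gene_id` (ChIA evidence
#'   via [assign_targets()], or nearest-gene fallback via
#'   [nearest_gene()]).
#' @param expr_normal,expr_tumor Named RPKM vectors.
#' @param pseudocount Fold-change pseudocount (default 0.1).
#' @return List with `fold_changes` (named, hyper-region targets),
#'   `median_fold`, `p_down` (one-sided signed-rank, log-folds < 0),
#'   `contrast` (two-sample result vs non-hyper targets, or NULL).
#' @export
target_silencing <- function(hyper_ids, assignments, expr_normal, expr_tumor,
                             pseudocount = 0.1) {
  hyper_targets <- unique(assignments$gene_id[assignments$region_id %in% hyper_ids])
  if (!length(hyper_targets)) stop("no targets for hypermethylated regions")
  folds <- expression_fold_change(hyper_targets, expr_tumor, expr_normal,
                                  pseudocount)
  if (!length(folds)) stop("no targets with expression in both conditions")
  res <- signed_rank_test(log(folds))
  other_targets <- setdiff(
    unique(assignments$gene_id[!(assignments$region_id %in% hyper_ids)]),
    hyper_targets)
  contrast <- NULL
  if (length(other_targets)) {
    other_folds <- expression_fold_change(other_targets, expr_tumor,
                                          expr_normal, pseudocount)
    if (length(other_folds)) {
      rs <- rank_sum_test(log(folds), log(other_folds))
      contrast <- list(statistic = rs$statistic, p_less = rs$p_less,
                       p_two_sided = rs$p_two_sided,
                       median_other_fold = stats::median(other_folds))
    }
  }
  list(fold_changes = folds, median_fold = stats::median(folds),
       p_down = res$p_less, p_two_sided = res$p_two_sided,
       contrast = contrast)
}

#' Matrix of differentially methylated CpGs within regions
#'
#' Long-format table of per-CpG dm values for CpGs with `|dm| > threshold`
#' located inside the given regions — the substrate for heatmaps of
#' aberrant methylation. `threshold = 0` keeps every in-region CpG.
#'
#' @param sites Data frame from [differential_methylation()].
#' @param regions Interval data frame.
#' @param threshold Absolute dm threshold (default 0.5).
#' @return Data frame with `region_id`, `chrom`, `position`, `dm` (possibly
#'   zero rows).
#' @export
dm_matrix <- function(sites, regions, threshold = 0.5) {
  ids <- .region_ids(regions)
  empty <- data.frame(region_id = character(0), chrom = character(0),
                      position = numeric(0), dm = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(sites) == 0L) return(empty)
  keep <- abs(sites$dm) > threshold
  s <- sites[keep, , drop = FALSE]
  if (!nrow(s)) return(empty)
  cpg_iv <- data.frame(chrom = s$chrom, start = s$position,
                       end = s$position + 1, stringsAsFactors = FALSE)
  pairs <- .overlap_pairs(cpg_iv, regions)
  if (!nrow(pairs)) return(empty)
  out <- data.frame(region_id = ids[pairs[, 2L]],
                    chrom = s$chrom[pairs[, 1L]],
                    position = s$position[pairs[, 1L]],
                    dm = s$dm[pairs[, 1L]], stringsAsFactors = FALSE)
  out[order(out$region_id, out$chrom, out$position), , drop = FALSE]
}
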