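# ChIA-PET link filtering and enhancer-to-gene target assignment. Links are
# undirected two-anchor interactions with a tag count; only links with tag
# count >= 3 are considered significant (the upstream filter used for Pol2
# ChIA-PET interactomes).

#' Filter chromatin-interaction links by tag count
#'
#' @param links Link data frame ([make_links()]).
#' @param min_tags Minimum tag count retained (default 3).
#' @return Subset of `links` with `tag_count >= min_tags`, order preserved.
#' @export
filter_links <- function(links, min_tags = 3) {
  stopifnot(min_tags >= 1)
  out <- links[links$tag_count >= min_tags, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: region ids (name column or positional fallback).
.region_ids <- function(regions, prefix = "region") {
  ids <- if ("name" %in% names(regions)) regions$name else
    rep(".", nrow(regions))
  anon <- ids == "." | is.na(ids)
  ids[anon] <- paste0(prefix, "_", which(anon))
  ids
}

#' Assign target genes to regions via chromatin interactions
#'
#' A region targets a gene iff some link has one anchor overlapping the
#' region and the other anchor overlapping the gene's promoter window
#' (TSS +/- `flank`). Anchors are interchangeable (links are undirected).
#' One assignment per (region, gene) pair; the supporting links' tag counts
#' are aggregated by `agg` (default max).
#'
#' @param regions Interval data frame (region ids from `name`).
#' @param links Filtered link data frame.
#' @param genes Gene table.
#' @param flank Promoter half-width in bp (default 1000).
#' @param agg Tag-count aggregation over supporting links: `"max"` or
#'   `"sum"`.
#' @return Data frame with columns `region_id`, `gene_id`, `tag_count`,
#'   `evidence` (`"chia"`).
#' @export
assign_targets <- function(regions, links, genes, flank = 1000,
                           agg = c("max", "sum")) {
  agg <- match.arg(agg)
  ids <- .region_ids(regions)
  empty <- data.frame(region_id = character(0), gene_id = character(0),
                      tag_count = numeric(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(links) == 0L || nrow(genes) == 0L)
    return(empty)
  prom <- promoter_window(genes, flank)
  a1 <- data.frame(chrom = links$chrom1, start = links$start1,
                   end = links$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = links$chrom2, start = links$start2,
                   end = links$end2, stringsAsFactors = FALSE)
  hits <- list()
  for (dir in 1:2) {
    r_anchor <- if (dir == 1) a1 else a2
    g_anchor <- if (dir == 1) a2 else a1
    pr <- .overlap_pairs(r_anchor, regions)        # (link, region)
    pg <- .overlap_pairs(g_anchor, prom)           # (link, gene)
    if (!nrow(pr) || !nrow(pg)) next
    r_by_link <- split(pr[, 2L], pr[, 1L])
    g_by_link <- split(pg[, 2L], pg[, 1L])
    shared <- intersect(names(r_by_link), names(g_by_link))
    for (l in shared) {
      li <- as.integer(l)
      combo <- expand.grid(region = r_by_link[[l]], gene = g_by_link[[l]])
      hits[[length(hits) + 1L]] <- data.frame(
        region = combo$region, gene = combo$gene,
        tag = links$tag_count[li], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  all_hits <- do.call(rbind, hits)
  key <- paste(all_hits$region, all_hits$gene, sep = "\r")
  f <- if (agg == "max") max else sum
  tag <- tapply(all_hits$tag, key, f)
  parts <- strsplit(names(tag), "\r", fixed = TRUE)
  ridx <- as.integer(vapply(parts, `[`, "", 1L))
  gidx <- as.integer(vapply(parts, `[`, "", 2L))
  out <- data.frame(region_id = ids[ridx], gene_id = genes$gene_id[gidx],
                    tag_count = as.numeric(tag), evidence = "chia",
                    stringsAsFactors = FALSE)
  out <- out[order(out$region_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single- vs multi-target proportions
#'
#' Among regions with at least one assigned target, the proportion
#' targeting exactly one gene (single) and two or more genes (multiple).
#'
#' @param assignments Data frame from [assign_targets()].
#' @return List with `fraction_single`, `fraction_multiple`, `n_regions`.
#' @export
target_multiplicity <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no assigned regions")
  counts <- table(assignments$region_id)
  list(fraction_single = mean(counts == 1),
       fraction_multiple = mean(counts >= 2),
       n_regions = length(counts))
}

#' Compare interaction strength between two region classes
#'
#' Two-sample rank test on per-pair tag counts (e.g. eCGI-promoter pairs
#' vs typical-enhancer-promoter pairs). The samples are unpaired, so the
#' rank-sum (Mann-Whitney) form is the primary method; a paired
#' signed-rank variant is available when the pairs are genuinely matched
#' one-to-one.
#'
#' @param strengths_a,strengths_b Numeric vectors of per-pair tag counts.
#' @param paired Use the signed-rank test on `strengths_a - strengths_b`
#'   (requires equal lengths; default FALSE).
#' @return List with `statistic`, `p_greater` (one-sided, A stronger),
#'   `p_two_sided`, `exact`.
#' @export
compare_link_strength <- function(strengths_a, strengths_b, paired = FALSE) {
  if (!length(strengths_a) || !length(strengths_b))
    stop("both samples must be non-empty")
  if (paired) {
    stopifnot(length(strengths_a) == length(strengths_b))
    res <- signed_rank_test(strengths_a - strengths_b)
    return(list(statistic = res$statistic, p_greater = res$p_greater,
                p_two_sided = res$p_two_sided, exact = res$exact))
  }
  res <- rank_sum_test(strengths_a, strengths_b)
  list(statistic = res$statistic, p_greater = res$p_greater,
       p_two_sided = res$p_two_sided, exact = res$exact)
}

#' Expression fold change of target genes between conditions
#'
#' `fold = (RPKM_a + pseudocount) / (RPKM_b + pseudocount)` per distinct
#' target gene. Genes missing from either table are excluded with a
#' warning.
#'
#' @param assignments Data frame from [assign_targets()] (or any data frame
#'   with a `gene_id` column), or a character vector of gene ids.
#' @param expr_a,expr_b Named numeric RPKM vectors keyed by gene id.
#' @param pseudocount Added to both numerator and denominator (default 0.1).
#' @return Named numeric vector of fold changes (a over b) per gene.
#' @export
expression_fold_change <- function(assignments, expr_a, expr_b,
                                   pseudocount = 0.1) {
  genes <- if (is.data.frame(assignments)) unique(assignments$gene_id)
  else unique(as.character(assignments))
  if (any(expr_a < 0, na.rm = TRUE) || any(expr_b < 0, na.rm = TRUE))
    stop("negative RPKM")
  present <- genes[genes %in% names(expr_a) & genes %in% names(expr_b)]
  missing <- setdiff(genes, present)
  if (length(missing))
    warning(length(missing), " gene(s) missing from an expression table, ",
            "excluded: ", paste(utils::head(missing, 5), collapse = ", "))
  (expr_a[present] + pseudocount) / (expr_b[present] + pseudocount)
}
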