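# Enrichment machinery: length- and chromosome-matched random segments, the
# random-segment permutation test for transcription-regulator targeting,
# and Fisher's exact test for tumor-suppressor / oncogene categories.

#' Draw random DNA segments matched to a template set
#'
#' One segment per template region: same chromosome, same length, start
#' uniform over the chromosome, redrawn while overlapping `excluded` (up to
#' 10^4 rejections per segment, then an error naming the segment).
#' Deterministic given `seed`; with `seed = NULL` the current RNG stream is
#' used (as inside [permutation_enrichment()]).
#'
#' @param template_regions Interval data frame.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param excluded Optional interval data frame to avoid.
#' @param seed Optional integer seed.
#' @param length_matched Keep each segment's length equal to its template's
#'   (default TRUE). If FALSE, only the segment count is matched: lengths
#'   are resampled with replacement from the template length distribution.
#' @return Interval data frame of segments, names `seg_1`, `seg_2`, ...
#' @export
random_segments <- function(template_regions, chrom_sizes, excluded = NULL,
                            seed = NULL, length_matched = TRUE) {
  validate_intervals(template_regions, "template")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(template_regions)
  lens <- template_regions$end - template_regions$start
  if (!length_matched && n > 0) lens <- sample(lens, n, replace = TRUE)
  chroms <- template_regions$chrom
  if (!all(chroms %in% names(chrom_sizes)))
    stop("chrom_sizes missing chromosome: ",
         setdiff(chroms, names(chrom_sizes))[1L])
  sizes <- chrom_sizes[chroms]
  if (any(lens >= sizes))
    stop("template longer than its chromosome at segment ",
         which(lens >= sizes)[1L])
  draw <- function(idx) floor(stats::runif(length(idx)) * (sizes[idx] - lens[idx] + 1))
  starts <- draw(seq_len(n))
  if (!is.null(excluded) && nrow(excluded) > 0L && n > 0) {
    tries <- rep(0L, n)
    repeat {
      seg <- data.frame(chrom = chroms, start = starts, end = starts + lens,
                        stringsAsFactors = FALSE)
      bad <- which(intersect_flags(seg, excluded))
      if (!length(bad)) break
      tries[bad] <- tries[bad] + 1L
      if (any(tries > 1e4))
        stop("placement impossible after 10^4 rejections for segment ",
             which(tries > 1e4)[1L])
      starts[bad] <- draw(bad)
    }
  }
  gintervals(chroms, starts, starts + lens, name = paste0("seg_", seq_len(n)))
}

#' Permutation test for transcription-regulator targeting
#'
#' The observed statistic is the number of distinct regulator genes
#' targeted by `regions` through the (pre-filtered) chromatin-interaction
#' links, via [assign_targets()] semantics. Each permutation replaces the
#' regions by chromosome- and length-matched random segments and recounts.
#' The empirical p-value uses add-one smoothing:
#' `p = (1 + #[null >= observed]) / (1 + n_perm)` for direction `greater`,
#' so p is never 0 and is reproducible bit-exactly given `seed`.
#'
#' @param regions Interval data frame (e.g. the eCGIs of one cell line).
#' @param links Filtered link data frame.
#' @param genes Gene table.
#' @param regulator_ids Character vector of regulator gene ids (non-empty).
#' @param chrom_sizes Named chromosome lengths for segment placement.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param flank Promoter half-width (default 1000).
#' @param direction `"greater"`, `"less"` or `"two_sided"`.
#' @param statistic Count distinct regulator genes (`"genes"`, default) or
#'   regulator-touching link-anchor events (`"links"`).
#' @param length_matched Keep per-template segment lengths (default TRUE).
#' @return List with `observed`, `null_counts`, `p_value`, `direction`,
#'   `n_perm`.
#' @export
permutation_enrichment <- function(regions, links, genes, regulator_ids,
                                   chrom_sizes, n_perm = 1000, seed = 1,
                                   flank = 1000,
                                   direction = c("greater", "less", "two_sided"),
                                   statistic = c("genes", "links"),
                                   length_matched = TRUE) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  if (!length(regulator_ids)) stop("regulator_ids must be non-empty")
  stopifnot(n_perm >= 1)
  reg_set <- unique(as.character(regulator_ids))
  prom <- promoter_window(genes, flank)
  a1 <- data.frame(chrom = links$chrom1, start = links$start1,
                   end = links$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = links$chrom2, start = links$start2,
                   end = links$end2, stringsAsFactors = FALSE)
  # regulator genes reachable through each anchor's promoter overlaps,
  # precomputed once; permutations only move the region set
  reg_genes_by_anchor <- function(anchors) {
    hits <- .overlap_pairs(anchors, prom)
    keep <- genes$gene_id[hits[, 2L]] %in% reg_set
    split(genes$gene_id[hits[, 2L][keep]], hits[, 1L][keep])
  }
  reg1 <- reg_genes_by_anchor(a1)   # regulators at anchor1 promoters
  reg2 <- reg_genes_by_anchor(a2)
  count_stat <- function(region_df) {
    hit1 <- intersect_flags(a1, region_df)   # anchor1 lands in a region
    hit2 <- intersect_flags(a2, region_df)
    l1 <- as.character(which(hit1))          # partner anchor2 genes count
    l2 <- as.character(which(hit2))
    g <- c(unlist(reg2[intersect(l1, names(reg2))], use.names = FALSE),
           unlist(reg1[intersect(l2, names(reg1))], use.names = FALSE))
    if (statistic == "genes") length(unique(g)) else length(g)
  }
  observed <- count_stat(regions)
  # permutation loop: per-chromosome anchor IRanges are fixed, only the
  # segment set moves, so overlaps reduce to one countOverlaps per side
  chroms <- regions$chrom
  if (!all(chroms %in% names(chrom_sizes)))
    stop("chrom_sizes missing chromosome: ",
         setdiff(chroms, names(chrom_sizes))[1L])
  lens0 <- regions$end - regions$start
  sizes <- unname(chrom_sizes[chroms])
  if (any(lens0 >= sizes))
    stop("template longer than its chromosome at segment ",
         which(lens0 >= sizes)[1L])
  # fold chromosomes onto one absolute axis (half-open coordinates cannot
  # overlap across the per-chromosome offsets), so each permutation costs a
  # single findOverlaps per anchor side
  all_chr <- names(chrom_sizes)
  offsets <- stats::setNames(
    cumsum(c(0, utils::head(unname(chrom_sizes) + 1, -1))), all_chr)
  anchor_abs <- function(a) {
    keep <- which(a$chrom %in% all_chr)
    off <- offsets[a$chrom[keep]]
    list(idx = keep,
         ir = IRanges::IRanges(off + a$start[keep] + 1, off + a$end[keep]))
  }
  ab1 <- anchor_abs(a1)
  ab2 <- anchor_abs(a2)
  seg_off <- unname(offsets[chroms])
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    lens <- if (length_matched) lens0 else
      sample(lens0, length(lens0), replace = TRUE)
    starts <- floor(stats::runif(length(lens)) * (sizes - lens + 1))
    seg_ir <- IRanges::IRanges(seg_off + starts + 1, seg_off + starts + lens)
    l1 <- ab1$idx[IRanges::countOverlaps(ab1$ir, seg_ir) > 0L]
    l2 <- ab2$idx[IRanges::countOverlaps(ab2$ir, seg_ir) > 0L]
    g <- c(unlist(reg2[intersect(as.character(l1), names(reg2))],
                  use.names = FALSE),
           unlist(reg1[intersect(as.character(l2), names(reg1))],
                  use.names = FALSE))
    if (statistic == "genes") length(unique(g)) else length(g)
  }, numeric(1))
  p <- switch(direction,
    greater = (1 + sum(null_counts >= observed)) / (1 + n_perm),
    less = (1 + sum(null_counts <= observed)) / (1 + n_perm),
    two_sided = min(1, 2 * min(
      (1 + sum(null_counts >= observed)) / (1 + n_perm),
      (1 + sum(null_counts <= observed)) / (1 + n_perm))))
  list(observed = observed, null_counts = null_counts, p_value = p,
       direction = direction, n_perm = n_perm)
}

#' Fisher's exact test for gene-category enrichment
#'
#' Builds the 2x2 table (hit/non-hit x in-category/not) over the gene
#' universe and computes the two-sided exact p by summing hypergeometric
#' point probabilities not exceeding the observed table's (with the usual
#' relative tolerance on the comparison). The odds ratio is the sample
#' cross-product `(a*d)/(b*c)`; 0/0 gives NaN.
#'
#' @param hit_genes Character vector, subset of `universe` (e.g. targets of
#'   hypermethylated eCGIs).
#' @param category Character vector, subset of `universe` (e.g. tumor
#'   suppressor genes).
#' @param universe Non-empty character vector of all eligible gene ids.
#' @return List with `table` (2x2 matrix), `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(hit_genes, category, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  hit <- unique(as.character(hit_genes))
  cat_ <- unique(as.character(category))
  if (!all(hit %in% universe)) stop("hit_genes must be a subset of universe")
  if (!all(cat_ %in% universe)) stop("category must be a subset of universe")
  a <- length(intersect(hit, cat_))
  b <- length(setdiff(hit, cat_))
  c_ <- length(setdiff(cat_, hit))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, c_, b, d), nrow = 2,
                dimnames = list(c("hit", "non_hit"),
                                c("in_category", "not_in_category")))
  n_hit <- a + b
  k_cat <- a + c_
  n_tot <- length(universe)
  support <- max(0, n_hit + k_cat - n_tot):min(n_hit, k_cat)
  probs <- stats::dhyper(support, k_cat, n_tot - k_cat, n_hit)
  p_obs <- stats::dhyper(a, k_cat, n_tot - k_cat, n_hit)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  # cross-product ratio: x/0 -> Inf, 0/0 -> NaN, as documented
  list(table = tab, odds_ratio = (a * d) / (b * c_), p_value = min(1, p))
}
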