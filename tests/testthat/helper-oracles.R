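# Independent brute-force oracles used to check the package's fast paths.
# All are deliberately naive: nested loops, per-base materialization, full
# enumeration. They must never share code with the implementation.

# nested-loop overlap flag: query i overlaps >= 1 subject
bf_intersect_flags <- function(queries, subjects) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(subjects$chrom == queries$chrom[i] &
          queries$start[i] < subjects$end &
          subjects$start < queries$end[i])
  }, logical(1))
}

# random interval fixture on a toy genome
rand_intervals <- function(n, chroms = c("chr1", "chr2"), size = 1e6,
                           min_len = 50, max_len = 5000) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- floor(runif(n) * (size - len))
  gintervals(chrom, start, start + len, name = paste0("iv_", seq_len(n)))
}

# brute-force classification cascade, one CGI at a time
bf_classify <- function(cgis, genes, k27, dhs, cage, denovo, flank = 1000) {
  coding <- genes[genes$coding, , drop = FALSE]
  prom <- data.frame(chrom = coding$chrom,
                     start = pmax(0, coding$tss - flank),
                     end = coding$tss + flank + 1)
  dn_win <- if (nrow(denovo)) data.frame(chrom = denovo$chrom,
                                         start = pmax(0, denovo$start - flank),
                                         end = denovo$end + flank)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  hits <- function(i, subj) {
    nrow(subj) > 0 && any(subj$chrom == cgis$chrom[i] &
                            cgis$start[i] < subj$end &
                            subj$start < cgis$end[i])
  }
  vapply(seq_len(nrow(cgis)), function(i) {
    if (hits(i, prom)) return("pCGI")
    if (!(hits(i, k27) && hits(i, dhs))) return("orphan_inactive")
    if (hits(i, cage) || hits(i, dn_win)) return("npCGI")
    "eCGI"
  }, character(1))
}

# per-base materialization of a coverage track over [lo, hi) on one chrom
bf_base_vector <- function(coverage, chrom, lo, hi) {
  v <- numeric(hi - lo)
  seg <- coverage[coverage$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(seg))) {
    a <- max(seg$start[j], lo); b <- min(seg$end[j], hi)
    if (a < b) v[(a - lo + 1):(b - lo)] <- seg$value[j]
  }
  v
}

# per-base metaprofile oracle (regions on arbitrary chroms, clip at 0)
bf_metaprofile <- function(regions, coverage, flank, n_bins) {
  w <- 2 * flank / n_bins
  acc <- matrix(NA_real_, nrow = n_bins, ncol = nrow(regions))
  for (i in seq_len(nrow(regions))) {
    center <- floor((regions$start[i] + regions$end[i]) / 2)
    lo <- center - flank
    base <- bf_base_vector(coverage, regions$chrom[i], max(lo, 0),
                           center + flank)
    offset <- max(0, -lo)        # bases clipped below position 0
    full <- c(rep(NA_real_, offset), base)
    for (b in seq_len(n_bins)) {
      vals <- full[((b - 1) * w + 1):(b * w)]
      vals <- vals[!is.na(vals)]
      if (length(vals)) acc[b, i] <- mean(vals)
    }
  }
  out <- rowMeans(acc, na.rm = TRUE)
  out[is.nan(out)] <- 0
  out
}

# exact two-sample rank-sum p-values by enumerating group assignments
bf_rank_sum_p <- function(x, y) {
  n_a <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  list(p_greater = mean(sums >= obs - 1e-9),
       p_less = mean(sums <= obs + 1e-9),
       p_two_sided = min(1, mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)))
}

# exact signed-rank p-values by enumerating all 2^n sign patterns
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  sums <- apply(signs, 1, function(s) sum(r[s]))
  mu <- mean(sums)
  list(p_greater = mean(sums >= obs - 1e-9),
       p_less = mean(sums <= obs + 1e-9),
       p_two_sided = min(1, mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)))
}

# two-sided Fisher p by explicit enumeration of tables with fixed margins
bf_fisher_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  n_hit <- a + b
  k_cat <- a + c_
  ks <- max(0, n_hit + k_cat - n):min(n_hit, k_cat)
  pr <- vapply(ks, function(k) {
    choose(k_cat, k) * choose(n - k_cat, n_hit - k) / choose(n, n_hit)
  }, numeric(1))
  p_obs <- pr[ks == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# all-triples target assignment oracle
bf_assign_targets <- function(regions, links, genes, flank = 1000) {
  ov <- function(c1, s1, e1, c2, s2, e2) c1 == c2 && s1 < e2 && s2 < e1
  out <- list()
  rid <- regions$name
  for (l in seq_len(nrow(links))) {
    for (r in seq_len(nrow(regions))) {
      for (g in seq_len(nrow(genes))) {
        ps <- max(0, genes$tss[g] - flank); pe <- genes$tss[g] + flank + 1
        hit <- (ov(links$chrom1[l], links$start1[l], links$end1[l],
                   regions$chrom[r], regions$start[r], regions$end[r]) &&
                  ov(links$chrom2[l], links$start2[l], links$end2[l],
                     genes$chrom[g], ps, pe)) ||
          (ov(links$chrom2[l], links$start2[l], links$end2[l],
              regions$chrom[r], regions$start[r], regions$end[r]) &&
             ov(links$chrom1[l], links$start1[l], links$end1[l],
                genes$chrom[g], ps, pe))
        if (hit)
          out[[length(out) + 1L]] <- data.frame(
            region_id = rid[r], gene_id = genes$gene_id[g],
            tag = links$tag_count[l], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(0), gene_id = character(0),
                      tag_count = numeric(0)))
  df <- do.call(rbind, out)
  agg <- stats::aggregate(tag ~ region_id + gene_id, df, max)
  agg <- agg[order(agg$region_id, agg$gene_id), ]
  rownames(agg) <- NULL
  names(agg)[3] <- "tag_count"
  agg
}

# sliding-window dinucleotide counting oracle for sequence statistics
bf_seq_stats <- function(s) {
  ch <- strsplit(s, "")[[1]]
  eff <- sum(ch != "N")
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  ncpg <- 0
  for (i in seq_len(length(ch) - 1))
    if (ch[i] == "C" && ch[i + 1] == "G") ncpg <- ncpg + 1
  list(gc = 100 * (nc + ng) / eff,
       oe = if (nc > 0 && ng > 0) ncpg * eff / (nc * ng) else 0)
}

# small noise-free dataset for fast end-to-end checks
small_clean_config <- function(seed = 1) {
  synth_config(
    seed = seed,
    chrom_sizes = c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6),
    n_genes = 90, n_cgis = 120, n_typical = 40,
    n_hyper_ecgis = 10, dm_noise_sd = 0, peak_dropout = 0,
    background_cpg_rate = 1e-4
  )
}
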