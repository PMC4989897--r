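test_that("random segments match template chromosome and length", {
  set.seed(101)
  templates <- rand_intervals(50)
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  seg <- random_segments(templates, sizes, seed = 5)
  expect_equal(seg$chrom, templates$chrom)
  expect_equal(seg$end - seg$start, templates$end - templates$start)
  expect_true(all(seg$start >= 0 & seg$end <= sizes[seg$chrom]))
  # deterministic given seed
  expect_equal(random_segments(templates, sizes, seed = 5), seg)
  # template longer than its chromosome is rejected
  expect_error(random_segments(gintervals("chr1", 0, 2e6), sizes),
               "longer than its chromosome")
})

test_that("excluded regions force placement into the remaining gap", {
  sizes <- c(chr1 = 10000)
  excluded <- gintervals("chr1", c(0, 600), c(500, 10000))
  seg <- random_segments(gintervals("chr1", 0, 100), sizes, excluded,
                         seed = 7)
  expect_gte(seg$start, 500)
  expect_lte(seg$end, 600)
  # impossible placement errors after bounded rejections
  full <- gintervals("chr1", 0, 10000)
  expect_error(random_segments(gintervals("chr1", 0, 100), sizes, full,
                               seed = 7), "placement impossible")
})

test_that("segment starts are uniform over the chromosome", {
  set.seed(103)
  template <- gintervals("chr1", 5000, 6000)
  sizes <- c(chr1 = 101000)  # 10^5 legal start positions
  starts <- replicate(10000, random_segments(template, sizes)$start)
  bins <- cut(starts, breaks = seq(0, 100000, length.out = 11),
              include.lowest = TRUE)
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.001)
})

test_that("fisher enrichment matches hypergeometric enumeration and edge cases", {
  res <- fisher_enrichment(paste0("h", 1:10),
                           c(paste0("h", 1), paste0("c", 1:11)),
                           c(paste0("h", 1:10), paste0("c", 1:11),
                             paste0("u", 1:79)))
  expect_equal(res$table[1, 1], 1)
  expect_equal(res$p_value, bf_fisher_p(1, 9, 11, 79), tolerance = 1e-12)
  # independence table -> odds ratio 1
  u <- paste0("g", 1:100)
  res2 <- fisher_enrichment(u[1:10], c(u[1:2], u[11:28]), u)
  expect_equal(res2$odds_ratio, 1)
  # category == universe -> p = 1
  res3 <- fisher_enrichment(u[1:10], u, u)
  expect_equal(res3$p_value, 1)
  expect_error(fisher_enrichment("a", "a", character(0)), "empty universe")
  expect_error(fisher_enrichment("zz", u[1], u), "subset")
})

test_that("fisher p agrees with stats::fisher.test across random tables", {
  set.seed(107)
  for (k in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b + c_ + d == 0) next
    u <- paste0("g", seq_len(a + b + c_ + d))
    hit <- u[seq_len(a + b)]
    cat_ <- c(u[seq_len(a)],
              if (c_ > 0) u[(a + b + 1):(a + b + c_)])
    got <- fisher_enrichment(hit, cat_, u)
    ref <- stats::fisher.test(got$table)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("permutation p-values are reproducible, smoothed and calibrated", {
  set.seed(109)
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  gstart <- sample(5000:900000, 40)
  genes <- make_gene_table(paste0("g", 1:40),
                           sample(names(sizes), 40, TRUE), "+",
                           gstart, gstart + 3000, TRUE)
  regions <- rand_intervals(30, min_len = 500, max_len = 2000)
  a1 <- rand_intervals(60, min_len = 200, max_len = 500)
  a2 <- rand_intervals(60, min_len = 200, max_len = 500)
  links <- make_links(a1$chrom, a1$start, a1$end, a2$chrom, a2$start,
                      a2$end, sample(3:8, 60, TRUE))
  regs <- paste0("g", 1:20)
  r1 <- permutation_enrichment(regions, links, genes, regs, sizes,
                               n_perm = 99, seed = 17)
  r2 <- permutation_enrichment(regions, links, genes, regs, sizes,
                               n_perm = 99, seed = 17)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 100)        # add-one smoothing floor
  expect_equal(length(r1$null_counts), 99)
  expect_error(permutation_enrichment(regions, links, genes, character(0),
                                      sizes), "non-empty")
  # empty interactome: observed 0, every null count 0, p(greater) = 1
  nolinks <- links[0, ]
  r0 <- permutation_enrichment(regions, nolinks, genes, regs, sizes,
                               n_perm = 19, seed = 3)
  expect_equal(r0$observed, 0)
  expect_true(all(r0$null_counts == 0))
  expect_equal(r0$p_value, 1)
  # saturating category: observed equals total distinct targeted genes
  rall <- permutation_enrichment(regions, links, genes, paste0("g", 1:40),
                                 sizes, n_perm = 9, seed = 3)
  asg <- assign_targets(regions, links, genes)
  expect_equal(rall$observed, length(unique(asg$gene_id)))
})

test_that("observed regulator count equals the assign_targets route", {
  set.seed(127)
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  gstart <- sample(5000:900000, 50)
  genes <- make_gene_table(paste0("g", 1:50), sample(names(sizes), 50, TRUE),
                           sample(c("+", "-"), 50, TRUE), gstart,
                           gstart + 4000, TRUE)
  for (k in 1:5) {
    regions <- rand_intervals(25, min_len = 500, max_len = 2000)
    a1 <- rand_intervals(120, min_len = 200, max_len = 500)
    a2 <- rand_intervals(120, min_len = 200, max_len = 500)
    links <- make_links(a1$chrom, a1$start, a1$end, a2$chrom, a2$start,
                        a2$end, sample(3:8, 120, TRUE))
    regs <- paste0("g", sample(1:50, 20))
    res <- permutation_enrichment(regions, links, genes, regs, sizes,
                                  n_perm = 1, seed = 1)
    asg <- assign_targets(regions, links, genes)
    expect_equal(res$observed, length(intersect(unique(asg$gene_id), regs)))
  }
})
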