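test_that("link filtering keeps tag_count >= min_tags, order preserved", {
  links <- make_links("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                      "chr1", c(1000, 1100, 1200, 1300),
                      c(1050, 1150, 1250, 1350), tag_count = 1:4)
  kept <- filter_links(links, 3)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$tag_count, c(3, 4))
  expect_equal(filter_links(links, 1), links, ignore_attr = TRUE)
  # idempotent subset
  expect_equal(filter_links(kept, 3), kept, ignore_attr = TRUE)
  # linear-scan oracle at scale
  set.seed(73)
  tags <- sample(1:10, 1e4, replace = TRUE)
  big <- make_links("chr1", 0, 10, "chr1", 20, 30, tags)
  expect_equal(nrow(filter_links(big, 4)), sum(tags >= 4))
})

test_that("target assignment matches the all-triples brute-force oracle", {
  set.seed(79)
  gstart <- sample(5000:900000, 30)
  genes <- make_gene_table(paste0("g", 1:30),
                           sample(c("chr1", "chr2"), 30, TRUE),
                           sample(c("+", "-"), 30, TRUE), gstart,
                           gstart + sample(2000:8000, 30, TRUE), TRUE)
  regions <- rand_intervals(50, min_len = 200, max_len = 2000)
  n_l <- 200
  a1 <- rand_intervals(n_l, min_len = 100, max_len = 600)
  a2 <- rand_intervals(n_l, min_len = 100, max_len = 600)
  links <- make_links(a1$chrom, a1$start, a1$end, a2$chrom, a2$start, a2$end,
                      sample(3:9, n_l, replace = TRUE))
  got <- assign_targets(regions, links, genes)
  ora <- bf_assign_targets(regions, links, genes)
  expect_equal(got[, c("region_id", "gene_id", "tag_count")], ora,
               ignore_attr = TRUE)
  # anchors are interchangeable: swapping leaves assignments unchanged
  swapped <- make_links(links$chrom2, links$start2, links$end2,
                        links$chrom1, links$start1, links$end1,
                        links$tag_count)
  expect_equal(assign_targets(regions, swapped, genes), got,
               ignore_attr = TRUE)
})

test_that("self-loop links without a promoter anchor assign nothing", {
  genes <- make_gene_table("g1", "chr1", "+", 500000, 505000, TRUE)
  region <- gintervals("chr1", 1000, 3000, name = "r1")
  # both anchors inside the region, far from the promoter
  self_loop <- make_links("chr1", 1100, 1300, "chr1", 2500, 2700, 5)
  expect_equal(nrow(assign_targets(region, self_loop, genes)), 0)
  # one anchor in region, other at promoter -> assigned
  good <- make_links("chr1", 1100, 1300, "chr1", 499800, 500200, 5)
  res <- assign_targets(region, good, genes)
  expect_equal(res$gene_id, "g1")
  expect_equal(res$evidence, "chia")
})

test_that("tag counts aggregate by max (or sum) over supporting links", {
  genes <- make_gene_table("g1", "chr1", "+", 500000, 505000, TRUE)
  region <- gintervals("chr1", 1000, 3000, name = "r1")
  links <- make_links("chr1", c(1100, 1500), c(1300, 1700), "chr1",
                      c(499800, 499900), c(500200, 500300), c(4, 7))
  expect_equal(assign_targets(region, links, genes)$tag_count, 7)
  expect_equal(assign_targets(region, links, genes, agg = "sum")$tag_count, 11)
})

test_that("target multiplicity fractions count single vs multiple targets", {
  asg <- data.frame(region_id = c("r1", "r2", "r3", "r3"),
                    gene_id = c("g1", "g1", "g2", "g3"))
  m <- target_multiplicity(asg)
  expect_equal(m$fraction_single, 2 / 3)
  expect_equal(m$fraction_multiple, 1 / 3)
  expect_equal(m$fraction_single + m$fraction_multiple, 1)
  one <- target_multiplicity(data.frame(region_id = "r", gene_id = "g"))
  expect_equal(c(one$fraction_single, one$fraction_multiple), c(1, 0))
  expect_error(target_multiplicity(asg[0, ]), "no assigned")
})

test_that("planted multi-target fraction is recovered at n=500 eCGIs", {
  set.seed(83)
  n <- 500
  multi <- runif(n) < 0.6
  counts <- ifelse(multi, sample(2:4, n, replace = TRUE), 1L)
  asg <- data.frame(
    region_id = rep(paste0("r", seq_len(n)), counts),
    gene_id = paste0("g", sequence(counts), "_", rep(seq_len(n), counts)))
  m <- target_multiplicity(asg)
  expect_lt(abs(m$fraction_multiple - 0.6), 0.05)
})

test_that("link strength comparison uses the two-sample rank test", {
  res <- compare_link_strength(c(5, 6, 7), c(1, 2, 3))
  expect_equal(res$p_greater, 0.05)
  # planted tag-count shift is detected reliably
  set.seed(89)
  rej <- vapply(1:100, function(i) {
    a <- 3 + rpois(200, 2) + 2
    b <- 3 + rpois(200, 2)
    compare_link_strength(a, b)$p_greater < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # paired variant
  pr <- compare_link_strength(c(4, 5, 6, 7), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(pr$p_greater, 1 / 16)
})

test_that("expression fold changes use the pseudocount and drop missing genes", {
  ea <- c(g1 = 10, g2 = 5.88, g3 = 2)
  eb <- c(g1 = 10, g2 = 1.0)
  expect_equal(unname(expression_fold_change("g1", ea, eb, 0.1)), 1)
  expect_equal(unname(expression_fold_change("g2", ea, eb, 0)), 5.88)
  expect_warning(fc <- expression_fold_change(c("g1", "g3"), ea, eb, 0.1),
                 "missing")
  expect_equal(names(fc), "g1")
  expect_error(expression_fold_change("g1", c(g1 = -1), eb), "negative")
})

test_that("planted 4x up-regulation yields median fold near 4 at n=200", {
  set.seed(97)
  genes <- paste0("g", 1:200)
  base <- 2^rnorm(200, 3, 1.5)
  ea <- stats::setNames(base * 4 * 2^rnorm(200, 0, 0.3), genes)
  eb <- stats::setNames(base * 2^rnorm(200, 0, 0.3), genes)
  folds <- expression_fold_change(genes, ea, eb, 0.1)
  expect_true(median(folds) >= 3 && median(folds) <= 5)
})
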