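.beta_tbl <- function(chrom, position, beta) {
  data.frame(chrom = chrom, position = position, beta = beta,
             stringsAsFactors = FALSE)
}

test_that("differential methylation matches sites and computes dm", {
  n <- .beta_tbl("chr1", c(10, 20, 30), c(0.1, 0.5, NA))
  t <- .beta_tbl("chr1", c(10, 30, 40), c(0.8, 0.4, 0.9))
  res <- suppressMessages(differential_methylation(n, t))
  expect_equal(res$position, 10)
  expect_equal(res$dm, 0.7)
  expect_equal(res$beta_tumor - res$beta_normal, res$dm)
  # identical tables -> all dm zero
  res0 <- suppressMessages(differential_methylation(n[1:2, ], n[1:2, ]))
  expect_equal(res0$dm, c(0, 0))
  # invalid beta is rejected with the position named
  bad <- .beta_tbl("chr2", 5, 1.2)
  expect_error(suppressMessages(differential_methylation(bad, bad)), "chr2:5")
  # matched count equals the set-intersection oracle
  set.seed(131)
  pos_n <- sample(1:5000, 800)
  pos_t <- sample(1:5000, 800)
  rn <- .beta_tbl("chr1", pos_n, runif(800))
  rt <- .beta_tbl("chr1", pos_t, runif(800))
  res2 <- suppressMessages(differential_methylation(rn, rt))
  expect_equal(nrow(res2), length(intersect(pos_n, pos_t)))
})

test_that("dm is antisymmetric in the condition labels", {
  set.seed(137)
  pos <- sort(sample(1:10000, 300))
  a <- .beta_tbl("chr1", pos, runif(300))
  b <- .beta_tbl("chr1", pos, runif(300))
  ab <- suppressMessages(differential_methylation(a, b))
  ba <- suppressMessages(differential_methylation(b, a))
  expect_equal(ab$dm, -ba$dm)
  regions <- rand_intervals(40, chroms = "chr1", size = 10000,
                            min_len = 50, max_len = 500)
  r_ab <- suppressMessages(aggregate_region_dm(ab, regions))
  r_ba <- suppressMessages(aggregate_region_dm(ba, regions))
  expect_equal(r_ab$mean_dm, -r_ba$mean_dm)
})

test_that("region aggregation averages contained CpGs and drops empty regions", {
  sites <- suppressMessages(differential_methylation(
    .beta_tbl("chr1", c(100, 150, 500), c(0.1, 0.1, 0.2)),
    .beta_tbl("chr1", c(100, 150, 500), c(0.3, 0.7, 0.2))))
  regions <- gintervals("chr1", c(50, 400, 900), c(200, 600, 1000),
                        name = c("rA", "rB", "rC"))
  agg <- suppressMessages(aggregate_region_dm(sites, regions))
  expect_equal(agg$region_id, c("rA", "rB"))
  expect_equal(agg$mean_dm, c(0.4, 0))
  expect_equal(agg$n_cpgs, c(2L, 1L))
  expect_equal(attr(agg, "n_excluded"), 1L)
  # brute-force per-region scan oracle
  set.seed(139)
  pos <- sort(sample(1:50000, 2000))
  sites2 <- suppressMessages(differential_methylation(
    .beta_tbl("chr1", pos, runif(2000)), .beta_tbl("chr1", pos, runif(2000))))
  regions2 <- rand_intervals(60, chroms = "chr1", size = 50000,
                             min_len = 20, max_len = 800)
  agg2 <- suppressMessages(aggregate_region_dm(sites2, regions2))
  for (i in seq_len(nrow(regions2))) {
    inside <- sites2$dm[sites2$position >= regions2$start[i] &
                          sites2$position < regions2$end[i]]
    if (!length(inside)) {
      expect_false(regions2$name[i] %in% agg2$region_id)
    } else {
      expect_equal(agg2$mean_dm[agg2$region_id == regions2$name[i]],
                   mean(inside), tolerance = 1e-12)
    }
  }
})

test_that("hypermethylation selection is strict and monotone in the threshold", {
  rd <- data.frame(region_id = c("a", "b", "c", "d"), n_cpgs = 5L,
                   mean_dm = c(0.5, 0.51, 0.09, 0.11))
  expect_equal(select_hypermethylated(rd, 0.5)$region_id, "b")  # strict >
  expect_setequal(select_hypermethylated(rd, 0.1)$region_id,
                  c("a", "b", "d"))
  expect_error(select_hypermethylated(rd, 0), "0, 1")
  # monotone nesting over a threshold grid
  set.seed(149)
  rd2 <- data.frame(region_id = paste0("r", 1:200), n_cpgs = 10L,
                    mean_dm = runif(200, -0.2, 0.9))
  prev <- select_hypermethylated(rd2, 0.1)$region_id
  for (t in c(0.3, 0.5, 0.7)) {
    cur <- select_hypermethylated(rd2, t)$region_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("class dm contrast shares the exact rank-sum machinery", {
  e <- data.frame(region_id = paste0("e", 1:5), n_cpgs = 5L, mean_dm = 0.6)
  p <- data.frame(region_id = paste0("p", 1:5), n_cpgs = 5L, mean_dm = 0)
  res <- class_dm_contrast(e, p)
  expect_equal(res$p_greater, 1 / choose(10, 5))
  expect_equal(res$median_a, 0.6)
  expect_equal(res$median_b, 0)
  expect_error(class_dm_contrast(e[0, ], p), "non-empty")
  # power at planted shift 0.2, n=100 per class
  set.seed(151)
  rej <- vapply(1:200, function(i) {
    a <- rnorm(100, 0.2, 0.15)
    b <- rnorm(100, 0, 0.15)
    class_dm_contrast(a, b)$p_greater < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("target silencing folds and one-sample test behave at the null", {
  asg <- data.frame(region_id = c("h1", "h2", "o1"),
                    gene_id = c("g1", "g2", "g3"))
  e <- c(g1 = 4, g2 = 8, g3 = 2)
  res <- target_silencing(c("h1", "h2"), asg, e, e)
  expect_equal(unname(res$fold_changes), c(1, 1))
  expect_equal(res$p_down, 1)
  # all folds below 1 at n=12 -> exact signed-rank 1/2^12
  asg12 <- data.frame(region_id = "h", gene_id = paste0("g", 1:12))
  en <- stats::setNames(rep(8, 12), paste0("g", 1:12))
  et <- stats::setNames(seq(1, 4, length.out = 12), paste0("g", 1:12))
  res12 <- target_silencing("h", asg12, en, et)
  expect_equal(res12$p_down, 1 / 2^12)
  expect_error(target_silencing("nope", asg, e, e), "no targets")
})

test_that("dm matrix keeps only CpGs beyond the threshold inside regions", {
  sites <- suppressMessages(differential_methylation(
    .beta_tbl("chr1", c(100, 150, 200), c(0.1, 0.2, 0.9)),
    .beta_tbl("chr1", c(100, 150, 200), c(0.9, 0.3, 0.1))))
  regions <- gintervals("chr1", 50, 250, name = "r")
  m <- dm_matrix(sites, regions, 0.5)
  expect_equal(m$position, c(100, 200))
  expect_equal(m$dm, c(0.8, -0.8))
  # threshold 0 keeps all in-region CpGs; nothing passing is not an error
  expect_equal(nrow(dm_matrix(sites, regions, 0)), 3)
  expect_equal(nrow(dm_matrix(sites, regions, 0.95)), 0)
  # filter-scan oracle
  set.seed(157)
  pos <- sort(sample(1:30000, 1500))
  s2 <- suppressMessages(differential_methylation(
    .beta_tbl("chr1", pos, runif(1500)), .beta_tbl("chr1", pos, runif(1500))))
  r2 <- rand_intervals(30, chroms = "chr1", size = 30000)
  m2 <- dm_matrix(s2, r2, 0.4)
  manual <- 0
  for (i in seq_len(nrow(r2)))
    manual <- manual + sum(abs(s2$dm) > 0.4 & s2$position >= r2$start[i] &
                             s2$position < r2$end[i])
  expect_equal(nrow(m2), manual)
})

test_that("planted region dm is recovered within sampling error", {
  set.seed(163)
  delta <- 0.6; sigma <- 0.05; n_cpg <- 25
  ok <- vapply(1:300, function(i) {
    bn <- rbeta(n_cpg, 1.5, 15)
    bt <- pmin(1, bn + delta + rnorm(n_cpg, 0, sigma))
    dm <- bt - bn
    abs(mean(dm) - delta) <= 3 * sigma / sqrt(n_cpg)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})
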