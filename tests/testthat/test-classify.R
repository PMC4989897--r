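# fixture pieces shared across blocks
.mk_tracks <- function() {
  genes <- make_gene_table(c("NM_1", "NR_1"), c("chr1", "chr1"), c("+", "+"),
                           c(50000, 200000), c(60000, 210000), c(TRUE, FALSE))
  list(
    genes = genes,
    k27 = gintervals("chr1", c(49500, 120000), c(51000, 121000)),
    dhs = gintervals("chr1", c(49600, 120100), c(50800, 120900)),
    cage = gintervals("chr1", 300000, 300020),
    denovo = gintervals("chr1", 400000, 400001)
  )
}

test_that("classification cascade applies rules in order", {
  tr <- .mk_tracks()
  cgis <- gintervals("chr1",
                     c(49700, 120200, 120300, 300000, 399500, 700000),
                     c(50500, 120800, 120700, 300400, 400400, 700600),
                     name = paste0("c", 1:6))
  # c1: overlaps coding promoter AND both peaks -> promoter rule wins
  # c2/c3: both peaks, no TSS evidence -> eCGI
  # c4: would need peaks; has CAGE only -> orphan_inactive (AND requirement)
  # c5: overlaps de-novo TSS window but no peaks -> orphan_inactive
  # c6: nothing -> orphan_inactive
  out <- classify_cgis(cgis, tr$genes, tr$k27, tr$dhs, tr$cage, tr$denovo)
  expect_equal(as.character(out$label),
               c("pCGI", "eCGI", "eCGI", "orphan_inactive",
                 "orphan_inactive", "orphan_inactive"))
  # noncoding gene promoters do not make pCGIs
  cgi_nr <- gintervals("chr1", 199800, 200400, name = "nr")
  k27 <- rbind(tr$k27, gintervals("chr1", 199700, 200500))
  dhs <- rbind(tr$dhs, gintervals("chr1", 199700, 200500))
  out2 <- classify_cgis(cgi_nr, tr$genes, k27, dhs, tr$cage, tr$denovo)
  expect_equal(as.character(out2$label), "eCGI")
  # active orphan with CAGE evidence -> npCGI; with only one mark -> inactive
  cgi_np <- gintervals("chr1", 299900, 300500, name = "np")
  k27b <- rbind(tr$k27, gintervals("chr1", 299800, 300600))
  dhsb <- rbind(tr$dhs, gintervals("chr1", 299800, 300600))
  out3 <- classify_cgis(cgi_np, tr$genes, k27b, dhsb, tr$cage, tr$denovo)
  expect_equal(as.character(out3$label), "npCGI")
  out4 <- classify_cgis(cgi_np, tr$genes, k27b, tr$dhs, tr$cage, tr$denovo)
  expect_equal(as.character(out4$label), "orphan_inactive")
})

test_that("labels partition the input and empty input is not an error", {
  set.seed(19)
  tr <- .mk_tracks()
  cgis <- rand_intervals(300, chroms = "chr1")
  out <- classify_cgis(cgis, tr$genes, tr$k27, tr$dhs, tr$cage, tr$denovo)
  expect_equal(nrow(out), 300)
  expect_equal(sum(table(out$label)), 300)
  expect_false(any(is.na(out$label)))
  empty <- gintervals(character(0), numeric(0), numeric(0))
  expect_equal(nrow(classify_cgis(empty, tr$genes, tr$k27, tr$dhs,
                                  tr$cage, tr$denovo)), 0)
  expect_error(classify_cgis(cgis, tr$genes, NULL, tr$dhs, tr$cage,
                             tr$denovo), "missing required track")
})

test_that("adding H3K27ac peaks never demotes pCGIs (cascade monotonicity)", {
  set.seed(23)
  tr <- .mk_tracks()
  cgis <- rand_intervals(200, chroms = "chr1")
  before <- classify_cgis(cgis, tr$genes, tr$k27, tr$dhs, tr$cage, tr$denovo)
  more_k27 <- rbind(tr$k27, rand_intervals(100, chroms = "chr1"))
  after <- classify_cgis(cgis, tr$genes, more_k27, tr$dhs, tr$cage, tr$denovo)
  was_p <- before$label == "pCGI"
  expect_true(all(after$label[was_p] == "pCGI"))
  # CGIs can only leave orphan_inactive, never enter it
  expect_true(all(before$label[after$label == "orphan_inactive"] ==
                    "orphan_inactive"))
})

test_that("typical enhancers are DHS peaks with H3K27ac and no exclusions", {
  tr <- .mk_tracks()
  cgis <- gintervals("chr1", 120300, 120700, name = "cgi")
  dhs <- gintervals("chr1", c(120100, 500000, 600000, 300005),
                    c(120900, 500800, 600900, 300500),
                    name = c("d1", "d2", "d3", "d4"))
  k27 <- gintervals("chr1", c(120000, 500100, 300000), c(121000, 500700, 300600))
  te <- call_typical_enhancers(k27, dhs, tr$cage, tr$denovo, cgis)
  # d1 overlaps the CGI -> excluded; d3 has no H3K27ac; d4 overlaps CAGE
  expect_equal(te$source_peak_id, "d2")
  # brute-force filter oracle on a random fixture
  set.seed(29)
  dhs_r <- rand_intervals(150, chroms = "chr1")
  k27_r <- rand_intervals(150, chroms = "chr1")
  cgi_r <- rand_intervals(50, chroms = "chr1")
  te_r <- call_typical_enhancers(k27_r, dhs_r, tr$cage, tr$denovo, cgi_r)
  dn_win <- gintervals(tr$denovo$chrom, pmax(0, tr$denovo$start - 1000),
                       tr$denovo$end + 1000)
  keep <- bf_intersect_flags(dhs_r, k27_r) &
    !bf_intersect_flags(dhs_r, cgi_r) &
    !bf_intersect_flags(dhs_r, tr$cage) &
    !bf_intersect_flags(dhs_r, dn_win)
  expect_equal(nrow(te_r), sum(keep))
  expect_equal(te_r$start, dhs_r$start[keep])
})

test_that("sequence statistics match hand arithmetic and a counting oracle", {
  s <- sequence_stats("CGCG")
  expect_equal(s$length, 4)
  expect_equal(s$gc_percent, 100)
  expect_equal(s$cpg_obs_exp, 2)          # (2 CpG * 4) / (2 C * 2 G)
  s2 <- sequence_stats("ATAT")
  expect_equal(s2$gc_percent, 0)
  expect_equal(s2$cpg_obs_exp, 0)
  expect_error(sequence_stats(""), "empty")
  # N bases excluded from the effective length
  s3 <- sequence_stats("CGNN")
  expect_equal(s3$gc_percent, 100)
  expect_equal(s3$cpg_obs_exp, 1 * 2 / (1 * 1))
  set.seed(31)
  for (k in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    got <- sequence_stats(seq)
    ora <- bf_seq_stats(seq)
    expect_equal(got$gc_percent, ora$gc)
    expect_equal(got$cpg_obs_exp, ora$oe)
  }
})

test_that("cell-specific set arithmetic partitions the union", {
  res <- cell_specific_sets(c("a", "b", "c"), c("c", "d"))
  expect_setequal(res$a_specific, c("a", "b"))
  expect_setequal(res$b_specific, "d")
  expect_setequal(res$common, "c")
  expect_equal(res$a_specific_pct, 100 * 2 / 3)
  expect_equal(length(res$a_specific) + length(res$common), 3)
  expect_equal(length(res$b_specific) + length(res$common), 2)
  # identical inputs
  same <- cell_specific_sets(c("x", "y"), c("x", "y"))
  expect_equal(length(same$a_specific), 0)
  expect_setequal(same$common, c("x", "y"))
  expect_equal(same$a_specific_pct, 0)
  expect_error(cell_specific_sets(c("x", "x"), "y"), "duplicate")
})
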