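test_that("hypergeometric enrichment matches exact enumeration", {
  uni <- paste0("g", 1:10)
  res <- hypergeometricEnrichment(paste0("g", 1:5), paste0("g", 1:4), uni)
  expect_equal(res$n_observed, 4)
  expect_equal(res$n_expected, 2)
  expect_equal(res$ratio, 2)
  expect_equal(res$p, 5 / 210)  # C(5,4) C(5,0) / C(10,4)

  # category == universe: ratio 1, p 1
  all_in <- hypergeometricEnrichment(uni, paste0("g", 1:4), uni)
  expect_equal(all_in$ratio, 1)
  expect_equal(all_in$p, 1)

  # disjoint: ratio 0, depletion lower tail P(X <= 0)
  disj <- hypergeometricEnrichment(paste0("g", 1:5), paste0("g", 6:9), uni)
  expect_equal(disj$ratio, 0)
  expect_equal(disj$direction, "depletion")
  expect_equal(disj$p, dhyper(0, 5, 5, 4))

  # property: upper tail equals subset enumeration for small universes
  set.seed(12)
  for (i in 1:10) {
    N <- sample(8:14, 1)
    uni <- paste0("u", seq_len(N))
    cat_g <- sample(uni, sample(2:(N - 2), 1))
    n <- sample(2:(N - 2), 1)
    cl <- sample(uni, n)
    res <- hypergeometricEnrichment(cat_g, cl, uni)
    if (res$ratio >= 1)
      expect_equal(res$p, oracleHyperUpper(uni, cat_g, n, res$n_observed))
  }
})

test_that("cluster enrichment ratios are conserved across a partition", {
  set.seed(13)
  uni <- paste0("g", 1:60)
  cl_map <- split(uni, rep(1:5, c(20, 15, 10, 10, 5)))
  cat_g <- sample(uni, 18)
  res <- clusterGeneEnrichment(cat_g, cl_map, universe = uni)
  expect_equal(sum(res$n_observed), 18)
  expect_equal(sum(res$n_expected), 18)
  # expected-weighted mean of the ratios is exactly 1
  expect_equal(sum(res$n_expected * res$ratio) / sum(res$n_expected), 1)
})

test_that("interval feature enrichment detects planted binding sites", {
  win <- GRanges("chrT", IRanges(seq(1, by = 20000, length.out = 50),
                                 width = 10000))
  seqlevels(win) <- "chrT"; seqlengths(win) <- 1.2e6
  win$cluster <- rep(1:5, each = 10)

  # uniform scatter: one feature per window -> all ratios exactly 1
  feats <- GRanges("chrT", IRanges(start(win) + 5000, width = 10))
  seqlevels(feats) <- "chrT"; seqlengths(feats) <- 1.2e6
  res <- intervalFeatureEnrichment(feats, win)
  expect_true(all(res$ratio == 1))

  # 200 sites planted only in cluster-5 windows
  set.seed(14)
  c5 <- win[win$cluster == 5]
  planted <- GRanges("chrT", IRanges(
    start(c5)[sample(10, 200, TRUE)] + sample(9000, 200, TRUE), width = 10))
  seqlevels(planted) <- "chrT"; seqlengths(planted) <- 1.2e6
  res2 <- intervalFeatureEnrichment(planted, win)
  expect_gt(res2$ratio[res2$cluster == 5], 4)
  expect_lt(res2$p[res2$cluster == 5], 1e-6)

  # single feature in the single covering cluster
  one <- intervalFeatureEnrichment(feats[1], win[1:10])
  expect_equal(one$ratio, 1)
  expect_equal(one$p, 1)
})

test_that("superenhancer stitching, TSS exclusion and the cutoff work", {
  ann <- toyAnnotation(
    data.frame(chrom = "chrT", start = 500001, end = 520000, strand = "+",
               gene_id = "gFar"), c(chrT = 1e6))
  # three peaks with 5 kb gaps stitch into one region
  p3 <- GRanges("chrT", IRanges(c(10001, 16001, 22001), width = 1000))
  seqlevels(p3) <- "chrT"; seqlengths(p3) <- 1e6
  expect_warning(se3 <- callSuperenhancers(p3, ann, signal = c(1, 1, 1)),
                 "fewer than 3")  # one stitched region: cutoff undefined
  expect_length(se3, 1)
  expect_equal(start(se3), 10001)
  expect_equal(end(se3), 23000)
  expect_equal(se3$n_peaks, 3)

  # signals {1,1,1,1,100}: exactly the 100-signal region is super
  p5 <- GRanges("chrT", IRanges(seq(1, by = 1e5, length.out = 5) + 1,
                                width = 1000))
  seqlevels(p5) <- "chrT"; seqlengths(p5) <- 1e6
  se5 <- callSuperenhancers(p5, ann, signal = c(1, 1, 1, 1, 100))
  expect_equal(sum(se5$is_super), 1)
  expect_equal(se5$total_signal[se5$is_super], 100)
  expect_equal(se5$rank[se5$is_super], 1L)

  # a peak fully inside TSS +/- 2 kb is removed before stitching
  tss_peak <- GRanges("chrT", IRanges(499501, width = 1000))  # on gFar's TSS
  seqlevels(tss_peak) <- "chrT"; seqlengths(tss_peak) <- 1e6
  se_t <- callSuperenhancers(c(p5, tss_peak), ann,
                             signal = c(1, 1, 1, 1, 100, 500))
  expect_false(any(overlapsAny(se_t, tss_peak)))

  # fewer than 3 stitched regions: cutoff undefined, all non-super
  expect_warning(se2 <- callSuperenhancers(p3[1:2], ann, signal = c(5, 9)),
                 "fewer than 3")
  expect_false(any(se2$is_super))
})

test_that("the hockey-stick cutoff matches a scaled-slope scan", {
  toys <- list(c(1, 1, 1, 1, 100),
               c(1, 2, 3, 5, 9, 20, 60),
               exp(seq(0, 4, by = 0.5)),
               c(2, 2.5, 3, 4, 6, 10, 18, 34, 66))
  for (v in toys) {
    cut <- roseCutoff(v)
    expect_identical(v > cut, oracleSuperSet(v))
  }
})

test_that("coverage fractions follow bedtools -f semantics", {
  a <- GRanges("chrT", IRanges(1, 100))     # 0-based [0, 100)
  b <- GRanges("chrT", IRanges(51, 150))    # 0-based [50, 150)
  expect_equal(coverageOverlapFraction(a, b), 0.5)
  expect_equal(coverageOverlapFraction(a, a), 1)
  b2 <- GRanges("chrT", IRanges(c(1, 21), c(30, 60)))  # union 60 bp
  expect_equal(coverageOverlapFraction(a, b2), 0.6)
  expect_equal(coverageOverlapFraction(a, GRanges()), 0)

  # monotone in b_set and invariant to ordering/overlap
  set.seed(15)
  bs <- GRanges("chrT", IRanges(sample(1000, 20), width = 50))
  f1 <- coverageOverlapFraction(a, bs[1:10])
  f2 <- coverageOverlapFraction(a, bs)
  expect_gte(f2, f1)
  expect_equal(coverageOverlapFraction(a, rev(bs)), f2)
  expect_equal(coverageOverlapFraction(a, c(bs, bs[1:5])), f2)
})

test_that("motif occurrence summaries report hit fractions and co-occurrence", {
  regions <- GRanges("chrT", IRanges(seq(1, by = 1000, length.out = 10),
                                     width = 500))
  none <- motifOccurrenceSummary(list(c1 = regions),
                                 list(m1 = GRanges("chrT", IRanges(9e5, 9e5))))
  expect_equal(none$percent_with_hit, 0)
  expect_true(is.na(none$mean_cooccurrence))

  hits6 <- GRanges("chrT", IRanges(rep(start(regions) + 10, 6), width = 5))
  all6 <- motifOccurrenceSummary(list(c1 = regions), list(m1 = hits6))
  expect_equal(all6$percent_with_hit, 100)
  expect_equal(all6$mean_cooccurrence, 6)
  expect_error(motifOccurrenceSummary(list(), list(m1 = hits6)), "empty")
})

test_that("direct targets intersect binding-annotated and KO-deregulated genes", {
  ann <- toyAnnotation(
    data.frame(chrom = "chrT", start = c(10001, 40001, 70001),
               end = c(12000, 42000, 72000), strand = "+",
               gene_id = c("g1", "g2", "g3")), c(chrT = 1e5))
  sites <- GRanges("chrT", IRanges(c(10001, 40001, 70050), width = 100))
  seqlevels(sites) <- "chrT"; seqlengths(sites) <- 1e5
  expect_equal(defineDirectTargets(sites, c("g2", "g3", "g4"), ann),
               c("g2", "g3"))
  expect_length(defineDirectTargets(sites, c("gX"), ann), 0)
})

test_that("two-factor target partitions report the three-way split", {
  a <- paste0("a", 1:1110)
  b <- c(paste0("a", 1:305), paste0("b", 1:376))  # 305 shared of 681
  p <- targetPartition(a, b)
  expect_equal(p$a_only, 805)
  expect_equal(p$b_only, 376)
  expect_equal(p$common, 305)
  expect_equal(p$union, 1486)
})
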