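ernaToyAnn <- function() {
  readGeneAnnotation(
    system.file("extdata", "erna_toy_genes.gtf", package = "broadAcetyl"),
    system.file("extdata", "erna_toy_chrom_sizes.tsv", package = "broadAcetyl"))
}

test_that("the packaged five-read toy leaves exactly the three survivors", {
  ann <- ernaToyAnn()
  reads <- readBedReads(
    system.file("extdata", "erna_toy_reads.bed", package = "broadAcetyl"),
    chromSizes(ann))
  expect_length(reads, 5)
  kept <- filterReadsForErna(reads, ann)
  expect_length(kept, 3)
  # the split read and the antisense genic read are gone
  expect_false(any(kept$split_mapped))
  expect_false(any(start(kept) == 12001 & strand(kept) == "-"))
  # the sense read inside the gene region survives (candidate antisense
  # transcription under the dUTP convention)
  expect_true(any(start(kept) == 12001 & strand(kept) == "+"))
})

test_that("strand conventions of the eRNA filter are explicit and invertible", {
  ann <- ernaToyAnn()  # one + strand protein_coding gene at [10001, 15000]
  sense <- grReads(12001, strand = "+", chrom_len = 5e4)
  anti <- grReads(12001, strand = "-", chrom_len = 5e4)
  expect_length(filterReadsForErna(sense, ann), 1)
  expect_length(filterReadsForErna(anti, ann), 0)
  # inverse convention flips the rule
  expect_length(filterReadsForErna(sense, ann, convention = "inverse"), 0)
  expect_length(filterReadsForErna(anti, ann, convention = "inverse"), 1)
  # the extension matters: an antisense read 9 kb past the TTS is removed
  far <- grReads(24001, strand = "-", chrom_len = 5e4)
  expect_length(filterReadsForErna(far, ann), 0)
  beyond <- grReads(25500, strand = "-", chrom_len = 5e4)
  expect_length(filterReadsForErna(beyond, ann), 1)
  # unstranded reads are rejected
  un <- grReads(12001, strand = "*", chrom_len = 5e4)
  expect_error(filterReadsForErna(un, ann), "stranded")
  # non-excluded biotypes do not trigger removal
  expect_length(filterReadsForErna(anti, ann,
                                   excluded_biotypes = "rRNA"), 1)
})

test_that("eRNA filtering is idempotent", {
  ann <- ernaToyAnn()
  set.seed(23)
  reads <- grReads(sample(45000, 400, TRUE), chrom_len = 5e4,
                   strand = sample(c("+", "-"), 400, TRUE),
                   split_mapped = runif(400) < 0.1)
  once <- filterReadsForErna(reads, ann)
  twice <- filterReadsForErna(once, ann)
  expect_identical(once, twice)
})

test_that("transcribed-region detection is stranded and recovers blocks", {
  set.seed(24)
  block <- grReads(sample(20001:21950, 200, TRUE), strand = "+",
                   chrom_len = 5e4)
  noise <- grReads(sample(45000, 40, TRUE), chrom_len = 5e4,
                   strand = sample(c("+", "-"), 40, TRUE))
  regions <- detectTranscribedRegions(c(block, noise))
  plus <- regions[strand(regions) == "+"]
  expect_length(plus, 1)
  block_iv <- GRanges("chrT", IRanges(20001, 22000))
  seqlevels(block_iv) <- "chrT"; seqlengths(block_iv) <- 5e4
  covered <- sum(width(GenomicRanges::intersect(granges(plus), block_iv,
                                                ignore.strand = TRUE)))
  expect_gte(covered / 2000, 0.9)

  # identical fragment sets on both strands give identical regions per
  # strand (full-length fragments, so 3'-directed extension is a no-op)
  set.seed(26)
  frag <- grReads(sample(20001:21800, 200, TRUE), width = 200, strand = "+",
                  chrom_len = 5e4)
  mirror <- c(frag, `strand<-`(frag, value = "-"))
  reg2 <- detectTranscribedRegions(mirror)
  expect_equal(ranges(reg2[strand(reg2) == "+"]),
               ranges(reg2[strand(reg2) == "-"]))
})

test_that("eRNA designation requires both acetylation marks at >= 50%", {
  ann <- ernaToyAnn()
  region <- GRanges("chrT", IRanges(30001, 31000), strand = "+")
  seqlevels(region) <- "chrT"; seqlengths(region) <- 5e4
  k9_full <- GRanges("chrT", IRanges(29001, 32000))
  k27_full <- GRanges("chrT", IRanges(29001, 32000))
  both <- designateErnas(region, k9_full, k27_full, ann)
  expect_true(both$is_erna)
  expect_equal(both$h3k9ac_coverage, 1)

  k9_06 <- GRanges("chrT", IRanges(30001, 30600))   # 0.6 coverage
  k27_03 <- GRanges("chrT", IRanges(30001, 30300))  # 0.3 coverage
  conj <- designateErnas(region, k9_06, k27_03, ann)
  expect_false(conj$is_erna)
  expect_equal(conj$h3k9ac_coverage, 0.6)
  expect_equal(conj$h3k27ac_coverage, 0.3)
  # exactly 50% counts as covered (bedtools -f 0.5 inclusive semantics)
  k_05 <- GRanges("chrT", IRanges(30001, 30500))
  expect_true(designateErnas(region, k_05, k_05, ann)$is_erna)
  # candidates annotate to the nearest gene
  expect_equal(both$gene_id, "toygene1")
})

test_that("the deregulation report pairs eRNA and mRNA fold changes", {
  ann <- ernaToyAnn()
  cand <- GRanges("chrT", IRanges(c(30001, 60001), width = c(25096, 2000)),
                  strand = "+")
  seqlevels(cand) <- "chrT"; seqlengths(cand) <- 1e5
  cand$gene_id <- c("toygene1", "toygene1")
  # planted eRNA counts: locus 1 drops ~log2FC -2; locus 2 unchanged
  mk_rep <- function(n1, n2) c(
    grReads(sample(30001:54800, n1, TRUE), strand = "+", chrom_len = 1e5),
    grReads(sample(60001:61800, n2, TRUE), strand = "+", chrom_len = 1e5))
  set.seed(25)
  reads <- list(wt1 = mk_rep(400, 100), wt2 = mk_rep(410, 105),
                wt3 = mk_rep(395, 98), wt4 = mk_rep(405, 101),
                m1 = mk_rep(100, 100), m2 = mk_rep(102, 99),
                m3 = mk_rep(98, 102))
  mrna <- data.frame(gene_id = "toygene1", log2fc = -1.5, adj_p = 1e-6)
  rep_tab <- ernaDeregulationReport(cand, reads, rep(c("WT", "SCA7"), c(4, 3)),
                                    mrna)
  expect_equal(rep_tab$erna_length[1], 25096)
  expect_true(rep_tab$concordant_down[1])
  expect_false(rep_tab$concordant_down[2])
  expect_lt(abs(rep_tab$log2fc[1] + 2), 0.5)
  # a candidate with no counts anywhere is flagged
  empty <- GRanges("chrT", IRanges(90001, 90500), strand = "+")
  seqlevels(empty) <- "chrT"; seqlengths(empty) <- 1e5
  empty$gene_id <- "toygene1"
  rep2 <- ernaDeregulationReport(c(cand, empty), reads,
                                 rep(c("WT", "SCA7"), c(4, 3)), mrna)
  expect_true(rep2$low_count[3])
  expect_false(rep2$concordant_down[3])
})

test_that("designated eRNAs never sit on removed-strand gene signal", {
  cfg <- smallSimConfig()
  sim <- simulateGenome(cfg)
  rna <- simulateRnaReads(sim$truth, "WT", cfg)
  filt <- filterReadsForErna(do.call(c, rna$reads), sim$annotation)
  regions <- detectTranscribedRegions(filt)
  g <- genes(sim$annotation)
  ext <- extendGeneRegion(g)
  hits <- findOverlaps(regions, ext, ignore.strand = TRUE)
  opp <- as.character(strand(regions))[queryHits(hits)] !=
    as.character(strand(ext))[subjectHits(hits)]
  expect_false(any(opp))
  # every planted eRNA locus is detected and designated at default depth
  k9 <- callIslands(simulateChipReads(sim$truth, "H3K9ac", "WT", cfg),
                    simulateChipReads(sim$truth, "input", "WT", cfg))
  k27 <- callIslands(simulateChipReads(sim$truth, "H3K27ac", "WT", cfg),
                     simulateChipReads(sim$truth, "input", "WT", cfg))
  cand <- designateErnas(regions, k9, k27, sim$annotation)
  ern <- cand[cand$is_erna]
  recovered <- overlapsAny(sim$truth$erna, ern, ignore.strand = FALSE)
  expect_gte(mean(recovered), 0.9)
})
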