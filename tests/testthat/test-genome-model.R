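writeToyGtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

test_that("GTF parsing applies coordinate and strand conventions", {
  gtf <- writeToyGtf(c(
    'chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    'chr1\ttoy\ttranscript\t1001\t1900\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\ttoy\texon\t1001\t1900\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\ttoy\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\texon\t1001\t1750\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\texon\t1251\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
    'chr1\ttoy\tgene\t3001\t4000\t.\t-\t.\tgene_id "gB"; gene_biotype "lincRNA";',
    'chr1\ttoy\ttranscript\t3001\t4000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";',
    'chr1\ttoy\texon\t3001\t4000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";'
  ))
  ann <- readGeneAnnotation(gtf, c(chr1 = 10000))
  g <- genes(ann)
  a <- g[g$gene_id == "gA"]
  b <- g[g$gene_id == "gB"]
  # 1-based 1001..2000 is the 0-based half-open interval [1000, 2000)
  expect_equal(start(a), 1001)
  expect_equal(end(a), 2000)
  expect_equal(a$tss, 1001)          # 0-based TSS 1000
  expect_equal(a$tts, 2000)
  # minus-strand gene: TSS is the 3'-coordinate end of the span
  expect_equal(b$tss, 4000)
  expect_equal(b$tts, 3001)
  # transcript exon sums 900 and 1500 -> median 1200 (1.2 kb)
  expect_equal(a$median_tx_len, 1200)
  expect_equal(a$biotype, "protein_coding")
  expect_equal(b$biotype, "lincRNA")
})

test_that("malformed GTF lines and orphan genes are reported", {
  bad <- writeToyGtf(c(
    'chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    "chr1\tonly\tfour\tfields"
  ))
  expect_error(readGeneAnnotation(bad, c(chr1 = 10000)), "line 2")

  orphan <- writeToyGtf(c(
    'chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\ttoy\tgene\t5001\t6000\t.\t+\t.\tgene_id "gB";',
    'chr1\ttoy\ttranscript\t5001\t6000\t.\t+\t.\tgene_id "gB"; transcript_id "gB.t1";',
    'chr1\ttoy\texon\t5001\t6000\t.\t+\t.\tgene_id "gB"; transcript_id "gB.t1";'
  ))
  expect_warning(ann <- readGeneAnnotation(orphan, c(chr1 = 10000)),
                 "without transcripts")
  g <- genes(ann)
  expect_setequal(g$gene_id, c("gA", "gB"))
  expect_equal(g$median_tx_len[g$gene_id == "gA"], 1000)  # gene span fallback
})

test_that("annotation round-trips through BED with identical intervals", {
  ann <- toyAnnotation(
    data.frame(chrom = "chrT", start = c(2001, 5001), end = c(3000, 7000),
               strand = c("+", "-"), gene_id = c("g1", "g2")),
    c(chrT = 1e5))
  path <- tempfile(fileext = ".bed")
  writeGenesBed(ann, path)
  back <- rtracklayer::import(path, format = "bed")
  expect_equal(start(back), start(genes(ann)))
  expect_equal(end(back), end(genes(ann)))
  expect_equal(as.character(strand(back)), as.character(strand(genes(ann))))
  expect_equal(back$name, genes(ann)$gene_id)
})

test_that("intergenic regions are the gene-span complement", {
  ann1 <- toyAnnotation(
    data.frame(chrom = "c1", start = 2001, end = 5000, strand = "+",
               gene_id = "g1"), c(c1 = 10000))
  ig <- deriveIntergenicRegions(ann1)
  expect_equal(start(ig), c(1, 5001))
  expect_equal(end(ig), c(2000, 10000))

  ann2 <- toyAnnotation(
    data.frame(chrom = "c1", start = c(1001, 2001), end = c(3000, 4000),
               strand = "+", gene_id = c("g1", "g2")), c(c1 = 6000))
  ig2 <- deriveIntergenicRegions(ann2)
  expect_equal(start(ig2), c(1, 4001))
  expect_equal(end(ig2), c(1000, 6000))

  ann3 <- toyAnnotation(
    data.frame(chrom = "c1", start = 1, end = 6000, strand = "+",
               gene_id = "g1"), c(c1 = 6000))
  expect_length(deriveIntergenicRegions(ann3), 0)
})

test_that("gene spans and intergenic regions partition each chromosome", {
  set.seed(42)
  sim <- simulateGenome(smallSimConfig())
  ig <- deriveIntergenicRegions(sim$annotation, min_length = 1)
  span <- reduce(granges(genes(sim$annotation)), ignore.strand = TRUE)
  total <- sum(width(ig)) + sum(width(span))
  expect_equal(total, sum(as.numeric(chromSizes(sim$annotation))))
  expect_false(any(overlapsAny(ig, span)))
})

test_that("read extension is 3'-directed, clipped, and never shrinks", {
  r <- grReads(101, width = 50, strand = "+", chrom_len = 1000)
  e <- extendReads(r)
  expect_equal(start(e), 101)
  expect_equal(end(e), 300)           # 0-based [100, 300)
  rm <- grReads(101, width = 50, strand = "-", chrom_len = 1000)
  em <- extendReads(rm)
  expect_equal(start(em), 1)          # clipped at the chromosome start
  expect_equal(end(em), 150)
  long <- grReads(101, width = 250, strand = "+", chrom_len = 1000)
  expect_equal(width(extendReads(long)), 250)  # never shrunk

  set.seed(1)
  rnd <- grReads(sample(900, 200, TRUE), width = 50,
                 strand = sample(c("+", "-"), 200, TRUE), chrom_len = 1000)
  ext <- extendReads(rnd)
  expect_identical(as.character(strand(ext)), as.character(strand(rnd)))
  expect_true(all(start(ext) >= 1 & end(ext) <= 1000))
})

test_that("gene regions extend strand-aware and clip at boundaries", {
  ann <- toyAnnotation(
    data.frame(chrom = "c1", start = 10001, end = 20000,
               strand = c("+"), gene_id = "g1"), c(c1 = 40000))
  ext <- extendGeneRegion(genes(ann))
  expect_equal(start(ext), 7001)      # 0-based [7000, 30000)
  expect_equal(end(ext), 30000)

  annm <- toyAnnotation(
    data.frame(chrom = "c1", start = 10001, end = 20000,
               strand = "-", gene_id = "g1"), c(c1 = 40000))
  extm <- extendGeneRegion(genes(annm))
  expect_equal(start(extm), 1)        # 10000 downstream clips to the start
  expect_equal(end(extm), 23000)

  same <- extendGeneRegion(genes(ann), upstream = 0, downstream = 0)
  expect_equal(ranges(same), ranges(genes(ann)))
})

test_that("nearest-TSS annotation uses midpoints, signed distance, tie-break", {
  ann <- toyAnnotation(
    data.frame(chrom = "c1", start = c(4001, 9001), end = c(6000, 9500),
               strand = "+", gene_id = c("gNear", "gFar")),
    c(c1 = 20000, c2 = 20000))
  # interval 1-based [4001,6001]: midpoint 5001, TSSs at 4001 and 9001
  iv <- GRanges("c1", IRanges(4001, 6001))
  res <- annotateToNearestTss(iv, ann)
  expect_equal(res$gene_id, "gNear")
  expect_equal(res$distance, 1000)

  # upstream of a plus-strand TSS: negative distance
  up <- GRanges("c1", IRanges(3001, 3801))  # midpoint 3401
  expect_equal(annotateToNearestTss(up, ann)$distance, -600)

  # minus-strand gene flips the sign
  annm <- toyAnnotation(
    data.frame(chrom = "c1", start = 4001, end = 6000, strand = "-",
               gene_id = "gM"), c(c1 = 20000))
  dn <- GRanges("c1", IRanges(5001, 5001))  # midpoint 5001, TSS 6000
  expect_equal(annotateToNearestTss(dn, annm)$distance, 999)

  # exact tie resolved by (chrom, tss, gene_id) order
  ann2 <- toyAnnotation(
    data.frame(chrom = "c1", start = c(1001, 9001), end = c(2000, 9900),
               strand = "+", gene_id = c("gB", "gA")), c(c1 = 20000))
  mid <- GRanges("c1", IRanges(5001, 5001))  # equidistant 4000 from both
  expect_equal(annotateToNearestTss(mid, ann2)$gene_id, "gB")

  # chromosome without genes
  nog <- GRanges("c2", IRanges(100, 200))
  res2 <- annotateToNearestTss(nog, ann)
  expect_true(is.na(res2$gene_id))
  expect_equal(res2$distance, Inf)
})

test_that("the SAM adapter maps primary alignments and split flags", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:50000",
    "r1\t0\tchrT\t1001\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchrT\t2001\t60\t25M100N25M\t*\t0\t0\t*\t*",
    "r3\t2048\tchrT\t3001\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t256\tchrT\t4001\t60\t50M\t*\t0\t0\t*\t*"
  ), sam)
  reads <- readSamReads(sam, c(chrT = 50000))
  expect_length(reads, 3)            # the secondary alignment is dropped
  r1 <- reads[start(reads) == 1001]
  expect_equal(width(r1), 50)
  expect_false(r1$split_mapped)
  r2 <- reads[start(reads) == 2001]  # N operation spans the reference
  expect_equal(width(r2), 150)
  expect_equal(as.character(strand(r2)), "-")
  expect_true(r2$split_mapped)
  expect_true(reads[start(reads) == 3001]$split_mapped)  # supplementary
})
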