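#' Read an Ensembl-dialect GTF into a GenomeAnnotation
#'
#' Parses gene, transcript and exon features. Transcript lengths are the sum
#' of exon widths per transcript; each gene's `median_tx_len` is the median of
#' its transcript lengths. The TSS is the strand-aware 5' end of the gene span
#' and the TTS its 3' end (one TSS per gene, not per transcript). Genes without
#' any transcript are retained with the gene span as their single transcript,
#' with a warning.
#'
#' @param gtf_path Path to a GTF file (gzip allowed).
#' @param chrom_sizes Named vector of chromosome lengths, or a path to a
#'   two-column TSV (chrom, length). Required so coordinates can be validated
#'   and reads clipped.
#' @return A [GenomeAnnotation].
#' @export
readGeneAnnotation <- function(gtf_path, chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- readChromSizes(chrom_sizes)
  .checkGtfLines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  if (is.null(gr$type) || !any(gr$type == "gene"))
    stop("GTF contains no gene features: ", gtf_path)
  g <- gr[gr$type == "gene"]
  ex <- gr[gr$type == "exon"]
  biotype <- if (!is.null(g$gene_biotype)) g$gene_biotype else
    rep("protein_coding", length(g))
  biotype[is.na(biotype)] <- "protein_coding"

  med_len <- setNames(as.numeric(width(g)), g$gene_id)
  if (length(ex)) {
    tx_len <- tapply(width(ex), ex$transcript_id, sum)
    tx_gene <- tapply(as.character(ex$gene_id), ex$transcript_id,
                      function(x) x[1L])
    by_gene <- tapply(as.numeric(tx_len), tx_gene[names(tx_len)], median)
    med_len[names(by_gene)] <- by_gene
  }
  orphan <- setdiff(g$gene_id, unique(ex$gene_id))
  if (length(ex) && length(orphan))
    warning(length(orphan),
            " gene(s) without transcripts; gene span used as single transcript")

  genes <- granges(g)
  mcols(genes) <- DataFrame(gene_id = g$gene_id, biotype = biotype,
                            median_tx_len = unname(med_len[g$gene_id]))
  exons <- granges(ex)
  if (length(ex)) mcols(exons) <- DataFrame(gene_id = ex$gene_id)
  GenomeAnnotation(genes, chrom_sizes = chrom_sizes, exons = exons)
}

# Light structural scan so a malformed line is reported by number.
.checkGtfLines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield < 8L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], " in ", path,
         " (expected >= 8 tab-separated fields)")
  invisible(TRUE)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path Path to a headerless TSV: chromosome name, length in bp.
#' @return Named numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  setNames(tab$length, tab$chrom)
}

#' Read aligned reads from a BED6 file
#'
#' Each record becomes one aligned read (GRanges, 1-based closed internally;
#' the BED offset conversion is handled by rtracklayer). A name field equal to
#' `"split"` marks a split-mapped read (the convention used by
#' [writeBedReads()]); any other name gives `split_mapped = FALSE`.
#'
#' @param path BED6 file path.
#' @param chrom_sizes Optional named lengths to attach as seqinfo.
#' @return GRanges with a logical `split_mapped` metadata column.
#' @export
readBedReads <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  split <- if (!is.null(gr$name)) !is.na(gr$name) & gr$name == "split" else
    rep(FALSE, length(gr))
  mcols(gr) <- DataFrame(split_mapped = split)
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- union(names(chrom_sizes), seqlevels(gr))
    seqlengths(gr) <- as.integer(chrom_sizes[seqlevels(gr)])
  }
  gr
}

#' Write aligned reads to BED6
#'
#' Split-mapped reads are written with name `"split"`, others with `"read"`,
#' so [readBedReads()] round-trips the flag.
#'
#' @param reads GRanges of reads (optionally with `split_mapped`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBedReads <- function(reads, path) {
  out <- granges(reads)
  split <- if (!is.null(reads$split_mapped)) reads$split_mapped else
    rep(FALSE, length(reads))
  out$name <- ifelse(split, "split", "read")
  out$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read aligned reads from SAM/BAM (optional adapter)
#'
#' Maps each primary alignment to one read. `split_mapped` is TRUE when the
#' CIGAR contains an N operation or the alignment is flagged supplementary.
#' Requires the Rsamtools package.
#'
#' @param path SAM or BAM path (SAM files are read directly).
#' @param chrom_sizes Optional named lengths to attach as seqinfo.
#' @return GRanges with a `split_mapped` column.
#' @export
readSamReads <- function(path, chrom_sizes = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("readSamReads requires the Rsamtools package")
  bam <- path
  tmp <- NULL
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, sub("\\.bam$", "", tmp),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "strand", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  if (!is.null(tmp)) unlink(c(bam, paste0(bam, ".bai")))
  wid <- .cigarRefWidth(res$cigar)
  gr <- GRanges(res$rname, IRanges(res$pos, width = wid), strand = res$strand)
  gr$split_mapped <- grepl("N", res$cigar, fixed = TRUE) |
    bitwAnd(res$flag, 2048L) > 0L
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- union(names(chrom_sizes), seqlevels(gr))
    seqlengths(gr) <- as.integer(chrom_sizes[seqlevels(gr)])
  }
  gr
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
.cigarRefWidth <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a GenomeAnnotation's gene spans to BED6
#'
#' @param annotation A [GenomeAnnotation].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenesBed <- function(annotation, path) {
  g <- genes(annotation)
  out <- granges(g)
  out$name <- g$gene_id
  out$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}
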