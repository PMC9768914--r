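#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<- resize promoters reduce gaps findOverlaps countOverlaps
#'   pintersect distanceToNearest tileGenome mcols mcols<- trim sort
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo keepSeqlevels seqnames
#' @importFrom stats median kmeans p.adjust phyper ppois quantile rbinom
#'   rnbinom rpois runif sd setNames t.test wilcox.test rnorm complete.cases
#'   optimize dist
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeAnnotation: gene models plus chromosome sizes
#'
#' Central annotation container. Gene models are held as a [GenomicRanges::GRanges]
#' spanning each gene (1-based, closed), with metadata columns:
#' \describe{
#'   \item{gene_id}{unique gene identifier}
#'   \item{biotype}{Ensembl biotype string}
#'   \item{tss, tts}{strand-aware 1-based positions of the 5' and 3' gene ends}
#'   \item{median_tx_len}{median across transcripts of summed exon lengths (bp)}
#' }
#' Chromosome sizes live in the object's [GenomeInfoDb::Seqinfo]; exon
#' intervals (used for genic subfeature classification and read placement) are
#' kept in a separate slot and may be empty.
#'
#' @slot genes GRanges of gene spans with the metadata columns above.
#' @slot exons GRanges of exon intervals with a `gene_id` metadata column
#'   (possibly empty).
#'
#' @seealso [readGeneAnnotation()], [genes()], [chromSizes()]
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", exons = "GRanges")
)

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (length(g)) {
    if (is.null(g$gene_id)) msg <- c(msg, "genes must carry a gene_id column")
    else if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_ids must be unique")
    sl <- seqlengths(g)
    if (any(is.na(sl))) msg <- c(msg, "all chromosomes must have a known length")
    else if (any(end(g) > sl[as.character(seqnames(g))]))
      msg <- c(msg, "gene coordinates exceed chromosome lengths")
    if (!is.null(g$median_tx_len) && any(g$median_tx_len <= 0))
      msg <- c(msg, "transcript lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for GenomeAnnotation
#'
#' `genes()` returns the gene-span GRanges, `exonRegions()` the exon GRanges,
#' and `chromSizes()` a named integer vector of chromosome lengths.
#'
#' @param x A `GenomeAnnotation`.
#' @return `genes()` and `exonRegions()` return a GRanges; `chromSizes()` a
#'   named numeric vector.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname genes
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname genes
#' @export
setGeneric("exonRegions", function(x) standardGeneric("exonRegions"))

#' @rdname genes
#' @export
setMethod("exonRegions", "GenomeAnnotation", function(x) x@exons)

#' @rdname genes
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname genes
#' @export
setMethod("chromSizes", "GenomeAnnotation", function(x) seqlengths(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
  g <- object@genes
  cat("GenomeAnnotation with", length(g), "genes on",
      length(seqlengths(g)), "chromosomes\n")
  if (length(g)) {
    bt <- table(g$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = "=", collapse = ", "), "\n")
    cat("  genome size:", sum(as.numeric(seqlengths(g))), "bp\n")
  }
})

#' Construct a GenomeAnnotation from components
#'
#' @param genes GRanges of gene spans carrying `gene_id`, `biotype` (optional,
#'   defaults to `protein_coding`), and optionally `median_tx_len` (defaults to
#'   the gene width).
#' @param chrom_sizes Named vector of chromosome lengths. If missing, taken
#'   from `seqlengths(genes)`.
#' @param exons Optional GRanges of exons with a `gene_id` column.
#' @return A validated `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(genes, chrom_sizes = NULL, exons = NULL) {
  if (!is.null(chrom_sizes)) {
    seqlevels(genes) <- names(chrom_sizes)
    seqlengths(genes) <- as.integer(chrom_sizes)
  }
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(genes$median_tx_len)) genes$median_tx_len <- width(genes)
  plus <- as.logical(strand(genes) == "+")
  genes$tss <- ifelse(plus, start(genes), end(genes))
  genes$tts <- ifelse(plus, end(genes), start(genes))
  if (is.null(exons)) {
    exons <- GRanges(seqinfo = seqinfo(genes))
  } else {
    seqlevels(exons) <- seqlevels(genes)
    seqlengths(exons) <- seqlengths(genes)
  }
  new("GenomeAnnotation", genes = sort(genes, ignore.strand = TRUE),
      exons = sort(exons, ignore.strand = TRUE))
}
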