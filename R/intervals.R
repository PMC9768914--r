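#' Derive intergenic regions from an annotation
#'
#' Complement of the union of all gene spans per chromosome, unstranded,
#' sorted and non-overlapping. Together with the gene-span union the returned
#' regions partition each chromosome (before the minimum-length filter, see
#' `min_length`). These regions are the background used by
#' [intergenicNormalizationFactor()].
#'
#' @param annotation A [GenomeAnnotation].
#' @param min_length Regions shorter than this are discarded (default 1000 bp,
#'   avoiding degenerate normalization regions).
#' @param gene_buffer Trim this many bp from each end of every intergenic
#'   region (default 0, the plain gene-span complement). A buffer keeps
#'   promoter-proximal acetylation that straddles gene boundaries out of the
#'   background used for between-genotype normalization.
#' @return GRanges of intergenic regions.
#' @export
deriveIntergenicRegions <- function(annotation, min_length = 1000,
                                    gene_buffer = 0) {
  g <- genes(annotation)
  if (!length(g)) stop("annotation contains no genes")
  sl <- seqlengths(g)
  if (any(is.na(sl)))
    stop("chromosome length missing for: ",
         paste(names(sl)[is.na(sl)], collapse = ", "))
  span <- reduce(granges(g), ignore.strand = TRUE)
  inter <- gaps(span)
  inter <- inter[strand(inter) == "*"]
  if (gene_buffer > 0) {
    keep <- width(inter) > 2 * gene_buffer
    inter <- inter[keep]
    start(inter) <- start(inter) + gene_buffer
    end(inter) <- end(inter) - gene_buffer
  }
  sort(inter[width(inter) >= min_length])
}

#' Extend reads to a fixed fragment length in the read direction
#'
#' Each read is extended from its 5' end to `target_length` bp in the
#' direction of the read (3' extension), the standard fragment-length
#' correction applied before density counting. Reads already at least
#' `target_length` long are left unchanged (evidence is never shrunk).
#' Results are clipped to chromosome bounds.
#'
#' @param reads GRanges of aligned reads with strand and seqlengths.
#' @param target_length Target fragment length in bp (default 200).
#' @return GRanges of extended reads (strand preserved).
#' @export
extendReads <- function(reads, target_length = 200) {
  short <- width(reads) < target_length
  out <- reads
  if (any(short))
    suppressWarnings(
      out[short] <- resize(reads[short], target_length, fix = "start"))
  trim(out)
}

#' Extend a gene region upstream of the TSS and downstream of the TTS
#'
#' Strand-aware extension of gene spans, the exclusion geometry of the eRNA
#' read filter (signal from polymerase read-through extends well past the
#' annotated 3' end).
#'
#' @param genes GRanges of gene spans (stranded, with seqlengths).
#' @param upstream Extension beyond the TSS (default 3000 bp).
#' @param downstream Extension beyond the TTS (default 10000 bp).
#' @return GRanges of extended regions, clipped to chromosome bounds.
#' @export
extendGeneRegion <- function(genes, upstream = 3000, downstream = 10000) {
  plus <- as.logical(strand(genes) != "-")
  sl <- seqlengths(genes)
  s <- pmax(1, start(genes) - ifelse(plus, upstream, downstream))
  e <- end(genes) + ifelse(plus, downstream, upstream)
  if (!any(is.na(sl))) e <- pmin(e, sl[as.character(seqnames(genes))])
  out <- GRanges(seqnames(genes), IRanges(s, e), strand = strand(genes),
                 seqinfo = seqinfo(genes))
  mcols(out) <- mcols(genes)
  out
}

#' Annotate intervals to the nearest gene TSS
#'
#' Each interval is assigned the gene whose TSS is nearest to the interval
#' midpoint. Distance is signed in the gene's orientation: negative means the
#' midpoint lies upstream of the TSS. Exact ties are broken deterministically
#' by (chromosome, TSS, gene_id) sort order. Intervals on chromosomes without
#' genes get `NA` gene and infinite distance.
#'
#' @param intervals GRanges to annotate.
#' @param annotation A [GenomeAnnotation].
#' @return A data.frame with columns `gene_id` and `distance` aligned to
#'   `intervals` (the same columns are also attached to a copy of the input,
#'   returned as the `granges` attribute-free data.frame).
#' @export
annotateToNearestTss <- function(intervals, annotation) {
  g <- genes(annotation)
  ord <- order(as.character(seqnames(g)), g$tss, g$gene_id)
  g <- g[ord]
  mid <- floor((start(intervals) + end(intervals)) / 2)
  gene_id <- rep(NA_character_, length(intervals))
  distance <- rep(Inf, length(intervals))
  chroms <- as.character(seqnames(intervals))
  gchrom <- as.character(seqnames(g))
  for (ch in unique(chroms)) {
    gi <- which(gchrom == ch)
    if (!length(gi)) next
    qi <- which(chroms == ch)
    tss <- g$tss[gi]
    # nearest TSS by absolute distance; first match in sorted order wins ties
    d <- abs(outer(mid[qi], tss, "-"))
    best <- max.col(-d, ties.method = "first")
    sel <- gi[best]
    gene_id[qi] <- g$gene_id[sel]
    signed <- mid[qi] - g$tss[sel]
    neg <- as.logical(strand(g)[sel] == "-")
    distance[qi] <- ifelse(neg, -signed, signed)
  }
  data.frame(gene_id = gene_id, distance = distance,
             stringsAsFactors = FALSE)
}

#' Fraction of an interval covered by a set of intervals
#'
#' For each interval in `a`, the fraction of its length covered by the union
#' of `b_set` (bedtools `intersect -f` semantics). The coverage predicate used
#' throughout the package is `fraction >= threshold` (bedtools' inclusive
#' rule), with the default threshold 0.5.
#'
#' @param a GRanges of query intervals.
#' @param b_set GRanges whose union covers the queries.
#' @return Numeric vector in `[0, 1]`, one value per query.
#' @export
coverageOverlapFraction <- function(a, b_set) {
  if (!length(a)) return(numeric(0))
  if (!length(b_set)) return(rep(0, length(a)))
  b <- reduce(granges(b_set), ignore.strand = TRUE)
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  ov <- pintersect(granges(a)[queryHits(hits)], b[subjectHits(hits)],
                   ignore.strand = TRUE)
  covered <- rep(0, length(a))
  if (length(hits)) {
    w <- tapply(width(ov), queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  covered / width(a)
}

# 1-bp midpoints of the 200-bp-extended fragments (strand preserved).
.fragmentMidpoints <- function(reads, extend = 200) {
  fr <- extendReads(reads, extend)
  GRanges(seqnames(fr), IRanges(floor((start(fr) + end(fr)) / 2), width = 1),
          strand = strand(fr), seqinfo = seqinfo(fr))
}

# Strand-aware promoter window around the TSS: [TSS - upstream, TSS +
# downstream) in 0-based half-open terms; GenomicRanges::promoters matches
# this exactly (width = upstream + downstream).
.tssWindow <- function(genes, upstream = 300, downstream = 300) {
  trim(suppressWarnings(promoters(genes, upstream = upstream,
                                  downstream = downstream)))
}

# Strand-aware gene-body windows. from5p/from3p are offsets interior to the
# gene's 5'/3' ends in bp (0-based): body = [TSS + from5p, TTS - from3p).
# Genes too short for the requested window are dropped.
.geneBody <- function(genes, from5p = 0, from3p = 0) {
  plus <- as.logical(strand(genes) != "-")
  s <- ifelse(plus, start(genes) + from5p, start(genes) + from3p)
  e <- ifelse(plus, end(genes) - from3p, end(genes) - from5p)
  ok <- s <= e
  out <- GRanges(seqnames(genes)[ok], IRanges(s[ok], e[ok]),
                 strand = strand(genes)[ok], seqinfo = seqinfo(genes))
  mcols(out) <- mcols(genes)[ok, , drop = FALSE]
  out
}
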