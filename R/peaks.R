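#' Poisson-window island caller
#'
#' Stand-in enriched-region detector parametrized like SICER: the genome is
#' tiled into `window`-bp bins, each bin's 200-bp-extended read count is
#' tested against a Poisson upper tail, and eligible bins separated by at
#' most `gap` bp are merged into one island. The Poisson rate per bin is the
#' library-scaled control count floored at the control's chromosome-wide
#' mean; with no control the ChIP library's own chromosome-wide background
#' supplies the rate (with a warning, or silently for
#' `background = "uniform"`, the analogue of detection with a uniform
#' genome-wide background). Identical read intervals are collapsed before
#' counting (redundancy threshold 1) unless `collapse_duplicates = FALSE`.
#'
#' @param chip_reads GRanges of ChIP reads (with seqlengths).
#' @param control_reads GRanges of control/input reads, or NULL.
#' @param window Bin size in bp (default 200).
#' @param gap Maximum merged gap in bp (default 600).
#' @param p_threshold Poisson upper-tail significance per bin (default 1e-2).
#' @param background `"control"` (default) or `"uniform"` (ignore control,
#'   chromosome-wide ChIP background).
#' @param collapse_duplicates Collapse identical read intervals before
#'   counting (default TRUE).
#' @return GRanges of islands with metadata columns `score` (total extended
#'   reads in the island), `mark` (NA, fill downstream) and
#'   `source = "island_caller"`.
#' @export
callIslands <- function(chip_reads, control_reads = NULL, window = 200,
                        gap = 600, p_threshold = 1e-2,
                        background = c("control", "uniform"),
                        collapse_duplicates = TRUE) {
  background <- match.arg(background)
  if (!length(chip_reads)) stop("empty ChIP library")
  sl <- seqlengths(chip_reads)
  if (any(is.na(sl))) stop("chip_reads must carry seqlengths")
  if (collapse_duplicates) chip_reads <- unique(granges(chip_reads))
  chip <- extendReads(chip_reads, 200)
  use_control <- background == "control" && length(control_reads) > 0
  if (background == "control" && !use_control && !is.null(control_reads))
    warning("control library empty; using chromosome-wide ChIP background")
  if (use_control && collapse_duplicates)
    control_reads <- unique(granges(control_reads))
  ctrl <- if (use_control) extendReads(control_reads, 200) else NULL

  tiles <- tileGenome(sl, tilewidth = window, cut.last.tile.in.chrom = TRUE)
  counts <- countOverlaps(tiles, chip, ignore.strand = TRUE)
  tchrom <- as.character(seqnames(tiles))
  if (use_control) {
    scale <- length(chip) / length(ctrl)
    cc <- countOverlaps(tiles, ctrl, ignore.strand = TRUE) * scale
    floor_by_chrom <- tapply(cc, tchrom, mean)
    lambda <- pmax(cc, floor_by_chrom[tchrom])
  } else {
    mean_by_chrom <- tapply(counts, tchrom, mean)
    lambda <- mean_by_chrom[tchrom]
  }
  eligible <- counts > 0 &
    ppois(counts - 1, lambda, lower.tail = FALSE) < p_threshold
  if (!any(eligible)) {
    out <- GRanges(seqinfo = seqinfo(tiles))
    out$score <- integer(0); out$mark <- character(0)
    out$source <- character(0)
    return(out)
  }
  islands <- reduce(tiles[eligible], min.gapwidth = gap + 1)
  islands$score <- countOverlaps(islands, chip, ignore.strand = TRUE)
  islands$mark <- NA_character_
  islands$source <- "island_caller"
  sort(islands)
}

#' Read externally called peaks from BED
#'
#' Drop-in alternative to [callIslands()]: accepts SICER/MACS output as BED,
#' with the name field taken as the mark and the score as the peak score.
#'
#' @param path BED file path.
#' @param chrom_sizes Optional named chromosome lengths.
#' @return GRanges with `score`, `mark`, `source = "external_bed"`.
#' @export
readPeaksBed <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- granges(gr)
  out$score <- if (!is.null(gr$score)) as.numeric(gr$score) else
    rep(NA_real_, length(gr))
  out$mark <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  out$source <- "external_bed"
  if (!is.null(chrom_sizes)) {
    seqlevels(out) <- union(names(chrom_sizes), seqlevels(out))
    seqlengths(out) <- as.integer(chrom_sizes[seqlevels(out)])
  }
  out
}

#' Per-gene peak broadness
#'
#' Peaks are annotated to the gene with the nearest TSS
#' ([annotateToNearestTss()]); a gene's broadness is the summed length of the
#' peaks annotated to it (per-peak lengths available via
#' `per_peak = TRUE`). Genes in `gene_set` without any annotated peak get
#' broadness 0 and `no_peak = TRUE`.
#'
#' @param peaks GRanges of peaks.
#' @param annotation A [GenomeAnnotation].
#' @param gene_set Character vector of gene ids to report (default: all).
#' @param per_peak If TRUE, return the per-peak table (peak interval, gene,
#'   length) instead of per-gene sums.
#' @return data.frame: `gene_id`, `broadness_bp`, `n_peaks`, `no_peak`.
#' @export
broadnessByGene <- function(peaks, annotation, gene_set = NULL,
                            per_peak = FALSE) {
  ann <- annotateToNearestTss(peaks, annotation)
  if (per_peak)
    return(data.frame(gene_id = ann$gene_id, length_bp = width(peaks),
                      distance = ann$distance, stringsAsFactors = FALSE))
  if (is.null(gene_set)) gene_set <- genes(annotation)$gene_id
  sums <- tapply(width(peaks), ann$gene_id, sum)
  counts <- table(ann$gene_id)
  broad <- as.numeric(sums[gene_set])
  npk <- as.integer(counts[gene_set])
  broad[is.na(broad)] <- 0
  npk[is.na(npk)] <- 0L
  data.frame(gene_id = gene_set, broadness_bp = broad, n_peaks = npk,
             no_peak = npk == 0L, stringsAsFactors = FALSE)
}

#' Genomic distribution of peaks across feature classes
#'
#' Assigns each peak by its midpoint with precedence promoter-TSS (-1 kb to
#' +100 bp of a TSS) > TTS (-100 bp to +1 kb of a TTS) > distal promoter
#' (-20 kb to -1 kb of a TSS) > exon > intron > intergenic, and reports the
#' percentage of peaks per class (summing to 100). With single-exon gene
#' models the genic subfeatures reduce to exon; UTRs require CDS annotation
#' and are folded into exon.
#'
#' @param peaks GRanges of peaks.
#' @param annotation A [GenomeAnnotation].
#' @return data.frame: `feature`, `n`, `percent`.
#' @export
genomicPeakDistribution <- function(peaks, annotation) {
  g <- genes(annotation)
  mid0 <- floor((start(peaks) + end(peaks)) / 2)
  mids <- GRanges(seqnames(peaks), IRanges(mid0, width = 1),
                  seqinfo = seqinfo(peaks))
  tss_pt <- .tssWindow(g, 0, 1)                       # 1-bp anchor at the TSS
  tts_pt <- GRanges(seqnames(g), IRanges(g$tts, width = 1), strand = strand(g),
                    seqinfo = seqinfo(g))
  prom <- trim(suppressWarnings(promoters(g, upstream = 1000,
                                          downstream = 100)))
  ttsw <- trim(suppressWarnings(promoters(tts_pt, upstream = 100,
                                          downstream = 1000)))
  distal <- trim(suppressWarnings(promoters(g, upstream = 20000,
                                            downstream = 0)))
  exons <- exonRegions(annotation)
  if (!length(exons)) exons <- granges(g)
  classes <- rep("intergenic", length(peaks))
  inside <- function(windows) overlapsAny(mids, windows, ignore.strand = TRUE)
  classes[inside(granges(g))] <- "intron"
  classes[classes == "intron" & inside(exons)] <- "exon"
  classes[inside(distal)] <- "distal_promoter"
  classes[inside(ttsw)] <- "tts"
  classes[inside(prom)] <- "promoter_tss"
  lev <- c("promoter_tss", "tts", "distal_promoter", "exon", "intron",
           "intergenic")
  n <- table(factor(classes, levels = lev))
  data.frame(feature = lev, n = as.integer(n),
             percent = 100 * as.integer(n) / max(1L, length(peaks)),
             stringsAsFactors = FALSE)
}
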