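#' Default biotype exclusion list for the eRNA read filter
#'
#' Coding genes and every pseudogene/structural-RNA class whose own
#' transcription must not masquerade as enhancer RNA.
#' @export
ernaExcludedBiotypes <- c(
  "IG_C_gene", "IG_C_pseudogene", "IG_D_gene", "IG_D_pseudogene",
  "IG_J_gene", "IG_LV_gene", "IG_pseudogene", "IG_V_gene",
  "IG_V_pseudogene", "Mt_rRNA", "Mt_tRNA", "polymorphic_pseudogene",
  "processed_pseudogene", "protein_coding", "pseudogene", "rRNA",
  "transcribed_processed_pseudogene", "transcribed_unitary_pseudogene",
  "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_J_pseudogene", "TR_V_gene",
  "unitary_pseudogene", "unprocessed_pseudogene")

#' Filter stranded RNA reads for eRNA detection
#'
#' Two rules, order-independent and idempotent:
#' 1. split-mapped reads are removed;
#' 2. reads overlapping (>= 1 bp) the extended region (3 kb upstream of the
#'    TSS to 10 kb downstream of the TTS) of an excluded-biotype gene are
#'    removed when the read's strand is OPPOSITE to the gene's strand.
#'
#' Under the dUTP protocol, sequenced reads map antisense to their transcript
#' of origin, so a gene's own mRNA reads carry the opposite strand and rule 2
#' removes exactly them; reads on the gene's strand (antisense transcription,
#' eRNA candidates) survive. The inverse reading of the strand rule is kept
#' behind `convention = "inverse"`.
#'
#' @param reads GRanges with strand and a `split_mapped` column.
#' @param annotation A [GenomeAnnotation].
#' @param excluded_biotypes Biotypes whose genes drive the removal (default
#'   [ernaExcludedBiotypes]).
#' @param upstream,downstream Gene extension in bp (defaults 3000 and 10000).
#' @param convention `"dutp"` (default, remove reads antisense to the gene)
#'   or `"inverse"` (remove reads on the gene's strand).
#' @return Filtered GRanges.
#' @export
filterReadsForErna <- function(reads, annotation,
                               excluded_biotypes = ernaExcludedBiotypes,
                               upstream = 3000, downstream = 10000,
                               convention = c("dutp", "inverse")) {
  convention <- match.arg(convention)
  if (any(strand(reads) == "*")) stop("eRNA filtering requires stranded reads")
  if (!is.null(reads$split_mapped)) reads <- reads[!reads$split_mapped]
  g <- genes(annotation)
  g <- g[g$biotype %in% excluded_biotypes]
  if (!length(g)) return(reads)
  ext <- extendGeneRegion(g, upstream, downstream)
  hits <- findOverlaps(reads, ext, ignore.strand = TRUE)
  rs <- as.character(strand(reads))[queryHits(hits)]
  gs <- as.character(strand(ext))[subjectHits(hits)]
  opposite <- rs != gs
  remove_hit <- if (convention == "dutp") opposite else !opposite
  drop <- unique(queryHits(hits)[remove_hit])
  if (length(drop)) reads[-drop] else reads
}

#' Detect transcribed regions on the filtered residue
#'
#' Runs the island detector per strand with a uniform genome-wide background
#' (no local-background model) and no duplicate collapsing, at a stringent
#' per-bin threshold — the read-enrichment analogue of peak detection on
#' RNA-seq residue. Returns stranded intervals.
#'
#' @param filtered_reads GRanges from [filterReadsForErna()].
#' @param p_threshold Per-bin Poisson upper-tail threshold (default 1e-4).
#' @param window Bin size in bp (default 200).
#' @param gap Merge gap in bp (default 600).
#' @return GRanges of candidate transcribed regions with strand and `score`.
#' @export
detectTranscribedRegions <- function(filtered_reads, p_threshold = 1e-4,
                                     window = 200, gap = 600) {
  out <- lapply(c("+", "-"), function(s) {
    r <- filtered_reads[strand(filtered_reads) == s]
    if (!length(r)) {
      gr <- GRanges()
      seqlevels(gr) <- seqlevels(filtered_reads)
      seqlengths(gr) <- seqlengths(filtered_reads)
      return(gr)
    }
    isl <- callIslands(r, control_reads = NULL, window = window, gap = gap,
                       p_threshold = p_threshold, background = "uniform",
                       collapse_duplicates = FALSE)
    strand(isl) <- s
    isl
  })
  sort(do.call(c, out))
}

#' Designate eRNAs by acetylation coverage
#'
#' A candidate transcribed region is an eRNA when it is covered >= 50% by
#' H3K9ac peaks AND >= 50% by H3K27ac peaks (both marks required; bedtools
#' `-f 0.5` inclusive semantics). Each candidate is annotated to the nearest
#' gene TSS; an optional photoreceptor-specific category list sets
#' `pr_specific`.
#'
#' @param regions GRanges from [detectTranscribedRegions()].
#' @param h3k9ac_peaks,h3k27ac_peaks Peak GRanges.
#' @param annotation A [GenomeAnnotation].
#' @param pr_genes Optional character vector of photoreceptor-specific genes.
#' @param min_fraction Coverage threshold (default 0.5).
#' @return GRanges of candidates with `h3k9ac_coverage`, `h3k27ac_coverage`,
#'   `is_erna`, `gene_id`, `distance`, `pr_specific`.
#' @export
designateErnas <- function(regions, h3k9ac_peaks, h3k27ac_peaks, annotation,
                           pr_genes = NULL, min_fraction = 0.5) {
  out <- regions
  out$h3k9ac_coverage <- coverageOverlapFraction(regions, h3k9ac_peaks)
  out$h3k27ac_coverage <- coverageOverlapFraction(regions, h3k27ac_peaks)
  out$is_erna <- out$h3k9ac_coverage >= min_fraction &
    out$h3k27ac_coverage >= min_fraction
  ann <- annotateToNearestTss(regions, annotation)
  out$gene_id <- ann$gene_id
  out$distance <- ann$distance
  out$pr_specific <- if (is.null(pr_genes)) NA else out$gene_id %in% pr_genes
  out
}

#' Deregulation report for eRNA candidates
#'
#' Counts filtered reads overlapping each candidate on its own strand, per
#' replicate; tests eRNA deregulation with the stand-in expression test; and
#' pairs each eRNA with its annotated gene's mRNA fold change. A candidate is
#' `concordant_down` when both eRNA and mRNA have log2FC < 0 with adjusted
#' p < `alpha`.
#'
#' @param candidates GRanges from [designateErnas()] (typically subset to
#'   `is_erna`).
#' @param reads_by_sample Named list of *filtered* read GRanges, one per
#'   RNA-seq replicate.
#' @param genotypes Character vector per sample.
#' @param mrna_table [standInDiffTest()] output for the gene-level counts.
#' @param wt_genotype Reference genotype (default "WT").
#' @param size_factors Per-sample factors from the mRNA analysis, reused so
#'   eRNA counts share the library-size correction (default: recomputed from
#'   the gene-level table is not possible here, so factors default to 1).
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame: one row per candidate with `erna_length`, `gene_id`,
#'   eRNA `log2fc`/`adj_p`, mRNA `mrna_log2fc`/`mrna_adj_p`,
#'   `concordant_down`, `low_count` flag.
#' @export
ernaDeregulationReport <- function(candidates, reads_by_sample, genotypes,
                                   mrna_table, wt_genotype = "WT",
                                   size_factors = NULL, alpha = 0.05) {
  if (is.null(size_factors)) size_factors <- rep(1, length(reads_by_sample))
  counts <- vapply(seq_along(reads_by_sample), function(s) {
    r <- reads_by_sample[[s]]
    countOverlaps(candidates, r, ignore.strand = FALSE)
  }, integer(length(candidates)))
  counts <- matrix(counts, nrow = length(candidates))
  rownames(counts) <- paste0("erna_", seq_len(length(candidates)))
  low <- rowSums(counts) == 0
  de <- standInDiffTest(counts, genotypes, wt_genotype,
                        size_factors = size_factors)
  m <- match(candidates$gene_id, mrna_table$gene_id)
  out <- data.frame(
    erna_id = rownames(counts),
    erna_length = width(candidates),
    gene_id = candidates$gene_id,
    log2fc = de$log2fc,
    adj_p = de$adj_p,
    mrna_log2fc = mrna_table$log2fc[m],
    mrna_adj_p = mrna_table$adj_p[m],
    low_count = low,
    stringsAsFactors = FALSE
  )
  out$concordant_down <- !low &
    !is.na(out$log2fc) & out$log2fc < 0 & out$adj_p < alpha &
    !is.na(out$mrna_log2fc) & out$mrna_log2fc < 0 & out$mrna_adj_p < alpha
  out
}
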