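#' Normalized ChIP occupancy density of regions
#'
#' The core occupancy readout: reads are extended to 200 bp in the read
#' direction, a read counts once if it overlaps the region by at least 1 bp,
#' and the density is
#' \deqn{density = (n / L_{Mb}) / (N \times 10^{-8})}
#' i.e. reads per megabase scaled to a 10^8-read library, where `n` is the
#' overlapping read count, `L_Mb` the region length in Mb and `N` the library
#' size. The unit is invariant under joint rescaling of `n` and `N`.
#'
#' @param reads GRanges of aligned reads.
#' @param regions GRanges of regions of interest.
#' @param total_reads Library size `N` (total aligned reads in the dataset).
#' @param extend Fragment extension applied before counting (default 200 bp;
#'   set to `NA` to count reads as given).
#' @return Numeric vector of densities, one per region.
#' @export
rawDensity <- function(reads, regions, total_reads, extend = 200) {
  if (any(width(regions) <= 0)) stop("zero-length region")
  if (total_reads <= 0) stop("total_reads must be positive")
  if (!is.na(extend)) reads <- extendReads(reads, extend)
  n <- countOverlaps(regions, reads, ignore.strand = TRUE)
  l_mb <- width(regions) / 1e6
  (n / l_mb) / (total_reads * 1e-8)
}

#' Intergenic normalization factor between genotypes
#'
#' For each intergenic region the mutant/WT density fold change is computed;
#' the factor is the median of those fold changes. WT densities are
#' subsequently *multiplied* by this factor, which forces the median
#' intergenic fold change (mutant / normalized-WT) to exactly 1 — the
#' background-matching normalization applied to all WT density tables.
#' Regions with zero WT density are excluded (the ratio is undefined).
#'
#' @param wt_reads,mut_reads GRanges of reads for each genotype.
#' @param intergenic GRanges from [deriveIntergenicRegions()].
#' @param wt_total,mut_total Library sizes (default: number of reads).
#' @param mark Mark label recorded in the result.
#' @param min_regions Minimum usable regions (default 20).
#' @return A list with elements `value` (the factor), `n_regions` (regions
#'   used), `mark`, and `fold_changes` (the per-region FCs).
#' @export
intergenicNormalizationFactor <- function(wt_reads, mut_reads, intergenic,
                                          wt_total = length(wt_reads),
                                          mut_total = length(mut_reads),
                                          mark = NA_character_,
                                          min_regions = 20) {
  wt_d <- rawDensity(wt_reads, intergenic, wt_total)
  mut_d <- rawDensity(mut_reads, intergenic, mut_total)
  usable <- wt_d > 0
  if (sum(usable) < min_regions)
    stop("only ", sum(usable), " intergenic regions with nonzero WT density; ",
         "need >= ", min_regions,
         " (enlarge the simulation or relax the intergenic minimum length)")
  fc <- mut_d[usable] / wt_d[usable]
  list(value = median(fc), n_regions = sum(usable), mark = mark,
       fold_changes = fc)
}

# Shared density-table builder over arbitrary region sets.
.densityTable <- function(reads_by_genotype, totals, regions, region_role,
                          mark, norm_factor = 1, wt_genotype = "WT") {
  stopifnot(!is.null(names(reads_by_genotype)))
  out <- lapply(names(reads_by_genotype), function(gt) {
    d <- rawDensity(reads_by_genotype[[gt]], regions, totals[[gt]])
    f <- if (gt == wt_genotype) norm_factor else 1
    data.frame(gene_id = regions$gene_id, mark = mark, genotype = gt,
               region_role = region_role,
               n_reads = countOverlaps(regions,
                                       extendReads(reads_by_genotype[[gt]]),
                                       ignore.strand = TRUE),
               length_mb = width(regions) / 1e6,
               density = d * f,
               norm_factor = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Promoter (TSS window) density table
#'
#' Densities on the TSS +/- `half_window` region of each gene in
#' `gene_filter` (the expressed-and-RNAPII-peaked set), per genotype.
#' WT densities carry the intergenic normalization factor.
#'
#' @param reads_by_genotype Named list of read GRanges, one per genotype.
#' @param annotation A [GenomeAnnotation].
#' @param mark Mark label.
#' @param half_window Half-width of the TSS window (default 300 bp, giving
#'   the 600 bp TSS window).
#' @param gene_filter Character vector of gene ids to keep (required).
#' @param norm_factor Intergenic normalization factor applied to WT
#'   (`value` from [intergenicNormalizationFactor()]; default 1).
#' @param totals Named list/vector of library sizes (default: read counts).
#' @param wt_genotype Name of the genotype treated as WT (default "WT").
#' @return data.frame with one row per (gene, genotype): `gene_id`, `mark`,
#'   `genotype`, `region_role`, `n_reads`, `length_mb`, `density`,
#'   `norm_factor`.
#' @export
promoterDensityTable <- function(reads_by_genotype, annotation, mark,
                                 half_window = 300, gene_filter,
                                 norm_factor = 1, totals = NULL,
                                 wt_genotype = "WT") {
  if (missing(gene_filter) || !length(gene_filter))
    stop("gene_filter is empty: supply the expressed-and-peaked gene set")
  g <- genes(annotation)
  g <- g[g$gene_id %in% gene_filter]
  if (!length(g)) stop("no annotated genes match gene_filter")
  win <- .tssWindow(g, half_window, half_window)
  if (is.null(totals))
    totals <- lapply(reads_by_genotype, length)
  .densityTable(reads_by_genotype, totals, win, "promoter_window", mark,
                norm_factor, wt_genotype)
}

#' Gene-body density table
#'
#' Densities over the gene body, either the full TSS-to-TTS span (H3K4me1
#' convention) or TSS+301 to TTS (the RNAPII body convention). Genes too
#' short for the `tss301_to_tts` window are skipped with a warning.
#'
#' @inheritParams promoterDensityTable
#' @param mode `"tss_to_tts"` or `"tss301_to_tts"`.
#' @return data.frame as in [promoterDensityTable()] with
#'   `region_role = "gene_body"`.
#' @export
genebodyDensityTable <- function(reads_by_genotype, annotation, mark,
                                 mode = c("tss_to_tts", "tss301_to_tts"),
                                 gene_filter, norm_factor = 1, totals = NULL,
                                 wt_genotype = "WT") {
  mode <- match.arg(mode)
  if (missing(gene_filter) || !length(gene_filter))
    stop("gene_filter is empty: supply the expressed-and-peaked gene set")
  g <- genes(annotation)
  g <- g[g$gene_id %in% gene_filter]
  body <- if (mode == "tss_to_tts") g else .geneBody(g, from5p = 301)
  if (length(body) < length(g))
    warning(length(g) - length(body),
            " gene(s) too short for the TSS+301..TTS window; skipped")
  if (is.null(totals))
    totals <- lapply(reads_by_genotype, length)
  .densityTable(reads_by_genotype, totals, body, "gene_body", mark,
                norm_factor, wt_genotype)
}

#' Compare densities between genotypes
#'
#' Per-gene fold change (mutant / normalized-WT density), the median fold
#' change, and a two-sided Mann-Whitney U test between the two genotypes'
#' density vectors. Genes with zero WT density have undefined FC and are
#' flagged and excluded from the median.
#'
#' @param table A density table from [promoterDensityTable()] or
#'   [genebodyDensityTable()] containing both genotypes.
#' @param wt_genotype,mut_genotype Genotype labels (defaults "WT" and the
#'   other level present).
#' @return A list: `per_gene` (data.frame with `gene_id`, `wt_density`,
#'   `mut_density`, `fc`, `defined`), `median_fc`, `p_value`.
#' @export
compareConditions <- function(table, wt_genotype = "WT",
                              mut_genotype = NULL) {
  gts <- unique(table$genotype)
  if (!(wt_genotype %in% gts)) stop("WT genotype absent from table")
  if (is.null(mut_genotype)) mut_genotype <- setdiff(gts, wt_genotype)[1L]
  if (is.na(mut_genotype)) stop("mutant genotype absent from table")
  wt <- table[table$genotype == wt_genotype, ]
  mut <- table[table$genotype == mut_genotype, ]
  m <- match(wt$gene_id, mut$gene_id)
  per_gene <- data.frame(
    gene_id = wt$gene_id,
    wt_density = wt$density,
    mut_density = mut$density[m],
    stringsAsFactors = FALSE
  )
  per_gene$defined <- per_gene$wt_density > 0 & !is.na(per_gene$mut_density)
  per_gene$fc <- ifelse(per_gene$defined,
                        per_gene$mut_density / per_gene$wt_density, NA_real_)
  list(per_gene = per_gene,
       median_fc = median(per_gene$fc[per_gene$defined]),
       p_value = .mannWhitney(per_gene$mut_density, per_gene$wt_density))
}

# Two-sided Mann-Whitney U: exact enumeration below 50 per group (no ties),
# normal approximation with tie correction otherwise (stats::wilcox.test's
# own switching rule, made explicit here).
.mannWhitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  exact <- length(a) < 50 && length(b) < 50 && !any(duplicated(c(a, b)))
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)$p.value
  )
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence against the null
  min(p, 1)
}
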