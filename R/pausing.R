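#' RNAPII pausing index per gene
#'
#' Pausing index = 5' read density / gene-body density, with the 5' region
#' TSS-30..TSS+300 (330 bp, strand-aware) and the body TSS+301..TTS-300.
#' Densities are raw (pre-normalization-factor) per-bp read densities: both
#' the library size and any normalization constant cancel in the ratio, so WT
#' and mutant indices are computed identically. Reads are extended to 200 bp
#' and counted by their fragment midpoint: any-overlap counting would inflate
#' the short 5' window by the fragment length (uniform coverage would give an
#' index of about 1.6 instead of 1), whereas midpoint counting makes the
#' index of uniform coverage exactly 1. Genes too short for a body window
#' (length <= 601 bp) are skipped. Genes with zero body density but nonzero
#' 5' density are reported with `fully_paused = TRUE` rather than an infinite
#' index, and excluded from medians.
#'
#' @param rnapii_reads GRanges of RNAPII reads.
#' @param annotation A [GenomeAnnotation].
#' @param gene_filter Optional character vector of gene ids to restrict to.
#' @param total_reads Library size (default: number of reads).
#' @return data.frame: `gene_id`, `five_prime_density`, `body_density`, `pi`,
#'   `defined`, `fully_paused`.
#' @export
pausingIndex <- function(rnapii_reads, annotation, gene_filter = NULL,
                         total_reads = length(rnapii_reads)) {
  g <- genes(annotation)
  if (!is.null(gene_filter)) g <- g[g$gene_id %in% gene_filter]
  body <- .geneBody(g, from5p = 301, from3p = 300)
  g <- g[match(body$gene_id, g$gene_id)]  # keep genes long enough
  five <- .tssWindow(g, upstream = 30, downstream = 300)
  mids <- .fragmentMidpoints(rnapii_reads)
  dens <- function(win) {
    n <- countOverlaps(win, mids, ignore.strand = TRUE)
    (n / (width(win) / 1e6)) / (total_reads * 1e-8)
  }
  fd <- dens(five)
  bd <- dens(body)
  defined <- bd > 0
  data.frame(
    gene_id = g$gene_id,
    five_prime_density = fd,
    body_density = bd,
    pi = ifelse(defined, fd / bd, NA_real_),
    defined = defined,
    fully_paused = !defined & fd > 0,
    stringsAsFactors = FALSE
  )
}

#' Ratio of group medians with a Mann-Whitney p-value
#'
#' @param group_a,group_b Numeric vectors (non-empty; NAs dropped).
#' @param decimals Rounding applied to the reported ratio (default 1).
#' @return A list: `ratio` (rounded), `ratio_raw`, `median_a`, `median_b`,
#'   `p_value`.
#' @export
ratioOfMedians <- function(group_a, group_b, decimals = 1) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  mb <- median(group_b)
  if (mb == 0) stop("median of group_b is zero; ratio undefined")
  r <- median(group_a) / mb
  list(ratio = round(r, decimals), ratio_raw = r,
       median_a = median(group_a), median_b = mb,
       p_value = .mannWhitney(group_a, group_b))
}

#' WT-basal pausing index by deregulation class
#'
#' Stratifies genes by their mutant/WT expression fold change and summarizes
#' the WT pausing index per stratum, reporting each stratum's median and its
#' ratio relative to the non-deregulated reference stratum. Default strata
#' follow the downregulation cuts FC < 0.5 and FC < 0.3.
#'
#' @param pi_table Output of [pausingIndex()] (WT library).
#' @param fc Named numeric vector of expression fold changes (mutant/WT),
#'   names are gene ids.
#' @param deregulated Character vector of significantly downregulated gene
#'   ids; all other genes in `pi_table` form the non-deregulated reference.
#' @param strata Numeric cut points applied to downregulated genes (each
#'   stratum is `fc < cut`), default `c(0.7, 0.5, 0.3)`.
#' @return data.frame: `stratum`, `n`, `median_pi`,
#'   `ratio_vs_non_deregulated` (reference median / stratum median, the
#'   fold-decrease convention; NA for empty strata).
#' @export
pausingByDeregulationClass <- function(pi_table, fc, deregulated,
                                       strata = c(0.7, 0.5, 0.3)) {
  ok <- pi_table$defined
  pis <- setNames(pi_table$pi[ok], pi_table$gene_id[ok])
  nondereg <- setdiff(names(pis), deregulated)
  ref <- pis[nondereg]
  rows <- list(data.frame(stratum = "non_deregulated", n = length(ref),
                          median_pi = median(ref),
                          ratio_vs_non_deregulated = 1,
                          stringsAsFactors = FALSE))
  for (cut in strata) {
    ids <- intersect(deregulated[!is.na(fc[deregulated]) &
                                   fc[deregulated] < cut], names(pis))
    med <- if (length(ids)) median(pis[ids]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = sprintf("down_fc_lt_%g", cut), n = length(ids),
      median_pi = med,
      ratio_vs_non_deregulated =
        if (length(ids) && med > 0) median(ref) / med else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
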