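#' Hypergeometric gene-set enrichment in a cluster
#'
#' Observed = |category ∩ cluster|; expected = |category ∩ universe| x
#' |cluster| / |universe|; ratio = observed / expected ("normalized to 1"
#' under the uniform null). The p-value is the hypergeometric upper tail
#' `P(X >= observed)` when the ratio is at least 1, and the lower tail
#' `P(X <= observed)` for depletion. The category is intersected with the
#' universe before testing.
#'
#' @param category Character vector of gene ids (the gene category).
#' @param cluster_genes Character vector of gene ids in the cluster (must be
#'   a subset of the universe).
#' @param universe Character vector of all analysis genes.
#' @return A one-row data.frame: `n_observed`, `n_expected`, `ratio`, `p`,
#'   `direction` ("enrichment"/"depletion").
#' @export
hypergeometricEnrichment <- function(category, cluster_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  cluster_genes <- unique(cluster_genes)
  if (!length(cluster_genes)) stop("empty cluster")
  if (!all(cluster_genes %in% universe))
    stop("cluster_genes must be a subset of the universe")
  cat_u <- intersect(unique(category), universe)
  obs <- length(intersect(cat_u, cluster_genes))
  expd <- length(cat_u) * length(cluster_genes) / length(universe)
  ratio <- if (expd > 0) obs / expd else NA_real_
  K <- length(cat_u); N <- length(universe); n <- length(cluster_genes)
  p <- if (is.na(ratio) || ratio >= 1)
    phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
  else
    phyper(obs, K, N - K, n, lower.tail = TRUE)
  data.frame(n_observed = obs, n_expected = expd, ratio = ratio, p = p,
             direction = if (!is.na(ratio) && ratio < 1) "depletion" else
               "enrichment",
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment across all clusters
#'
#' Applies [hypergeometricEnrichment()] per cluster. Observed counts sum to
#' |category ∩ universe| across clusters and the expected-weighted mean of
#' the ratios is 1 when the clusters partition the universe.
#'
#' @param category Character vector of gene ids.
#' @param cluster_map Named vector/list mapping gene id -> cluster label, or a
#'   list of character vectors per cluster.
#' @param universe Character vector of all analysis genes (default: all genes
#'   in `cluster_map`).
#' @return data.frame with one row per cluster.
#' @export
clusterGeneEnrichment <- function(category, cluster_map, universe = NULL) {
  if (is.list(cluster_map) && is.null(names(cluster_map)))
    stop("cluster_map list must be named by cluster")
  if (!is.list(cluster_map)) {
    cluster_map <- split(names(cluster_map), unlist(cluster_map))
  }
  if (is.null(universe)) universe <- unique(unlist(cluster_map))
  out <- lapply(names(cluster_map), function(cl) {
    res <- hypergeometricEnrichment(category, cluster_map[[cl]], universe)
    cbind(data.frame(cluster = cl, stringsAsFactors = FALSE), res)
  })
  do.call(rbind, out)
}

#' Binding-site / interval feature enrichment per cluster
#'
#' Each feature is assigned to the cluster whose 10 kb profile window
#' contains its midpoint (overlapping windows: nearest window center, ties to
#' the lower cluster label); unassigned features are dropped from the
#' universe. Expected counts are proportional to each cluster's window count.
#' Because features are independent placements rather than draws from a
#' finite gene set, the tail probability is binomial
#' (upper tail for enrichment, lower for depletion) with success probability
#' the cluster's share of windows.
#'
#' @param features GRanges of features (e.g. TF binding sites).
#' @param cluster_windows GRanges of profile windows with an integer
#'   `cluster` metadata column.
#' @return data.frame: `cluster`, `n_windows`, `n_observed`, `n_expected`,
#'   `ratio`, `p`, `direction`.
#' @export
intervalFeatureEnrichment <- function(features, cluster_windows) {
  if (is.null(cluster_windows$cluster))
    stop("cluster_windows must carry a 'cluster' column")
  mid <- GRanges(seqnames(features),
                 IRanges(floor((start(features) + end(features)) / 2),
                         width = 1))
  hits <- findOverlaps(mid, cluster_windows, ignore.strand = TRUE)
  if (length(hits)) {
    # resolve multi-window hits: nearest window center, tie -> lower label
    wc <- floor((start(cluster_windows) + end(cluster_windows)) / 2)
    hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits))
    hdf$d <- abs(start(mid)[hdf$q] - wc[hdf$s])
    hdf$lab <- cluster_windows$cluster[hdf$s]
    hdf <- hdf[order(hdf$q, hdf$d, hdf$lab), ]
    hdf <- hdf[!duplicated(hdf$q), ]
    assigned <- hdf$lab
  } else assigned <- integer(0)
  labs <- sort(unique(cluster_windows$cluster))
  n_win <- as.integer(table(factor(cluster_windows$cluster, levels = labs)))
  n_tot <- length(assigned)
  obs <- as.integer(table(factor(assigned, levels = labs)))
  share <- n_win / sum(n_win)
  expd <- n_tot * share
  ratio <- ifelse(expd > 0, obs / expd, NA_real_)
  p <- vapply(seq_along(labs), function(i) {
    if (is.na(ratio[i]) || ratio[i] >= 1)
      stats::pbinom(obs[i] - 1, n_tot, share[i], lower.tail = FALSE)
    else
      stats::pbinom(obs[i], n_tot, share[i], lower.tail = TRUE)
  }, numeric(1))
  data.frame(cluster = labs, n_windows = n_win, n_observed = obs,
             n_expected = expd, ratio = ratio, p = p,
             direction = ifelse(!is.na(ratio) & ratio < 1, "depletion",
                                "enrichment"),
             stringsAsFactors = FALSE)
}

#' ROSE-style superenhancer calling
#'
#' Peaks fully inside a TSS +/- `tss_exclusion` window are removed, the
#' remainder stitched when gaps are at most `stitch` bp, stitched regions
#' ranked by total signal, and the hockey-stick cutoff applied: on the
#' rank/signal curve scaled so both axes run 0..1, regions above the point
#' where a line of slope 1 is tangent to the curve are superenhancers
#' (equivalently, the tangent line position minimizing the number of points
#' below it). With fewer than 3 stitched regions the cutoff is undefined and
#' all regions are flagged non-super with a warning.
#'
#' @param peaks GRanges of H3K27ac peaks.
#' @param signal Numeric per-peak signal. Default: the peaks' `score` column.
#'   When `chip_reads` is given, the signal is recomputed as the peak's
#'   extended-read count minus the length-scaled control count, floored at 0.
#' @param annotation A [GenomeAnnotation] (for TSS exclusion).
#' @param chip_reads,control_reads Optional read GRanges for
#'   background-subtracted signal.
#' @param stitch Stitching distance (default 12500 bp).
#' @param tss_exclusion TSS half-window for exclusion (default 2000 bp).
#' @return GRanges of stitched regions with `total_signal`, `n_peaks`,
#'   `rank` (1 = strongest) and `is_super`.
#' @export
callSuperenhancers <- function(peaks, annotation, signal = peaks$score,
                               chip_reads = NULL, control_reads = NULL,
                               stitch = 12500, tss_exclusion = 2000) {
  g <- genes(annotation)
  tssw <- .tssWindow(g, tss_exclusion, tss_exclusion)
  drop <- overlapsAny(peaks, tssw, type = "within", ignore.strand = TRUE)
  peaks <- peaks[!drop]
  if (!is.null(chip_reads)) {
    chip_n <- countOverlaps(peaks, extendReads(chip_reads),
                            ignore.strand = TRUE)
    ctrl_n <- if (length(control_reads))
      countOverlaps(peaks, extendReads(control_reads), ignore.strand = TRUE) *
        length(chip_reads) / length(control_reads)
    else 0
    signal <- pmax(chip_n - ctrl_n, 0)
  } else {
    signal <- signal[!drop]
  }
  if (!length(peaks)) {
    out <- GRanges(seqinfo = seqinfo(peaks))
    out$total_signal <- numeric(0); out$n_peaks <- integer(0)
    out$rank <- integer(0); out$is_super <- logical(0)
    return(out)
  }
  stitched <- reduce(granges(peaks), min.gapwidth = stitch + 1,
                     ignore.strand = TRUE)
  ov <- findOverlaps(peaks, stitched, ignore.strand = TRUE)
  tot <- tapply(signal[queryHits(ov)], subjectHits(ov), sum)
  stitched$total_signal <- 0
  stitched$total_signal[as.integer(names(tot))] <- as.numeric(tot)
  stitched$n_peaks <- 0L
  np <- table(subjectHits(ov))
  stitched$n_peaks[as.integer(names(np))] <- as.integer(np)
  stitched$rank <- as.integer(rank(-stitched$total_signal,
                                   ties.method = "first"))
  if (length(stitched) < 3) {
    warning("fewer than 3 stitched regions; superenhancer cutoff undefined")
    stitched$is_super <- FALSE
    return(sort(stitched))
  }
  cutoff <- roseCutoff(stitched$total_signal)
  stitched$is_super <- stitched$total_signal > cutoff
  sort(stitched)
}

#' Hockey-stick signal cutoff (tangent of slope 1 on the scaled curve)
#'
#' Signals are sorted ascending; with both axes scaled to 0..1 the curve's
#' tangent line of slope 1 marks the inflection. Implemented on the raw axes
#' as a line of slope (max - min) / n through each candidate point, choosing
#' the point that minimizes the number of curve points below the line; the
#' cutoff is the signal at that point. Regions with signal strictly above
#' the cutoff are super.
#'
#' @param signal Numeric vector of region signals.
#' @return The cutoff value.
#' @export
roseCutoff <- function(signal) {
  v <- sort(as.numeric(signal))
  n <- length(v)
  slope <- (max(v) - min(v)) / n
  if (slope == 0) return(max(v))  # flat curve: nothing is super
  idx <- seq_len(n)
  tol <- 1e-9 * max(abs(v))
  n_below <- vapply(idx, function(i) {
    b <- v[i] - slope * i
    sum(v <= slope * idx + b + tol)
  }, numeric(1))
  # discrete tangent can tie between the two points straddling the true
  # tangent; take the rightmost (= where the scaled slope reaches 1)
  v[max(which(n_below == min(n_below)))]
}

#' Motif occurrence summary per cluster
#'
#' Given precomputed motif hits (one GRanges per motif), reports per cluster
#' the fraction of regions with at least one hit of any motif and the mean
#' total number of hits among hit-positive regions (the motif co-occurrence).
#'
#' @param regions_by_cluster Named list of GRanges, one per cluster.
#' @param motif_hits Named list of GRanges, one per motif.
#' @return data.frame: `cluster`, `n_regions`, `n_with_hit`,
#'   `fraction_with_hit`, `percent_with_hit` (nearest integer),
#'   `mean_cooccurrence` (NA when no region has a hit).
#' @export
motifOccurrenceSummary <- function(regions_by_cluster, motif_hits) {
  if (!length(regions_by_cluster)) stop("empty region list")
  out <- lapply(names(regions_by_cluster), function(cl) {
    regions <- regions_by_cluster[[cl]]
    if (!length(regions))
      return(data.frame(cluster = cl, n_regions = 0L, n_with_hit = 0L,
                        fraction_with_hit = NA_real_,
                        percent_with_hit = NA_real_,
                        mean_cooccurrence = NA_real_,
                        stringsAsFactors = FALSE))
    counts <- Reduce(`+`, lapply(motif_hits, function(h)
      countOverlaps(regions, h, ignore.strand = TRUE)))
    pos <- counts >= 1
    data.frame(cluster = cl, n_regions = length(regions),
               n_with_hit = sum(pos),
               fraction_with_hit = mean(pos),
               percent_with_hit = round(100 * mean(pos)),
               mean_cooccurrence = if (any(pos)) mean(counts[pos]) else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Direct transcriptional targets of a factor
#'
#' Genes harboring at least one binding site (sites annotated to the nearest
#' TSS) intersected with the genes deregulated in the factor's knockout.
#'
#' @param binding_sites GRanges of binding sites.
#' @param ko_deregulated Character vector of gene ids deregulated in the
#'   knockout.
#' @param annotation A [GenomeAnnotation].
#' @return Character vector of direct target gene ids.
#' @export
defineDirectTargets <- function(binding_sites, ko_deregulated, annotation) {
  ann <- annotateToNearestTss(binding_sites, annotation)
  bound <- unique(ann$gene_id[!is.na(ann$gene_id)])
  sort(intersect(bound, ko_deregulated))
}

#' Three-way partition of two target gene sets
#'
#' @param targets_a,targets_b Character vectors of gene ids.
#' @return A list: `a_only`, `b_only`, `common` (sizes), `union` (size),
#'   and the corresponding id vectors under `sets`.
#' @export
targetPartition <- function(targets_a, targets_b) {
  targets_a <- unique(targets_a); targets_b <- unique(targets_b)
  common <- intersect(targets_a, targets_b)
  a_only <- setdiff(targets_a, targets_b)
  b_only <- setdiff(targets_b, targets_a)
  list(a_only = length(a_only), b_only = length(b_only),
       common = length(common),
       union = length(a_only) + length(b_only) + length(common),
       sets = list(a_only = a_only, b_only = b_only, common = common))
}
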