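#' Build a peak-centered density profile matrix
#'
#' One row per peak: extended-read counts in `2*half_window/bin` consecutive
#' bins covering the peak midpoint +/- `half_window` (default a 10 kb window
#' of 100 x 100 bp bins). Bins falling outside the chromosome are zero-filled.
#' Each row is linearly scaled to maximum 1 (all-zero rows stay zero), so the
#' clustering sees profile shape, not height.
#'
#' @param peaks GRanges of peaks (midpoints define window centers).
#' @param reads GRanges of reads (extended to 200 bp before counting).
#' @param half_window Half window in bp (default 5000).
#' @param bin Bin width in bp (default 100).
#' @return Numeric matrix (rows = peaks, named by peak index or names(peaks));
#'   attribute `centers` holds the midpoints.
#' @export
buildProfileMatrix <- function(peaks, reads, half_window = 5000, bin = 100) {
  if (!length(peaks)) stop("empty peak set")
  nbin <- as.integer(2 * half_window / bin)
  # 0-based midpoint; bins cover [mid - half_window, mid + half_window)
  mid <- floor((start(peaks) - 1 + end(peaks)) / 2)
  sl <- seqlengths(peaks)
  chrom <- as.character(seqnames(peaks))
  # all bins for all peaks, flat (1-based starts)
  offs <- seq_len(nbin) - 1L
  bstart <- rep(mid - half_window + 1, each = nbin) +
    rep(offs * bin, length(peaks))
  bend <- bstart + bin - 1L
  bchrom <- rep(chrom, each = nbin)
  valid <- bstart >= 1 & bend <= sl[bchrom]
  counts <- numeric(length(bstart))
  if (any(valid)) {
    bins <- GRanges(bchrom[valid], IRanges(bstart[valid], bend[valid]))
    seqlevels(bins) <- seqlevels(peaks)
    seqlengths(bins) <- sl
    counts[valid] <- countOverlaps(bins, extendReads(reads, 200),
                                   ignore.strand = TRUE)
  }
  m <- matrix(counts, nrow = length(peaks), ncol = nbin, byrow = TRUE)
  rownames(m) <- if (!is.null(names(peaks))) names(peaks) else
    paste0("peak_", seq_len(length(peaks)))
  m <- scaleRowsToMax(m)
  attr(m, "centers") <- mid
  m
}

#' Row-linear scaling to maximum 1
#'
#' Divides each row by its maximum; all-zero rows are left at zero. This is
#' idempotent.
#'
#' @param m Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
scaleRowsToMax <- function(m) {
  mx <- apply(m, 1L, max)
  mx[mx == 0] <- 1
  m / mx
}

# k-means++ seeding (deterministic given the RNG state).
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  if (k > 1L) for (j in 2:k) {
    if (sum(d2) == 0) {
      centers[j, ] <- x[sample.int(n, 1L), ]
    } else {
      pick <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[pick, ]
    }
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Cluster peak profiles with k-means
#'
#' Euclidean k-means on the row-scaled profile matrix with k-means++
#' initialization, `restarts` restarts keeping the lowest total
#' within-cluster sum of squares, under a fixed seed. Labels are renumbered
#' by mean-profile breadth (number of bins >= 0.25 of the mean profile's
#' maximum) so label `k` is always the broadest cluster, making "the broad
#' cluster" addressable independently of the seed.
#'
#' @param m Profile matrix from [buildProfileMatrix()].
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 20).
#' @return A list: `cluster` (named integer vector, 1..k), `sizes`,
#'   `centers` (k x bins mean-profile matrix, renumbered), `breadth`
#'   (bins >= 0.25 of max per renumbered cluster), `totss_within`.
#' @export
kmeansProfiles <- function(m, k = 10, seed = 1, restarts = 20) {
  if (nrow(m) < k) stop("fewer rows (", nrow(m), ") than clusters (", k, ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- .kmeanspp_safe(m, k)
    fit <- suppressWarnings(
      kmeans(m, centers = init, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  centers <- best$centers
  breadth <- apply(centers, 1L, function(p) {
    mx <- max(p); if (mx == 0) 0L else sum(p >= 0.25 * mx)
  })
  ord <- order(breadth, rowMeans(centers), seq_len(k))  # broadest last
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cl <- relabel[best$cluster]
  names(cl) <- rownames(m)
  list(cluster = cl,
       sizes = tabulate(cl, nbins = k),
       centers = centers[ord, , drop = FALSE],
       breadth = breadth[ord],
       totss_within = best$tot.withinss)
}

# k-means++ seeding that retries degenerate draws (duplicate centers).
.kmeanspp_safe <- function(m, k) {
  init <- .kmeansppCenters(m, k)
  for (i in 1:5) {
    if (!anyDuplicated(init)) return(init)
    init <- .kmeansppCenters(m, k)
  }
  dup <- duplicated(init)
  init[dup, ] <- init[dup, , drop = FALSE] +
    matrix(rnorm(sum(dup) * ncol(init), sd = 1e-9), nrow = sum(dup))
  init
}

#' Per-cluster summaries of expression, pausing and broadness
#'
#' Joins a cluster assignment (peaks annotated to genes) with a per-gene
#' expression vector, a pausing-index table and per-genotype broadness
#' tables, reporting per cluster the number of protein-coding genes, median
#' expression, median WT pausing index, median broadness per genotype, and
#' the mutant/WT broadness change.
#'
#' @param assignment Result of [kmeansProfiles()].
#' @param peak_genes Character vector: gene id annotated to each peak (same
#'   order as the profile-matrix rows).
#' @param rpk Named per-gene expression values (e.g. WT mean RPK); optional.
#' @param pi_table [pausingIndex()] output (WT); optional.
#' @param broadness_by_genotype Named list of [broadnessByGene()] outputs
#'   (e.g. `list(WT = ..., SCA7 = ...)`); optional.
#' @param wt_genotype Which list element is WT (default "WT").
#' @return data.frame with one row per cluster.
#' @export
clusterSummaries <- function(assignment, peak_genes, rpk = NULL,
                             pi_table = NULL, broadness_by_genotype = NULL,
                             wt_genotype = "WT") {
  k <- length(assignment$sizes)
  cl <- assignment$cluster
  out <- data.frame(cluster = seq_len(k), n_peaks = assignment$sizes)
  gene_lists <- lapply(seq_len(k), function(c)
    unique(peak_genes[cl == c & !is.na(peak_genes)]))
  out$n_genes <- lengths(gene_lists)
  if (!is.null(rpk))
    out$median_rpk <- vapply(gene_lists, function(gs) {
      v <- rpk[intersect(gs, names(rpk))]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
  if (!is.null(pi_table)) {
    pis <- setNames(pi_table$pi[pi_table$defined],
                    pi_table$gene_id[pi_table$defined])
    out$median_pi <- vapply(gene_lists, function(gs) {
      v <- pis[intersect(gs, names(pis))]
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
  }
  if (!is.null(broadness_by_genotype)) {
    for (gt in names(broadness_by_genotype)) {
      b <- broadness_by_genotype[[gt]]
      bv <- setNames(b$broadness_bp, b$gene_id)
      out[[paste0("median_broadness_", gt)]] <- vapply(
        gene_lists, function(gs) {
          v <- bv[intersect(gs, names(bv))]
          if (length(v)) median(v) else NA_real_
        }, numeric(1))
    }
    mut <- setdiff(names(broadness_by_genotype), wt_genotype)[1L]
    if (!is.na(mut)) {
      wtc <- out[[paste0("median_broadness_", wt_genotype)]]
      mtc <- out[[paste0("median_broadness_", mut)]]
      out$broadness_change <- ifelse(wtc > 0, mtc / wtc - 1, NA_real_)
    }
  }
  out
}
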