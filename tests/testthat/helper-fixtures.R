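suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Quick read builder on a single chromosome with known length.
grReads <- function(starts, width = 50, strand = "+", chrom = "chrT",
                    chrom_len = 1e5, split_mapped = FALSE) {
  gr <- GRanges(chrom, IRanges(starts, width = width), strand = strand)
  seqlevels(gr) <- chrom
  seqlengths(gr) <- chrom_len
  gr$split_mapped <- rep_len(split_mapped, length(gr))
  gr
}

# Annotation with explicit gene table; genes: data.frame(chrom,start,end,
# strand, gene_id, biotype).
toyAnnotation <- function(genes_df, chrom_sizes) {
  g <- GRanges(genes_df$chrom, IRanges(genes_df$start, genes_df$end),
               strand = genes_df$strand)
  g$gene_id <- genes_df$gene_id
  if (!is.null(genes_df$biotype)) g$biotype <- genes_df$biotype
  GenomeAnnotation(g, chrom_sizes = chrom_sizes)
}

# Small simulation config used by unit tests (fast; the acceptance suite
# uses the full default conditions).
smallSimConfig <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_chroms = 1, chrom_length = 2e6,
                   n_genes = c(broad_identity = 6, narrow_housekeeping = 10,
                               other_expressed = 10, silent = 6),
                   chip_reads = 6e4, rna_noise_reads = 500)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# ---- independent oracles ---------------------------------------------------

# Naive extended-read overlap count for one region (plain vectors, no
# GenomicRanges machinery).
oracleOverlapCount <- function(reads_df, region_start, region_end, chrom_len,
                               target = 200) {
  s <- reads_df$start; e <- reads_df$end
  w <- e - s + 1
  plus <- reads_df$strand == "+"
  ext_s <- ifelse(w >= target, s, ifelse(plus, s, e - target + 1))
  ext_e <- ifelse(w >= target, e, ifelse(plus, s + target - 1, e))
  ext_s <- pmax(1, ext_s); ext_e <- pmin(chrom_len, ext_e)
  sum(ext_s <= region_end & ext_e >= region_start)
}

# Brute-force island caller on one toy chromosome: enumerate every bin,
# apply the Poisson rule, then merge by the gap rule with an explicit loop.
oracleIslands <- function(chip_df, ctrl_df = NULL, chrom_len, window = 200,
                          gap = 600, p_threshold = 1e-2, collapse = TRUE) {
  if (collapse) chip_df <- unique(chip_df[c("start", "end", "strand")])
  nbin <- ceiling(chrom_len / window)
  counts <- numeric(nbin)
  for (b in seq_len(nbin)) {
    bs <- (b - 1) * window + 1
    be <- min(chrom_len, b * window)
    counts[b] <- oracleOverlapCount(chip_df, bs, be, chrom_len)
  }
  if (!is.null(ctrl_df) && nrow(ctrl_df) > 0) {
    if (collapse) ctrl_df <- unique(ctrl_df[c("start", "end", "strand")])
    cc <- numeric(nbin)
    for (b in seq_len(nbin)) {
      bs <- (b - 1) * window + 1
      be <- min(chrom_len, b * window)
      cc[b] <- oracleOverlapCount(ctrl_df, bs, be, chrom_len)
    }
    cc <- cc * nrow(chip_df) / nrow(ctrl_df)
    lambda <- pmax(cc, mean(cc))
  } else {
    lambda <- rep(mean(counts), nbin)
  }
  eligible <- counts > 0 &
    ppois(counts - 1, lambda, lower.tail = FALSE) < p_threshold
  idx <- which(eligible)
  if (!length(idx)) return(data.frame(start = numeric(0), end = numeric(0)))
  starts <- ends <- numeric(0)
  cur_s <- (idx[1] - 1) * window + 1
  cur_e <- min(chrom_len, idx[1] * window)
  for (b in idx[-1]) {
    bs <- (b - 1) * window + 1
    be <- min(chrom_len, b * window)
    if (bs - cur_e - 1 <= gap) {
      cur_e <- be
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- bs; cur_e <- be
    }
  }
  data.frame(start = c(starts, cur_s), end = c(ends, cur_e))
}

grToDf <- function(gr) {
  data.frame(start = start(gr), end = end(gr),
             strand = as.character(strand(gr)), stringsAsFactors = FALSE)
}

# Exhaustive hypergeometric upper tail: enumerate all cluster draws.
oracleHyperUpper <- function(universe, category, cluster_size, observed) {
  combos <- utils::combn(universe, cluster_size)
  hits <- apply(combos, 2, function(cl) sum(cl %in% category))
  mean(hits >= observed)
}

# ROSE cutoff oracle: first point (ascending) where the slope of the curve
# scaled to the unit square reaches 1; everything above is super.
oracleSuperSet <- function(signal) {
  v <- sort(signal)
  n <- length(v)
  x <- seq_len(n) / n
  y <- (v - min(v)) / (max(v) - min(v))
  sl <- diff(y) / diff(x)
  j <- which(sl > 1)[1]
  cutoff <- v[j]
  signal > cutoff
}

# Profiles of two planted shapes: a narrow center peak and a plateau.
plantedProfiles <- function(n_per = 100, nbin = 100, seed = 5) {
  set.seed(seed)
  narrow <- t(vapply(seq_len(n_per), function(i) {
    p <- exp(-(seq_len(nbin) - nbin / 2)^2 / 8) + runif(nbin, 0, 0.02)
    p / max(p)
  }, numeric(nbin)))
  broad <- t(vapply(seq_len(n_per), function(i) {
    p <- rep(1, nbin) + runif(nbin, 0, 0.02)
    p / max(p)
  }, numeric(nbin)))
  m <- rbind(narrow, broad)
  rownames(m) <- c(paste0("n", seq_len(n_per)), paste0("b", seq_len(n_per)))
  m
}
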