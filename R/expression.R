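#' Median-of-ratios size factors
#'
#' Library-size normalization of a count matrix: the reference is the
#' per-gene geometric mean across samples over genes with all-positive
#' counts; each sample's factor is the median over those genes of
#' count / reference.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named numeric vector of size factors, one per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) stop("no gene with all-positive counts; cannot form reference")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  apply(logc, 2L, function(x) exp(median(x - ref)))
}

#' Reads-per-kilobase (RPK) table
#'
#' Size-factor-normalized counts divided by gene length in kb (the median
#' transcript length). Genes without a length are dropped with a warning.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param size_factors Per-sample factors ([medianRatioSizeFactors()]).
#' @param gene_lengths Named vector of gene lengths in bp.
#' @return Numeric matrix of RPK values.
#' @export
rpkTable <- function(counts, size_factors, gene_lengths) {
  counts <- as.matrix(counts)
  len <- gene_lengths[rownames(counts)]
  keep <- !is.na(len) & len > 0
  if (!all(keep))
    warning(sum(!keep), " gene(s) without a length; dropped from RPK table")
  norm <- sweep(counts[keep, , drop = FALSE], 2L, size_factors, "/")
  norm / (len[keep] / 1000)
}

#' Expressed-gene rule
#'
#' A gene is expressed when its RPK is at least `threshold` in every WT
#' sample (inclusive boundary).
#'
#' @param rpk RPK matrix from [rpkTable()].
#' @param wt_samples Column names or indices of the WT samples.
#' @param threshold RPK threshold (default 1).
#' @return Character vector of expressed gene ids.
#' @export
expressedGenes <- function(rpk, wt_samples, threshold = 1) {
  if (!length(wt_samples)) stop("no WT samples given")
  wt <- rpk[, wt_samples, drop = FALSE]
  rownames(rpk)[rowSums(wt >= threshold) == ncol(wt)]
}

#' Deregulation classification
#'
#' Strict boundary semantics exactly as stated: `down` when FC < `down_fc`
#' and adjusted p < `alpha`; `up` when FC > `up_fc` and adjusted p < `alpha`;
#' otherwise `none`. Missing adjusted p gives `none` (flagged).
#'
#' @param fc Numeric vector of mutant/WT fold changes.
#' @param adj_p Numeric vector of adjusted p-values.
#' @param down_fc,up_fc,alpha Thresholds (defaults 0.7, 1.3, 0.05).
#' @return data.frame: `fc`, `adj_p`, `class` (factor down/up/none),
#'   `p_missing`.
#' @export
classifyDeregulated <- function(fc, adj_p, down_fc = 0.7, up_fc = 1.3,
                                alpha = 0.05) {
  missing_p <- is.na(adj_p)
  cls <- rep("none", length(fc))
  sig <- !missing_p & adj_p < alpha
  cls[sig & fc < down_fc] <- "down"
  cls[sig & fc > up_fc] <- "up"
  data.frame(fc = fc, adj_p = adj_p,
             class = factor(cls, levels = c("down", "up", "none")),
             p_missing = missing_p)
}

#' Stand-in differential-expression test
#'
#' Fold changes are ratios of means of size-factor-normalized counts
#' (lengths cancel). The full negative-binomial machinery is out of scope;
#' when no external adjusted-p column is supplied, significance comes from a
#' documented stand-in on log2(normalized count + 1): by default a
#' variance-moderated t-test (limma's empirical-Bayes shrinkage, which keeps
#' sensible power at 4-vs-3 replicates), or a plain two-sample t-test with
#' `method = "ttest"`. Both use Benjamini-Hochberg adjustment.
#'
#' @param counts Integer matrix, genes x samples.
#' @param genotypes Character vector per sample (two levels).
#' @param wt_genotype Reference level (default "WT").
#' @param size_factors Optional precomputed factors.
#' @param method `"moderated"` (default) or `"ttest"`.
#' @return data.frame: `gene_id`, `base_mean_wt`, `base_mean_mut`, `fc`,
#'   `log2fc`, `p`, `adj_p`; attribute `test` records the method.
#' @export
standInDiffTest <- function(counts, genotypes, wt_genotype = "WT",
                            size_factors = NULL,
                            method = c("moderated", "ttest")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  norm <- sweep(counts, 2L, size_factors, "/")
  wt <- genotypes == wt_genotype
  if (!any(wt) || all(wt)) stop("need both genotypes")
  mean_wt <- rowMeans(norm[, wt, drop = FALSE])
  mean_mut <- rowMeans(norm[, !wt, drop = FALSE])
  fc <- ifelse(mean_wt > 0, mean_mut / mean_wt, NA_real_)
  lg <- log2(norm + 1)
  if (method == "moderated") {
    design <- cbind(intercept = 1, mutant = as.numeric(!wt))
    # all-zero rows (silent genes) have zero variance; limma offsets them
    fit <- suppressWarnings(limma::eBayes(limma::lmFit(lg, design)))
    p <- fit$p.value[, "mutant"]
  } else {
    p <- vapply(seq_len(nrow(lg)), function(i) {
      a <- lg[i, wt]; b <- lg[i, !wt]
      if (sd(a) == 0 && sd(b) == 0)
        return(if (mean(a) == mean(b)) 1 else 0)
      tryCatch(t.test(b, a, var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out <- data.frame(gene_id = rownames(counts),
                    base_mean_wt = mean_wt, base_mean_mut = mean_mut,
                    fc = fc, log2fc = log2(fc),
                    p = unname(p), adj_p = unname(p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  attr(out, "test") <- paste0(method,
    " test on log2(normalized counts + 1), BH adjusted")
  out
}

#' Median RPK ratio between two gene sets
#'
#' Ratio of the median per-gene RPK of `set_a` to that of `set_b`, with a
#' Mann-Whitney p-value. `rpk` is a named per-gene vector (e.g. the WT-mean
#' RPK).
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param rpk Named numeric per-gene RPK values.
#' @param digits Rounding for the reported ratio; `0` gives the nearest
#'   integer (default).
#' @return A list: `ratio` (rounded), `ratio_raw`, `median_a`, `median_b`,
#'   `p_value`.
#' @export
medianRpkRatio <- function(set_a, set_b, rpk, digits = 0) {
  a <- rpk[intersect(set_a, names(rpk))]
  b <- rpk[intersect(set_b, names(rpk))]
  if (!length(a) || !length(b)) stop("both gene sets must be present in rpk")
  if (median(b) == 0) stop("median RPK of set_b is zero")
  r <- median(a) / median(b)
  list(ratio = round(r, digits), ratio_raw = r, median_a = median(a),
       median_b = median(b), p_value = .mannWhitney(a, b))
}
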