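#' Run the full analysis pipeline on a simulated dataset
#'
#' End-to-end orchestration: simulate (annotation, ChIP and RNA reads) →
#' expression (size factors, RPK, expressed genes, stand-in DE) → island
#' calling per mark/genotype → intergenic normalization → promoter/gene-body
#' density tables and genotype comparisons → pausing indices → H3K9ac profile
#' clustering with per-cluster summaries → superenhancers → eRNA workflow.
#' Deterministic for a fixed config seed. Stage outputs are returned in one
#' list; `out_dir` additionally writes the TSV/BED/JSON outputs and a run
#' manifest (parameters, seed, per-stage record counts, file checksums).
#'
#' @param config A [simConfig()].
#' @param out_dir Optional output directory.
#' @param genotypes Genotype labels, WT first (default `c("WT", "SCA7")`).
#' @param k Number of profile clusters (default 10).
#' @return A list with elements `dataset`, `expression`, `peaks`,
#'   `normalization`, `density`, `pausing`, `clusters`, `superenhancers`,
#'   `erna`, `manifest`.
#' @export
runPipeline <- function(config = simConfig(), out_dir = NULL,
                        genotypes = c("WT", "SCA7"), k = 10) {
  wt <- genotypes[1L]; mut <- genotypes[2L]
  ds <- simulateDataset(config, genotypes = genotypes)
  ann <- ds$annotation
  glen <- setNames(genes(ann)$median_tx_len, genes(ann)$gene_id)

  ## expression
  sf <- medianRatioSizeFactors(ds$counts)
  rpk <- rpkTable(ds$counts, sf, glen)
  wt_samples <- colnames(ds$counts)[ds$genotype_of_sample == wt]
  expressed <- expressedGenes(rpk, wt_samples)
  de <- standInDiffTest(ds$counts, ds$genotype_of_sample, wt)
  cls <- classifyDeregulated(de$fc, de$adj_p)
  de$class <- cls$class
  expr <- list(size_factors = sf, rpk = rpk, expressed = expressed, de = de,
               wt_mean_rpk = rowMeans(rpk[, wt_samples, drop = FALSE]))

  ## peaks (islands) per mark and genotype, input as control
  marks <- c("H3K9ac", "H3K27ac", "RNAPII")
  peaks <- lapply(setNames(nm = marks), function(mk)
    lapply(setNames(nm = genotypes), function(gt)
      callIslands(ds$chip[[mk]][[gt]], ds$chip[["input"]][[gt]])))

  ## expressed genes with an annotated WT RNAPII peak
  pol_ann <- annotateToNearestTss(peaks$RNAPII[[wt]], ann)
  peaked <- unique(pol_ann$gene_id[!is.na(pol_ann$gene_id)])
  gene_filter <- intersect(expressed, peaked)

  ## intergenic normalization and density tables; a 2.5 kb gene buffer keeps
  ## boundary-straddling promoter/domain signal out of the background
  intergenic <- deriveIntergenicRegions(ann, gene_buffer = 2500)
  norm <- lapply(setNames(nm = c(marks, "H3K4me1")), function(mk)
    intergenicNormalizationFactor(ds$chip[[mk]][[wt]], ds$chip[[mk]][[mut]],
                                  intergenic, mark = mk))
  reads2 <- function(mk) setNames(list(ds$chip[[mk]][[wt]],
                                       ds$chip[[mk]][[mut]]), genotypes)
  density <- list()
  for (mk in marks)
    density[[mk]] <- compareConditions(
      promoterDensityTable(reads2(mk), ann, mk, gene_filter = gene_filter,
                           norm_factor = norm[[mk]]$value, wt_genotype = wt),
      wt_genotype = wt)
  density$H3K4me1 <- compareConditions(
    genebodyDensityTable(reads2("H3K4me1"), ann, "H3K4me1",
                         mode = "tss_to_tts", gene_filter = gene_filter,
                         norm_factor = norm$H3K4me1$value, wt_genotype = wt),
    wt_genotype = wt)

  ## pausing
  pi_tabs <- lapply(setNames(nm = genotypes), function(gt)
    pausingIndex(ds$chip$RNAPII[[gt]], ann, gene_filter = gene_filter))
  pi_ratio <- ratioOfMedians(pi_tabs[[mut]]$pi[pi_tabs[[mut]]$defined],
                             pi_tabs[[wt]]$pi[pi_tabs[[wt]]$defined])
  pausing <- list(tables = pi_tabs, mut_vs_wt = pi_ratio)

  ## profile clustering on WT H3K9ac peaks
  k9wt <- peaks$H3K9ac[[wt]]
  pm <- buildProfileMatrix(k9wt, ds$chip$H3K9ac[[wt]])
  kk <- min(k, nrow(pm))
  assignment <- kmeansProfiles(pm, k = kk, seed = config$seed)
  peak_genes <- annotateToNearestTss(k9wt, ann)$gene_id
  broadness <- lapply(setNames(nm = genotypes), function(gt)
    broadnessByGene(peaks$H3K9ac[[gt]], ann, gene_set = gene_filter))
  summaries <- clusterSummaries(assignment, peak_genes,
                                rpk = expr$wt_mean_rpk,
                                pi_table = pi_tabs[[wt]],
                                broadness_by_genotype = broadness,
                                wt_genotype = wt)
  windows <- GRanges(seqnames(k9wt),
                     IRanges(pmax(1, floor((start(k9wt) + end(k9wt)) / 2)
                                  - 5000),
                             width = 10000))
  seqlevels(windows) <- seqlevels(k9wt)
  seqlengths(windows) <- seqlengths(k9wt)
  windows <- trim(windows)
  windows$cluster <- assignment$cluster
  down_genes <- de$gene_id[de$class == "down"]
  cluster_map <- split(peak_genes[!is.na(peak_genes)],
                       assignment$cluster[!is.na(peak_genes)])
  down_enrich <- clusterGeneEnrichment(down_genes, cluster_map,
                                       universe = gene_filter)
  clusters <- list(matrix = pm, assignment = assignment,
                   peak_genes = peak_genes, summaries = summaries,
                   windows = windows, down_enrichment = down_enrich,
                   broadness = broadness)

  ## superenhancers from WT H3K27ac
  se <- callSuperenhancers(peaks$H3K27ac[[wt]], ann,
                           chip_reads = ds$chip$H3K27ac[[wt]],
                           control_reads = ds$chip$input[[wt]])

  ## eRNA workflow: filter all replicates, detect on pooled WT residue
  filt <- lapply(setNames(nm = genotypes), function(gt)
    lapply(ds$rna[[gt]]$reads, filterReadsForErna, annotation = ann))
  wt_residue <- do.call(c, filt[[wt]])
  regions <- detectTranscribedRegions(wt_residue)
  cand <- designateErnas(regions, peaks$H3K9ac[[wt]], peaks$H3K27ac[[wt]],
                         ann)
  ernas <- cand[cand$is_erna]
  reads_by_sample <- c(filt[[wt]], filt[[mut]])
  names(reads_by_sample) <- colnames(ds$counts)
  report <- if (length(ernas))
    ernaDeregulationReport(ernas, reads_by_sample,
                           ds$genotype_of_sample, de, wt_genotype = wt,
                           size_factors = sf)
  else NULL
  erna <- list(filtered = filt, regions = regions, candidates = cand,
               ernas = ernas, report = report)

  manifest <- list(
    package_version = as.character(utils::packageVersion("broadAcetyl")),
    seed = config$seed,
    genotypes = genotypes,
    parameters = config[!vapply(config, is.list, logical(1))],
    counts = list(
      genes = length(genes(ann)),
      expressed = length(expressed),
      gene_filter = length(gene_filter),
      deregulated_down = sum(de$class == "down"),
      deregulated_up = sum(de$class == "up"),
      peaks = lapply(peaks, function(x) vapply(x, length, integer(1))),
      intergenic_regions = length(intergenic),
      superenhancers = sum(se$is_super),
      erna_regions = length(regions),
      ernas = length(ernas)
    )
  )
  result <- list(dataset = ds, expression = expr, peaks = peaks,
                 normalization = norm, density = density, pausing = pausing,
                 clusters = clusters, superenhancers = se, erna = erna,
                 manifest = manifest)
  if (!is.null(out_dir)) .writePipelineOutputs(result, out_dir, genotypes)
  result
}

.writePipelineOutputs <- function(result, out_dir, genotypes) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, wtsv(result$expression$de, "expression_de.tsv"))
  for (mk in names(result$density))
    files <- c(files, wtsv(result$density[[mk]]$per_gene,
                           sprintf("density_%s.tsv", mk)))
  for (gt in genotypes)
    files <- c(files, wtsv(result$pausing$tables[[gt]],
                           sprintf("pausing_%s.tsv", gt)))
  files <- c(files, wtsv(result$clusters$summaries, "cluster_summaries.tsv"))
  files <- c(files, wtsv(data.frame(peak = names(result$clusters$assignment$cluster),
                                    cluster = result$clusters$assignment$cluster),
                         "cluster_assignments.tsv"))
  se <- result$superenhancers
  if (length(se)) {
    sedf <- data.frame(chrom = as.character(seqnames(se)),
                       start = start(se) - 1L, end = end(se),
                       name = ifelse(se$is_super, "super", "stitched"),
                       score = se$total_signal, strand = ".")
    path <- file.path(out_dir, "superenhancers.bed")
    write.table(sedf, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files <- c(files, path)
  }
  if (!is.null(result$erna$report))
    files <- c(files, wtsv(result$erna$report, "erna_report.tsv"))
  norm_path <- file.path(out_dir, "normalization_factors.json")
  jsonlite::write_json(lapply(result$normalization, function(x)
    x[c("value", "n_regions", "mark")]), norm_path, auto_unbox = TRUE,
    digits = NA)
  files <- c(files, norm_path)
  manifest <- result$manifest
  manifest$files <- lapply(setNames(nm = basename(files)), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Summarize a pipeline run as headline tables
#'
#' Produces the run's headline numbers in one plain-text-friendly list:
#' deregulation class counts, median density fold change per mark, pausing
#' medians and fold change, per-cluster summaries, enrichment of
#' downregulated genes, superenhancer counts, and the eRNA report.
#'
#' @param result A [runPipeline()] result.
#' @return A named list of data.frames/vectors (printed with `print()`).
#' @export
makeReport <- function(result) {
  de <- result$expression$de
  list(
    deregulation = table(de$class),
    density_median_fc = vapply(result$density, function(x) x$median_fc,
                               numeric(1)),
    pausing = unlist(result$pausing$mut_vs_wt[c("median_a", "median_b",
                                                "ratio")]),
    cluster_summaries = result$clusters$summaries,
    down_gene_enrichment = result$clusters$down_enrichment,
    superenhancers = c(stitched = length(result$superenhancers),
                       super = sum(result$superenhancers$is_super)),
    erna_counts = c(regions = length(result$erna$regions),
                    ernas = length(result$erna$ernas)),
    erna_report = result$erna$report
  )
}

#' Measure recovery of the planted genotype effects from a pipeline run
#'
#' Compares what the pipeline measured against the effect sizes the
#' synthetic-data generator planted: median promoter/gene-body density fold
#' changes per mark, broad-class and narrow-class broadness ratios, the
#' pausing-index fold change, the eRNA log2 fold change, and the
#' two-cluster profile ordering (the broadest cluster must carry the highest
#' median expression and the lowest median pausing index).
#'
#' @param result A [runPipeline()] result.
#' @return A named list of recovered quantities (see Details in the
#'   vignette): `h3k9ac_promoter_fc`, `h3k27ac_promoter_fc`,
#'   `rnapii_promoter_fc`, `h3k4me1_body_fc`, `broad_broadness_ratio`,
#'   `narrow_broadness_change`, `pausing_fc`, `erna_log2fc`,
#'   `broadest_cluster_rpk_ok`, `broadest_cluster_pi_ok`.
#' @export
recoverPlantedEffects <- function(result) {
  gd <- result$dataset$truth$genes
  wt <- result$manifest$genotypes[1L]
  broad <- gd$gene_id[gd$class == "broad_identity"]
  narrow <- gd$gene_id[gd$class == "narrow_housekeeping"]
  bro <- result$clusters$broadness
  mut_gt <- setdiff(names(bro), wt)[1L]
  bwv <- setNames(bro[[wt]]$broadness_bp, bro[[wt]]$gene_id)
  bmv <- setNames(bro[[mut_gt]]$broadness_bp, bro[[mut_gt]]$gene_id)
  ratio_for <- function(ids) {
    ids <- ids[ids %in% names(bwv) & bwv[ids] > 0]
    median(bmv[ids] / bwv[ids], na.rm = TRUE)
  }
  # planted two-shape ordering, clustered at the planted k = 2
  a2 <- kmeansProfiles(result$clusters$matrix, k = 2,
                       seed = result$manifest$seed)
  s2 <- clusterSummaries(a2, result$clusters$peak_genes,
                         rpk = result$expression$wt_mean_rpk,
                         pi_table = result$pausing$tables[[wt]])
  list(
    h3k9ac_promoter_fc = result$density$H3K9ac$median_fc,
    h3k27ac_promoter_fc = result$density$H3K27ac$median_fc,
    rnapii_promoter_fc = result$density$RNAPII$median_fc,
    h3k4me1_body_fc = result$density$H3K4me1$median_fc,
    broad_broadness_ratio = ratio_for(broad),
    narrow_broadness_change = ratio_for(narrow) - 1,
    pausing_fc = result$pausing$mut_vs_wt$ratio_raw,
    erna_log2fc = if (is.null(result$erna$report)) NA_real_ else
      median(result$erna$report$log2fc, na.rm = TRUE),
    broadest_cluster_rpk_ok = s2$median_rpk[2] == max(s2$median_rpk),
    broadest_cluster_pi_ok = s2$median_pi[2] == min(s2$median_pi)
  )
}
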