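#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' two genotypes (WT and a mutant with globally reduced promoter
#' acetylation), four gene classes, and the planted genotype effect sizes.
#' Defaults mirror the biology being modelled: mutant/WT promoter density
#' factors 0.26 (H3K9ac), 0.60 (H3K27ac), 0.61 (RNAPII) and 1.09 (H3K4me1,
#' gene body); broad-domain shrinkage to 0.38 of the WT length on
#' broad-acetylation identity genes; a 1.3-fold increase in RNAPII pausing;
#' eRNA log2 fold change -1.2; 4 WT and 3 mutant RNA-seq replicates.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param n_chroms,chrom_length Genome layout (default 2 x 3 Mb).
#' @param n_genes Named counts per class: `broad_identity` (broad acetylation
#'   domain over the full gene body + 2 kb upstream, high expression, low
#'   pausing), `narrow_housekeeping` and `other_expressed` (narrow TSS +/-
#'   300 bp acetylation), `silent`.
#' @param gene_length Named list of (min, max) gene lengths per class.
#' @param min_spacing Minimum intergenic gap between genes (default 20 kb).
#' @param chip_reads Reads per ChIP library (each mark, each genotype).
#' @param promoter_density_factor Named mutant/WT intensity factors per mark.
#' @param broadness_factor Mutant broad-domain length fraction (default 0.38),
#'   TSS-proximal edge kept fixed.
#' @param pausing_factor Mutant/WT pausing-index fold change (default 1.3).
#' @param pausing_level Named WT promoter:body density ratio per class.
#' @param acetyl_intensity Named per-bp domain enrichment (x background) for
#'   acetylation marks per class.
#' @param body_intensity Named per-bp RNAPII gene-body enrichment per class.
#' @param k4me1_intensity Per-bp H3K4me1 gene-body enrichment (all expressed
#'   classes).
#' @param expr_mean_rpk Named WT expression means per class (RPK scale).
#' @param expr_mut_factor Named mutant/WT expression mean factors per class.
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param n_wt,n_mut RNA-seq replicates per genotype (default 4 and 3).
#' @param erna_mean_reads Mean eRNA reads per broad-class locus per replicate.
#' @param erna_log2fc Mutant/WT eRNA log2 fold change (default -1.2).
#' @param rna_noise_reads Uniform background RNA reads per replicate.
#' @param rna_split_fraction Fraction of genic RNA reads flagged split-mapped.
#' @param read_length Simulated read length (default 50 bp).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1,
                      n_chroms = 2,
                      chrom_length = 3e6,
                      n_genes = c(broad_identity = 25,
                                  narrow_housekeeping = 40,
                                  other_expressed = 40,
                                  silent = 25),
                      gene_length = list(broad_identity = c(12000, 18000),
                                         narrow_housekeeping = c(4000, 8000),
                                         other_expressed = c(4000, 8000),
                                         silent = c(4000, 8000)),
                      min_spacing = 20000,
                      chip_reads = 2e5,
                      promoter_density_factor = c(H3K9ac = 0.26,
                                                  H3K27ac = 0.60,
                                                  RNAPII = 0.61,
                                                  H3K4me1 = 1.09),
                      broadness_factor = 0.38,
                      pausing_factor = 1.3,
                      pausing_level = c(broad_identity = 2,
                                        narrow_housekeeping = 10,
                                        other_expressed = 10,
                                        silent = 0),
                      acetyl_intensity = c(broad_identity = 8,
                                           narrow_housekeeping = 60,
                                           other_expressed = 40,
                                           silent = 0),
                      body_intensity = c(broad_identity = 25,
                                         narrow_housekeeping = 20,
                                         other_expressed = 15,
                                         silent = 0),
                      k4me1_intensity = 4,
                      expr_mean_rpk = c(broad_identity = 200,
                                        narrow_housekeeping = 25,
                                        other_expressed = 10,
                                        silent = 0.02),
                      expr_mut_factor = c(broad_identity = 0.4,
                                          narrow_housekeeping = 1,
                                          other_expressed = 1,
                                          silent = 1),
                      dispersion = 0.05,
                      n_wt = 4, n_mut = 3,
                      erna_mean_reads = 200,
                      erna_log2fc = -1.2,
                      rna_noise_reads = 2000,
                      rna_split_fraction = 0.02,
                      read_length = 50) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(n_genes) > 0), chip_reads > 0,
            all(promoter_density_factor > 0), broadness_factor > 0,
            pausing_factor > 0, dispersion > 0, n_wt >= 1, n_mut >= 1)
  class(cfg) <- "SimConfig"
  cfg
}

.simClasses <- c("broad_identity", "narrow_housekeeping", "other_expressed",
                 "silent")
.simMarks <- c("H3K9ac", "H3K27ac", "H3K4me1", "RNAPII", "input")

# Deterministic sub-seed derivation, kept below 2^31.
.deriveSeed <- function(base, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(base) * 7919 + h) %% .Machine$integer.max)
}

#' Simulate the genome layout and planted truth
#'
#' Places non-overlapping genes (>= `min_spacing` apart) of the four classes
#' on the configured chromosomes, assigns strands, and derives the planted
#' truth: per-gene acetylation domains (full gene body + 2 kb upstream for
#' the broad class, TSS +/- 300 bp for narrow classes), eRNA intervals (at
#' broad-class loci, antisense transcription so the dUTP reads land on the
#' gene's strand), and per-genotype expression means. Deterministic given
#' the config seed.
#'
#' @param config A [simConfig()].
#' @return A list: `annotation` ([GenomeAnnotation]) and `truth` (list with
#'   `genes` data.frame, `domains`, `erna` GRanges, `config`).
#' @export
simulateGenome <- function(config = simConfig()) {
  set.seed(.deriveSeed(config$seed, "genome"))
  sl <- setNames(rep(config$chrom_length, config$n_chroms),
                 paste0("chr", seq_len(config$n_chroms)))
  classes <- rep(names(config$n_genes), config$n_genes)
  classes <- sample(classes)  # interleave classes along the genome
  n <- length(classes)
  lens <- vapply(classes, function(cl) {
    rng <- config$gene_length[[cl]]
    round(runif(1, rng[1], rng[2]))
  }, numeric(1))
  # sequential placement with randomized gaps
  gaps <- config$min_spacing + round(runif(n, 0, 0.6 * config$min_spacing))
  chrom <- character(n); start <- numeric(n)
  cur_chrom <- 1L; cur_pos <- 1
  for (i in seq_len(n)) {
    cur_pos <- cur_pos + gaps[i]
    if (cur_pos + lens[i] + config$min_spacing > sl[cur_chrom]) {
      cur_chrom <- cur_chrom + 1L
      if (cur_chrom > length(sl))
        stop("genes do not fit: need roughly ",
             sum(lens + gaps) + n * config$min_spacing,
             " bp of genome, have ", sum(sl))
      cur_pos <- 1 + gaps[i]
    }
    chrom[i] <- names(sl)[cur_chrom]
    start[i] <- cur_pos
    cur_pos <- cur_pos + lens[i]
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("gene%03d", seq_len(n))
  g <- GRanges(chrom, IRanges(start, width = lens), strand = strand)
  seqlevels(g) <- names(sl)
  seqlengths(g) <- sl
  g$gene_id <- gene_id
  g$biotype <- "protein_coding"
  g$median_tx_len <- width(g)
  exons <- granges(g)
  exons$gene_id <- gene_id
  annotation <- GenomeAnnotation(g, exons = exons)

  plus <- strand == "+"
  tss <- ifelse(plus, start, start + lens - 1)
  genes_df <- data.frame(gene_id = gene_id, class = classes, chrom = chrom,
                         start = start, end = start + lens - 1,
                         strand = strand, tss = tss,
                         tts = ifelse(plus, start + lens - 1, start),
                         length = lens, stringsAsFactors = FALSE)

  # planted acetylation domains
  dom_start <- ifelse(classes == "broad_identity",
                      ifelse(plus, start - 2000, start),
                      tss - 300)
  dom_end <- ifelse(classes == "broad_identity",
                    ifelse(plus, start + lens - 1, start + lens - 1 + 2000),
                    tss + 299)
  keep <- classes != "silent"
  domains <- GRanges(chrom[keep],
                     IRanges(pmax(1, dom_start[keep]),
                             pmin(sl[chrom[keep]], dom_end[keep])),
                     strand = strand[keep])
  seqlevels(domains) <- names(sl)
  seqlengths(domains) <- sl
  domains$gene_id <- gene_id[keep]
  domains$class <- classes[keep]

  # eRNA loci at broad-class genes: antisense transcript over the TSS-proximal
  # enhancer region; dUTP reads map on the gene's strand
  bi <- which(classes == "broad_identity")
  er_start <- ifelse(plus[bi], tss[bi] - 1500, tss[bi] - 5999)
  er_end <- ifelse(plus[bi], tss[bi] + 6000, tss[bi] + 1500)
  erna <- GRanges(chrom[bi],
                  IRanges(pmax(1, er_start), pmin(sl[chrom[bi]], er_end)),
                  strand = strand[bi])
  seqlevels(erna) <- names(sl)
  seqlengths(erna) <- sl
  erna$gene_id <- gene_id[bi]

  truth <- list(genes = genes_df, domains = domains, erna = erna,
                chrom_sizes = sl, config = config)
  list(annotation = annotation, truth = truth)
}

# Draw n uniform read positions (width rl) with the read interval contained
# in [lo, hi]; strands sampled uniformly unless given.
.placeReads <- function(n, chrom, lo, hi, rl, sl, strand = NULL) {
  if (n <= 0) {
    gr <- GRanges()
    seqlevels(gr) <- names(sl)
    seqlengths(gr) <- sl
    return(gr)
  }
  lo <- max(1, lo); hi <- min(sl[chrom], hi)
  smax <- max(lo, hi - rl + 1)
  s <- floor(runif(n, lo, smax + 1))
  s <- pmin(s, sl[chrom] - rl + 1)  # keep the read on the chromosome
  if (is.null(strand)) strand <- sample(c("+", "-"), n, replace = TRUE)
  gr <- GRanges(chrom, IRanges(s, width = rl), strand = strand)
  seqlevels(gr) <- names(sl)
  seqlengths(gr) <- sl
  gr
}

# Component weight table for one ChIP mark/genotype; weight is intensity x
# width in background units (background per-bp intensity = 1).
.chipComponents <- function(truth, mark, genotype, config) {
  gd <- truth$genes
  sl <- truth$chrom_sizes
  mutant <- genotype != "WT"
  f <- if (mutant && mark %in% names(config$promoter_density_factor))
    config$promoter_density_factor[[mark]] else 1
  comp <- list()
  add <- function(chrom, lo, hi, intensity, contained = FALSE) {
    comp[[length(comp) + 1L]] <<- list(chrom = chrom, lo = lo, hi = hi,
                                       weight = intensity * (hi - lo + 1),
                                       contained = contained)
  }
  if (mark %in% c("H3K9ac", "H3K27ac")) {
    dom <- truth$domains
    for (i in seq_along(dom)) {
      cls <- dom$class[i]
      lo <- start(dom)[i]; hi <- end(dom)[i]
      if (mutant && cls == "broad_identity") {
        # shrink towards the TSS-proximal (upstream) edge
        newlen <- round(config$broadness_factor * (hi - lo + 1))
        if (as.logical(strand(dom)[i] == "+")) hi <- lo + newlen - 1
        else lo <- hi - newlen + 1
        # total domain weight scales by f over the shrunk length
        add(as.character(seqnames(dom))[i], lo, hi,
            f * config$acetyl_intensity[[cls]] / config$broadness_factor)
        next
      }
      add(as.character(seqnames(dom))[i], lo, hi,
          f * config$acetyl_intensity[[cls]])
    }
  } else if (mark == "H3K4me1") {
    for (i in seq_len(nrow(gd))) {
      if (gd$class[i] == "silent") next
      add(gd$chrom[i], gd$start[i], gd$end[i], f * config$k4me1_intensity)
    }
  } else if (mark == "RNAPII") {
    f_body <- if (mutant) f / config$pausing_factor else 1
    for (i in seq_len(nrow(gd))) {
      cls <- gd$class[i]
      if (cls == "silent") next
      bi <- config$body_intensity[[cls]]
      plus <- gd$strand[i] == "+"
      tss <- gd$tss[i]
      p_lo <- if (plus) tss - 30 else tss - 300
      p_hi <- if (plus) tss + 300 else tss + 30
      b_lo <- if (plus) tss + 301 else gd$start[i]
      b_hi <- if (plus) gd$end[i] else tss - 301
      add(gd$chrom[i], p_lo, p_hi, f * config$pausing_level[[cls]] * bi,
          contained = TRUE)
      if (b_hi > b_lo) add(gd$chrom[i], b_lo, b_hi, f_body * bi)
    }
  } else if (mark != "input") {
    stop("unknown mark: ", mark)
  }
  comp
}

#' Simulate one ChIP library
#'
#' Reads are a mixture of uniform genome-wide background and enrichment over
#' the planted domains; the library has exactly `config$chip_reads` reads.
#' Mutant libraries scale domain weights by the per-mark factor (background
#' weight unchanged, so the intergenic normalization has the same job it has
#' on real data), shrink broad-class acetylation domains to
#' `broadness_factor` of their WT length (TSS-proximal edge fixed), and scale
#' the RNAPII promoter component by the pausing factor relative to the body.
#' Input libraries are background only.
#'
#' @param truth Truth list from [simulateGenome()].
#' @param mark One of H3K9ac, H3K27ac, H3K4me1, RNAPII, input.
#' @param genotype "WT" or any other label (treated as mutant).
#' @param config The [simConfig()] used for the genome.
#' @return GRanges of reads (`split_mapped = FALSE`).
#' @export
simulateChipReads <- function(truth, mark, genotype, config = truth$config) {
  if (!mark %in% .simMarks) stop("unknown mark: ", mark)
  set.seed(.deriveSeed(config$seed, "chip", mark, genotype))
  sl <- truth$chrom_sizes
  comp <- .chipComponents(truth, mark, genotype, config)
  weights <- c(sum(as.numeric(sl)), vapply(comp, `[[`, numeric(1), "weight"))
  n_per <- as.vector(stats::rmultinom(1, config$chip_reads,
                                      weights / sum(weights)))
  rl <- config$read_length
  out <- vector("list", length(comp) + 1L)
  # background: chromosomes by length, then uniform
  nbg <- n_per[1L]
  bg_chrom <- sample(names(sl), nbg, replace = TRUE,
                     prob = as.numeric(sl) / sum(as.numeric(sl)))
  bg <- lapply(names(sl), function(ch) {
    k <- sum(bg_chrom == ch)
    .placeReads(k, ch, 1, sl[ch], rl, sl)
  })
  out[[1L]] <- do.call(c, bg)
  for (i in seq_along(comp)) {
    cm <- comp[[i]]
    k <- n_per[i + 1L]
    if (cm$contained) {
      # paused-polymerase component: keep the extended 200 bp footprint
      # inside the window so the 5' signal does not bleed into the body
      strands <- sample(c("+", "-"), k, replace = TRUE)
      kp <- sum(strands == "+")
      gp <- .placeReads(kp, cm$chrom, cm$lo, cm$hi - 200 + rl, rl, sl,
                        strand = rep("+", kp))
      gm <- .placeReads(k - kp, cm$chrom, cm$lo + 200 - rl, cm$hi, rl, sl,
                        strand = rep("-", k - kp))
      out[[i + 1L]] <- c(gp, gm)
    } else {
      out[[i + 1L]] <- .placeReads(k, cm$chrom, cm$lo, cm$hi, rl, sl)
    }
  }
  reads <- do.call(c, out)
  reads$split_mapped <- FALSE
  sort(reads)
}

#' Simulate one genotype's stranded RNA-seq replicates
#'
#' Per replicate, gene counts are negative-binomial with class means on the
#' RPK scale times gene length (mutant means scaled by the class factor);
#' genic reads are placed within the gene with strand antisense to the gene
#' (dUTP first-strand convention), a small fraction flagged split-mapped.
#' eRNA reads are placed within the planted eRNA intervals on the gene's
#' strand (the eRNA transcript is antisense to the gene, so its dUTP reads
#' land on the gene strand), with mutant means scaled by `2^erna_log2fc`.
#' Uniform background noise reads are added on random strands.
#'
#' @param truth Truth list from [simulateGenome()].
#' @param genotype "WT" or mutant label.
#' @param config The [simConfig()].
#' @return A list: `reads` (list of GRanges, one per replicate), `counts`
#'   (gene x replicate integer matrix), `erna_counts` (locus x replicate).
#' @export
simulateRnaReads <- function(truth, genotype, config = truth$config) {
  set.seed(.deriveSeed(config$seed, "rna", genotype))
  gd <- truth$genes
  sl <- truth$chrom_sizes
  mutant <- genotype != "WT"
  n_rep <- if (mutant) config$n_mut else config$n_wt
  mu_gene <- config$expr_mean_rpk[gd$class] * gd$length / 1000
  if (mutant) mu_gene <- mu_gene * config$expr_mut_factor[gd$class]
  mu_erna <- rep(config$erna_mean_reads, length(truth$erna))
  if (mutant) mu_erna <- mu_erna * 2^config$erna_log2fc
  size <- 1 / config$dispersion
  rl <- config$read_length
  counts <- matrix(0L, nrow(gd), n_rep,
                   dimnames = list(gd$gene_id, paste0(genotype, seq_len(n_rep))))
  erna_counts <- matrix(0L, length(truth$erna), n_rep,
                        dimnames = list(truth$erna$gene_id, colnames(counts)))
  reads <- vector("list", n_rep)
  anti <- ifelse(gd$strand == "+", "-", "+")
  for (r in seq_len(n_rep)) {
    cg <- rnbinom(nrow(gd), mu = mu_gene, size = size)
    ce <- rnbinom(length(mu_erna), mu = mu_erna, size = size)
    counts[, r] <- cg
    erna_counts[, r] <- ce
    genic <- lapply(which(cg > 0), function(i)
      .placeReads(cg[i], gd$chrom[i], gd$start[i], gd$end[i], rl, sl,
                  strand = rep(anti[i], cg[i])))
    ern <- lapply(which(ce > 0), function(i)
      .placeReads(ce[i], as.character(seqnames(truth$erna))[i],
                  start(truth$erna)[i], end(truth$erna)[i], rl, sl,
                  strand = rep(as.character(strand(truth$erna))[i], ce[i])))
    noise_chrom <- sample(names(sl), config$rna_noise_reads, replace = TRUE,
                          prob = as.numeric(sl) / sum(as.numeric(sl)))
    noise <- lapply(names(sl), function(ch)
      .placeReads(sum(noise_chrom == ch), ch, 1, sl[ch], rl, sl))
    rr <- do.call(c, c(genic, ern, noise))
    rr$split_mapped <- runif(length(rr)) < config$rna_split_fraction
    reads[[r]] <- sort(rr)
  }
  list(reads = reads, counts = counts, erna_counts = erna_counts)
}

#' Simulate the full two-genotype dataset
#'
#' Runs [simulateGenome()], [simulateChipReads()] for every mark and
#' genotype, and [simulateRnaReads()] for both genotypes; optionally writes
#' everything to disk (BED6 reads per mark/genotype, counts TSV, GTF,
#' chrom-sizes TSV, truth JSON).
#'
#' @param config A [simConfig()].
#' @param dir Optional output directory; created if needed.
#' @param genotypes Genotype labels (first is WT; default `c("WT", "SCA7")`).
#' @return A list: `annotation`, `truth`, `chip` (nested list
#'   mark -> genotype -> GRanges), `rna` (genotype -> simulateRnaReads()
#'   output), `counts` (combined gene x sample matrix), `genotype_of_sample`.
#' @export
simulateDataset <- function(config = simConfig(), dir = NULL,
                            genotypes = c("WT", "SCA7")) {
  sim <- simulateGenome(config)
  chip <- lapply(setNames(nm = .simMarks), function(mark)
    lapply(setNames(nm = genotypes), function(gt)
      simulateChipReads(sim$truth, mark, gt, config)))
  rna <- lapply(setNames(nm = genotypes), function(gt)
    simulateRnaReads(sim$truth, gt, config))
  counts <- do.call(cbind, lapply(genotypes, function(gt) rna[[gt]]$counts))
  genotype_of_sample <- rep(genotypes, vapply(rna, function(x)
    ncol(x$counts), integer(1)))
  out <- list(annotation = sim$annotation, truth = sim$truth, chip = chip,
              rna = rna, counts = counts,
              genotype_of_sample = genotype_of_sample)
  if (!is.null(dir)) .writeDataset(out, dir, genotypes)
  out
}

.writeDataset <- function(ds, dir, genotypes) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sl <- chromSizes(ds$annotation)
  write.table(data.frame(names(sl), as.integer(sl)),
              file.path(dir, "chrom_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  .writeGtf(ds$annotation, file.path(dir, "annotation.gtf"))
  for (mark in names(ds$chip))
    for (gt in genotypes)
      writeBedReads(ds$chip[[mark]][[gt]],
                    file.path(dir, sprintf("chip_%s_%s.bed", mark, gt)))
  for (gt in genotypes)
    for (r in seq_along(ds$rna[[gt]]$reads))
      writeBedReads(ds$rna[[gt]]$reads[[r]],
                    file.path(dir, sprintf("rna_%s_rep%d.bed", gt, r)))
  counts_out <- data.frame(gene_id = rownames(ds$counts), ds$counts,
                           check.names = FALSE)
  write.table(counts_out, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  jsonlite::write_json(
    list(genes = truth$genes,
         domains = as.data.frame(truth$domains),
         erna = as.data.frame(truth$erna),
         config = truth$config[setdiff(names(truth$config), "gene_length")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Minimal Ensembl-dialect GTF writer (gene/transcript/exon rows).
.writeGtf <- function(annotation, path) {
  g <- genes(annotation)
  mkattr <- function(id, tx = NULL) {
    a <- sprintf('gene_id "%s"; gene_biotype "%s";', id,
                 g$biotype[match(id, g$gene_id)])
    if (!is.null(tx)) a <- paste0(a, sprintf(' transcript_id "%s";', tx))
    a
  }
  rows <- character(0)
  for (i in seq_along(g)) {
    ch <- as.character(seqnames(g))[i]; s <- start(g)[i]; e <- end(g)[i]
    st <- as.character(strand(g))[i]; id <- g$gene_id[i]
    tx <- paste0(id, ".t1")
    rows <- c(rows,
      paste(ch, "sim", "gene", s, e, ".", st, ".", mkattr(id), sep = "\t"),
      paste(ch, "sim", "transcript", s, e, ".", st, ".", mkattr(id, tx),
            sep = "\t"),
      paste(ch, "sim", "exon", s, e, ".", st, ".", mkattr(id, tx), sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
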