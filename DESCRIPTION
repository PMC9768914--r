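Package: broadAcetyl
Title: Broad Histone Acetylation Domains, RNAPII Pausing and Enhancer RNAs
    in Retinal ChIP-seq/RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated re-analysis toolkit for paired ChIP-seq and
    stranded total RNA-seq of two-genotype (wild-type versus mutant) mouse
    retina. Computes intergenic-normalized occupancy densities for histone
    acetylation marks and RNAPII, RNAPII pausing indices, a Poisson-window
    island caller for broad acetylation domains, peak-profile k-means
    clustering around peak centers, hypergeometric/observed-expected
    gene-set and binding-site enrichment per cluster, ROSE-style
    superenhancer stitching with coverage-fraction intersection, and a
    strand-aware enhancer-RNA detection workflow for dUTP libraries. Ships a
    deterministic synthetic-data generator that plants gene classes (broad
    acetylation identity genes, narrow housekeeping promoters), genotype
    effect sizes and antisense eRNA transcription so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    DESeq2,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
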