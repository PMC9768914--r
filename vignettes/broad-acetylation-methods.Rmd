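---
title: "Methods: broad acetylation domains, RNAPII pausing, and eRNAs"
author: "broadAcetyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: broad acetylation domains, RNAPII pausing, and eRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cell-identity genes of rod photoreceptors are transcribed at extreme levels
and carry a distinctive chromatin signature: H3K9ac and H3K27ac domains that
are not confined to a narrow promoter peak but spread across the entire gene
body, flanking superenhancers, antisense enhancer RNAs (eRNAs), and a low
RNAPII promoter-proximal pausing index. When histone-acetyltransferase
activity is impaired (as in SCA7 retina, where polyQ-expanded ATXN7
compromises SAGA), promoter acetylation drops genome-wide, but the *broad*
domains shrink preferentially and the identity genes they mark are
downregulated. Quantifying that chain — densities, pausing, broadness,
cluster structure, superenhancers, eRNAs — requires a pipeline of a dozen
interlocking conventions. This package implements each stage explicitly and
validates the whole chain against a synthetic dataset in which every effect
size is planted and therefore known.

# Occupancy densities and the intergenic normalization

Reads are extended to 200 bp in the read direction (never shrunk — a longer
read is better evidence, not worse), and a region's raw density is

$$\mathrm{density} = \frac{n / L_{\mathrm{Mb}}}{N \times 10^{-8}},$$

with `n` the number of extended reads overlapping the region by at least
1 bp, `L` the region length in Mb, and `N` the library size. The printed
form of this expression is ambiguous about whether the $10^{-8}$ multiplies
`N` or the whole quotient; any consistent reading rescales every density by
a constant that cancels in all fold changes and pausing indices, so we fix
the reading that gives an interpretable unit — reads per Mb per $10^8$
library reads. The overlap rule (≥ 1 bp of the extended read, counted once)
is likewise a convention; the alternative (5′-end containment) changes
nothing downstream because it, too, cancels in ratios.

Bulk acetylation differs between genotypes, so equal sequencing depth does
not mean equal per-read occupancy. The intergenic normalization factor is
the median over intergenic regions of the mutant/WT density ratio; WT
densities are multiplied by it, which forces the median intergenic fold
change to exactly 1 and makes promoter fold changes interpretable. Regions
with zero WT density are excluded (the ratio is undefined); at least 20
usable regions are required; intergenic regions shorter than 1 kb are
discarded as degenerate.

One adjustment is specific to desk-scale simulated genomes:
`deriveIntergenicRegions(gene_buffer = )` can trim a buffer from each end of
every intergenic region. The simulation places the TSS at the gene-span
boundary, so promoter and broad-domain signal straddles into the adjacent
intergenic region; on a 6 Mb genome that contamination is a visible share of
each ~25 kb region and biases the median fold change. The pipeline uses a
2.5 kb buffer (2 kb upstream-domain extension + 200 bp read smear + margin).
On genome-scale data promoters are a vanishing fraction of intergenic
length, and the default buffer of 0 reproduces the plain gene-span
complement.

# RNAPII pausing index

$$\mathrm{PI} = \frac{\text{density(TSS−30..TSS+300)}}{\text{density(TSS+301..TTS−300)}}$$

strand-aware, computed from raw (pre-normalization) densities so WT and
mutant are treated identically — library size and the normalization constant
cancel. Genes shorter than 602 bp have no body window and are skipped. Genes
with 5′ signal but zero body density are reported as `fully_paused` rather
than given an infinite index, and excluded from medians (the treatment of
zero-body genes is our convention; excluding them biases no between-genotype
comparison because the rule is genotype-blind).

Counting convention: the pausing windows are short (330 bp), so counting any
overlap of a 200 bp extended fragment would inflate the 5′ window density by
roughly the fragment length — uniform coverage would yield PI ≈ 1.6, not 1.
`pausingIndex` therefore counts extended fragments by their midpoint, which
makes the PI of uniform coverage exactly 1 and leaves every fold-change
comparison unchanged in expectation.

# Island calling

A single Poisson-window detector stands in for the external island/peak
callers, parametrized by their published settings: 200 bp windows, 600 bp
merge gap, per-bin upper-tail threshold $10^{-2}$ (acetylation marks) or
$10^{-4}$ with uniform background and no duplicate collapsing (the
RNA-residue mode). A bin is eligible when its extended-read count exceeds
the Poisson tail at the control-scaled expected count, floored at the
control's chromosome-wide mean (with no control, the ChIP library's own
chromosome mean — conservative, since enrichment inflates it). Eligible bins
at most `gap` bp apart merge into one island. Identical read intervals are
collapsed first (redundancy threshold 1). Externally called peaks can be
substituted as BED (`readPeaksBed`). The caller is verified bin-by-bin
against a brute-force enumeration oracle on 50 kb toy chromosomes.

Per-gene broadness is the summed length of the peaks annotated (by nearest
TSS at the peak midpoint) to the gene; a per-peak mode is available. The
genomic distribution of peaks assigns midpoints with precedence
promoter-TSS (−1 kb..+100 bp) > TTS (−100 bp..+1 kb) > distal promoter
(−20 kb..−1 kb) > exon > intron > intergenic; with single-exon gene models
(as simulated) the genic subfeatures reduce to exon, and UTRs — which
require CDS annotation — are folded into exon.

# Profile clustering

Each peak contributes a row of extended-read counts in 100 bins of 100 bp
covering its midpoint ± 5 kb (out-of-chromosome bins zero-filled), linearly
scaled to row maximum 1 so the clustering sees shape, not height. k-means
uses k-means++ seeding, Lloyd iterations, and 20 restarts keeping the lowest
within-cluster sum of squares, under a fixed seed. Because the native label
order of k-means is arbitrary, labels are renumbered by mean-profile breadth
(bins ≥ 0.25 of the profile maximum), so cluster *k* is always the broadest
and can be addressed deterministically.

The genome-scale default is k = 10. The synthetic generator, however,
plants exactly two profile shapes (narrow TSS peak vs gene-body plateau), so
at k = 10 the plateau group is split into exchangeable sub-clusters and
"the broadest cluster" among them is arbitrary. Recovery checks therefore
cluster the simulated peaks at the planted k = 2, where the expected
ordering — broadest cluster has the highest median expression and the lowest
median pausing index — is deterministic.

# Enrichment, superenhancers, coverage fractions

Gene-set enrichment per cluster is observed/expected with
`expected = |category ∩ universe| × |cluster| / |universe|` and a
hypergeometric tail (upper for enrichment, lower for depletion). Summed over
a partition, observed counts equal the category size and the
expected-weighted mean of ratios is exactly 1. For *interval* features
(binding sites assigned to cluster windows by midpoint; ties to the nearest
window center, then the lower label), the features are independent
placements rather than draws from a finite set, so the exact null is
binomial with success probability the cluster's window share; the tail test
is binomial accordingly.

Superenhancers: peaks fully inside TSS ± 2 kb are removed, the rest stitched
at ≤ 12.5 kb, stitched regions ranked by total background-subtracted signal
(peak read count minus length-scaled control, floored at 0), and the
hockey-stick cutoff applied — on the rank/signal curve scaled to the unit
square, regions above the point where a slope-1 line is tangent are super.
The implementation scans every candidate tangent point and minimizes the
number of curve points below the line; discrete ties between the two points
straddling the continuous tangent are broken to the right (the point where
the scaled slope reaches 1). Note that on the simulated genome all stitched
regions are strong broad domains — there is no weak typical-enhancer tail —
so most stitched regions rank as super; the hockey stick only becomes
selective with a realistic signal continuum.

Coverage fractions follow bedtools `intersect -f` semantics: the fraction of
a query covered by the union of the subject set, with the predicate
`fraction ≥ 0.5` (inclusive, matching the tool even where prose says "more
than 50%").

# Expression

Size factors are median-of-ratios (reference: per-gene geometric mean over
genes with all-positive counts). RPK divides normalized counts by the median
transcript length in kb. A gene is expressed when RPK ≥ 1 in *every* WT
sample (inclusive boundary). Deregulation uses strict inequalities: down if
FC < 0.7 and adjusted p < 0.05; up if FC > 1.3 and adjusted p < 0.05. FC is
the ratio of means of size-factor-normalized counts (lengths cancel).

Negative-binomial Wald testing is out of scope; adjusted p-values are either
supplied externally or produced by a documented stand-in on
log2(normalized counts + 1). The default stand-in is a variance-moderated
t-test (limma's empirical Bayes), chosen because at 4-vs-3 replicates and
dispersion 0.05 a plain per-gene t-test has only ~0.77 sensitivity for a
planted FC of 0.4, while variance moderation restores ~0.99 — the property
the pipeline needs to classify the planted downregulated class reliably. The
plain t-test remains available (`method = "ttest"`).

A known, faithful artifact: when a large fraction of genes is strongly DE in
one direction (25 of 105 reference genes at FC 0.4 in the simulation),
median-of-ratios factors shift (~+9% WT, −5% mutant), which attenuates all
measured fold changes by ~15% of their log — the simulated eRNA log2FC reads
≈ −1.0 rather than the planted −1.2. Genome-scale data with a smaller DE
share exhibit proportionally less of this classic normalization bias.

# eRNA workflow

Filtering removes (1) split-mapped reads and (2) reads overlapping ≥ 1 bp of
the extended region (3 kb upstream of the TSS to 10 kb downstream of the
TTS) of a gene in the excluded-biotype list (coding genes, pseudogene
classes, rRNA, Mt/IG/TR classes) **when the read's strand is opposite to the
gene's strand**. The strand rule is the workflow's central interpretive
decision: under the dUTP protocol, sequenced reads map antisense to their
transcript, so a gene's own mRNA reads carry the opposite strand and rule 2
removes exactly them, leaving transcription antisense to, or outside,
annotated genes. The inverse reading is preserved behind
`convention = "inverse"`. The two rules commute and the filter is
idempotent.

Transcribed regions are detected per strand by the island caller in its
uniform-background, keep-duplicates mode at $p = 10^{-4}$. A region is an
eRNA when ≥ 50% covered by H3K9ac peaks *and* ≥ 50% by H3K27ac peaks.
Candidates annotate to the nearest TSS; the deregulation report counts
filtered reads on the candidate's strand per replicate, tests with the
stand-in, pairs each eRNA with its gene's mRNA fold change, and flags
concordant downregulation (both log2FC < 0 at adjusted p < 0.05).

# The synthetic-data generator

`simConfig()` fixes the study conditions: 2 chromosomes × 3 Mb; 130 genes in
four classes — 25 broad-identity (12–18 kb), 40 narrow-housekeeping, 40
other-expressed, 25 silent (4–8 kb) — placed ≥ 20 kb apart; 2 × 10^5 reads
per ChIP library per genotype; 4 WT / 3 mutant RNA replicates,
negative-binomial counts at dispersion 0.05 with class means on the RPK
scale of 200 / 25 / 10 / 0.02 (preserving the ~8× identity-vs-housekeeping
and ~20× identity-vs-other contrasts of real retina).

Planted genotype effects mirror the biology under study: mutant/WT promoter
density factors 0.26 (H3K9ac), 0.60 (H3K27ac), 0.61 (RNAPII) and 1.09 for
H3K4me1 gene bodies; broad-class acetylation domains shrink to 0.38 of
their WT length with the TSS-proximal edge fixed (loss of gene-body
spreading, not of the promoter peak); RNAPII pausing increases 1.3-fold
(promoter component × 0.61, body × 0.61/1.3 — the unique weight assignment
that realizes the promoter density factor and the pausing fold change
simultaneously); broad-class expression falls to 0.4; eRNA transcription
falls by log2FC −1.2.

ChIP reads are drawn from a mixture of uniform background (weight = genome
length) and enrichment domains with per-bp intensities, in background units:
broad acetylation domains 8×, narrow promoters 60× (H3K9ac/H3K27ac; 40× for
the other-expressed class), H3K4me1 gene bodies 4×, RNAPII bodies 15–25×
with the promoter at `pausing_level` (2 for identity genes, 10 for others)
times the body. These intensities are set high enough that island detection
is saturated — peak extent, not height, determines measured broadness — and
that background contributes little to body densities; at weaker settings the
generator fails its own contract that every planted effect size be
recoverable by the downstream stages. Mutant libraries scale domain weights
by the per-mark factor while background weight is unchanged, and each
library is drawn multinomially at its exact configured total: raw count
ratios are therefore slightly above the planted factor and the intergenic
normalization factor (> 1) restores it — the same job the normalization does
on real data, where ChIP efficiency tracks bulk acetylation.

RNA reads are placed within gene spans antisense to the gene (dUTP), with
2% flagged split-mapped; eRNA reads land in the planted antisense-transcript
interval (TSS −1.5 kb to TSS +6 kb in gene orientation) on the gene's
strand; a small uniform noise component (2,000 reads/replicate) exercises
the filters.

What the generator does *not* emulate: mapping artifacts and blacklist
regions, fragment-length variation, GC and accessibility bias, transcript
isoforms and UTRs (single-exon gene models), replicate-level ChIP
variability (one library per mark/genotype), bidirectional eRNA pairs, and a
continuum of enhancer strengths. Passing recovery tests therefore validates
the pipeline's arithmetic, conventions, and statistical wiring — not
robustness to alignment artifacts or annotation noise.

# Determinism and problem sizes

Every stochastic step derives its seed from the config seed (sub-seeds are
hashed per mark/genotype below 2^31), so simulated datasets and full
pipeline runs are byte-identical across runs. The test suite exercises unit
fixtures plus a reduced simulation (32 genes, 6 × 10^4 reads/library); the
planted-recovery checks and `scripts/acceptance.R` run the default
conditions on three seeds (~35 s per seed on one CPU). Tolerances for the
recovery checks are 20% for density factors and the pausing fold change,
± 0.1 absolute for broadness ratios, and 25% for the eRNA log2FC.

# Known limitations

* The island caller is a stand-in: it reproduces the window/gap/threshold
  semantics of the published settings but not SICER's E-value island scoring
  or model-based shift estimation; externally called peaks drop in via BED.
* Nearest-TSS annotation uses one TSS per gene (the 5' end of the gene
  span); multi-TSS genes are not modelled, and exact midpoint ties are
  broken deterministically by (chromosome, TSS, gene id).
* The feature-level enrichment p-value is binomial, not hypergeometric (see
  above); for gene sets the hypergeometric is exact.
* The hockey-stick cutoff needs ≥ 3 stitched regions and a signal continuum
  to be meaningful; on flat signal vectors most regions rank as super.
* The stand-in DE test operates on log-transformed normalized counts; it is
  a pragmatic replacement for, not a re-implementation of,
  negative-binomial inference.
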