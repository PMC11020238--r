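---
title: "Building and annotating a multi-tissue transcriptome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and annotating a multi-tissue transcriptome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txatlas)
```

## Overview

txatlas rebuilds the computational core of a multi-tissue transcriptome
annotation effort of the kind carried out for livestock genomes: assembled
transcript models from dozens of tissues are quality-filtered, collapsed
into a non-redundant catalogue, classified into biotypes from their ORF
structure, validated at their borders against independent 5'-end
(RAMPAGE) and 3'-end (WTTS-seq) evidence, scored for tissue specificity,
scanned for alternative-splicing events, and finally connected to
quantitative-trait loci. Every stage is a pure function over explicit
inputs, and a synthetic-data generator with planted ground truth stands in
for the sequencing data, so the whole pipeline is testable on a laptop.

Coordinates are 1-based closed throughout, the native convention of the
R/Bioconductor interval stack (IRanges, GenomicRanges, rtracklayer) this
package is built on. GTF is read and written natively; BED is shifted by
one on import. Keeping a single convention that the underlying libraries
share eliminates the class of off-by-one errors that window rules are
otherwise prone to.

## Transcript QC filters

Four families of filters are applied to assembled models, in the order in
which their inputs become available:

* **Support filters** (`filter_support`): a transcript needs a minimum
  per-base read coverage of 3x in every tissue it was assembled in (the
  minimum over transcript bases, the strictest reading of "3 times base
  coverage"), every splice junction must be canonical (GT..AG, GC..AG or
  AT..AC on the transcript strand — the three standard dialects, carried
  as a flag in the junction table), and every junction needs at least one
  spanning read with a 5-nt overhang on both sides in some assembled
  tissue. Requiring the overhang on both sides is the conservative choice
  where one-sided support would be ambiguous; the support tables record
  the overhang so the threshold is adjustable.
* **Pre-mRNA removal** (`flag_premrna`): a spliced transcript whose
  junction chain is a subset of a same-strand reference transcript's
  chain, and which retains at least one reference intron inside an exon,
  is treated as unspliced precursor contamination. Unspliced transcripts
  are exempt — the rule targets partially processed spliced models.
* **Genomic poly(A) artifacts** (`flag_genomic_polya`): an unspliced
  transcript with a stretch of at least 20 adenines (one mismatch
  allowed; the run must start and end with A, so the allowance cannot be
  spent on a terminal base) within the 30 bp immediately 3' of its
  terminal site is an internal-priming artifact of poly(A) selection.
  The window follows the strand and is truncated at contig ends.
* **Locus noise rules** (`filter_locus_rules`), applied after expression
  marking: unspliced transcripts expressed in a single tissue are
  removed, and single-exon genes with no H3K4me3, H3K4me1, H3K27ac or
  ATAC peak in their promoter (500 bp 5' to 100 bp 3' of the start site)
  are removed entirely. CTCF peaks deliberately do not rescue a gene —
  insulator binding is not evidence of transcription initiation.

## Structural collapsing and border validation

Two transcripts are structurally equivalent when their junction chains
have equal length with every intron boundary within 15 nt, and their
borders agree. A border without evidence support may move by up to
100 nt. When both transcripts' ends are evidence-supported the package
requires the two ends' evidence windows to overlap — the windows must be
able to contain one shared peak — which means at most 40 nt between
supported TSSs (the span of the 30-bp-5'/10-bp-3' TSS window) and at most
175 nt between supported TTSs. The function receives only support flags,
so window overlap is the closest executable reading of "supported by the
same evidence"; passing the peaks themselves would let the check be
exact, at the cost of dragging evidence tracks through every structural
comparison.

Fuzzy equivalence is not transitive, so `collapse_transcripts` takes the
transitive closure (union-find over all candidate pairs) and keeps, per
class, the member with the longest genomic span (ties: lexicographically
smallest id). This makes the output deterministic and invariant to input
order, at the price of occasionally chaining through an intermediate — a
property the test suite checks explicitly rather than hides.

Genes are single-linkage clusters of same-strand transcripts with at
least 1 nt of span overlap. Predicted genes are assigned to reference
genes by same-strand exon-versus-exon overlap (stricter than
exon-versus-span: a transcript lying entirely in a reference intron is
not "the same gene"), and gene-border extensions are measured
strand-aware between gene spans, with the extended borders validated by
RAMPAGE (TSS window −30/+10) and WTTS (TTS window −10/+165) evidence.

## Biotype decision tree

ORFs are found in the three sense frames of the spliced sequence with
`ATG` plus the vertebrate alternative initiation codons `CTG/GTG/TTG`
(the documented option set of standalone ORF finders; alternative starts
can be disabled). The representative ORF is the best protein-homology
hit (E ≤ 1e-6, coverage ≥ 60%, identity ≥ 95%) among the three longest
ORFs, else the longest ORF. The tree is then:

1. representative ORF with a stop codon and **more than 44 aa**: if the
   stop lies **more than 50 nt** (spliced distance) upstream of the final
   exon–exon junction → **nmd**, else → **protein_coding**. The distance
   is measured in mRNA coordinates because the 50-nt rule describes where
   the terminating ribosome sits relative to the last exon-junction
   complex — a property of the spliced molecule, not the genome.
   Unspliced transcripts have no final junction and can never be nmd.
2. representative ORF with a start but no stop → **nsd** (nonstop decay).
3. otherwise noncoding: shorter than 200 nt with no external
   coding-potential call and no miRNA-precursor overlap → **sncRNA**;
   otherwise a lncRNA, subtyped with precedence **antisense**
   (exon overlaps a coding-gene span on the opposite strand) →
   **sense-intronic** (entirely inside one intronic block of a
   same-strand coding gene) → **intragenic** (exon overlaps coding
   exons, same strand) → **intergenic**. The precedence is needed
   because a transcript can satisfy several definitions; antisense first
   because strand-discordant overlap is the least ambiguous signal.
   All boundaries ("longer than 44", "more than 50", ">0.9", ">50%")
   are strict, and a transcript of exactly 200 nt is a lncRNA.
   The external coding-potential flag is consulted only inside the
   noncoding branch — it can withhold sncRNA status but never overrides
   an ORF-based coding call.

Genes with one coding transcript are protein-coding; genes transcribing
only nmd/nsd isoforms with a passing nucleotide-homology hit (coverage ≥
90%, identity ≥ 95%) are pseudogenes — homology to a protein-coding gene
with a disrupted reading frame; the rest are noncoding. Per tissue, a
gene expressing both coding and noncoding isoforms is bifunctional, and
PATs (nmd + nsd) are its main products when they exceed half of its
expressed transcripts.

## Expression, TSI and tissue clustering

A transcript is expressed in a tissue iff it was assembled there, or its
abundance exceeds 1 RPKM (strictly) with all of its junctions quantified
there; genes inherit the OR over their transcripts. The two-clause rule
exists because assembly alone badly overcalls tissue specificity.

The tissue-specificity index of a feature with max-normalised expression
`x` over `N` tissues is `TSI = sum(1 - x_i) / (N - 1)`: 0 for an exactly
uniform housekeeper, 1 for single-tissue expression, computed over all N
tissues including zeros. Features expressed in one tissue are
tissue-specific; multi-tissue features with TSI > 0.9 are expressed in a
tissue-specific manner.

Tissues are clustered on pairwise sharing of expressed features,
`100 * |A ∩ B| / min(|A|, |B|)` by default. The min denominator reads
"percentage of a tissue's transcripts shared with another" the way a
smaller tissue experiences it and keeps the matrix symmetric; Jaccard is
available. Clustering is complete-linkage `hclust` on `100 − sharing`,
and two dendrograms are compared by the Spearman correlation of their
cophenetic distance vectors.

## Alternative splicing

Events are local (exon-level), enumerated per gene from all transcript
pairs and deduplicated by type plus defining coordinates: skipped exon,
retained intron, alternative 5'/3' splice sites (strand-aware; the exons
flanking the variable boundary must overlap, so a skipped exon does not
masquerade as an A5/A3), mutually exclusive exons, and alternative
first/last exons. The eighth class, the unique splice site exon (USE),
is a pair of overlapping internal exons from two isoforms that share no
splice junction: neither flanking intron of one exon occurs anywhere in
the other transcript's chain. USEs are restricted to internal exons
because transcript termini are not splice sites; the suite verifies the
whole enumerator against an independent exhaustive scan and checks that
flipping the strand swaps A5 with A3 and AF with AL.

## QTL integration

Each QTL's nearest expressed gene (distance 0 inside the span, boundary
gap otherwise, ties to the smaller id) defines the trait's
QTL-associated gene set. Enrichment of a query gene set in a trait's
genes is the right-sided Fisher exact test — computed as the
hypergeometric upper tail — BH-corrected across traits at 0.05.

Directed trait similarity is a permutation test: the observed overlap of
trait A's genes with trait B's is compared with the overlap of A's genes
with 1,000 random gene sets of B's size drawn without replacement from
the expressed-gene universe, with the add-one estimator
`p = (1 + #{null ≥ obs}) / (n_perm + 1)`. Both directions are tested, BH
correction is applied globally over all directional tests, and an edge
is reported when either direction passes 0.05.

One property of this estimator deserves a note: its smallest attainable
p-value is `1/(n_perm+1)`, so under global BH a floor-level test can only
be significant when roughly `m * 0.05^-1 * floor` of the `m` tests sit at
the floor. In a catalogue-scale analysis thousands of trait pairs reach
the floor and global BH behaves as intended; in a desk-scale experiment
with a single planted pair nothing could ever pass. The calibration
experiments therefore plant several similar pairs (the generator default
is three), which is also the statistically honest configuration: it
reproduces the regime in which the published procedure operates.

The tissue-axis test takes a source and a target gene set with matched
samples, computes all pairwise Spearman correlations, and compares them
with the correlations of 1,000 random target-sized sets from a candidate
pool using right-sided two-sample t-tests; the BH-adjusted p-value
distribution (and its fraction below 0.05) is the significance summary.
Because the t-test treats correlation pairs as independent while a
shared latent factor makes them strongly dependent, the test is
anticonservative for internally correlated gene sets — a limitation of
the published procedure that the package reproduces rather than repairs;
the null-calibration test uses uncorrelated sets where the assumption
holds.

## The synthetic-data generator

`simulate_annotation` and its companions generate every pipeline input
with planted truth. Design choices worth knowing:

* **Sequence planting is constructive, not probabilistic.** Functional
  transcript sequence is built over the {A,C} alphabet — which cannot
  contain any start codon, since all of ATG/CTG/GTG/TTG require a TG
  dinucleotide — plus one explicit `ATG … TAA` open reading frame where
  the class requires it. A planted coding transcript therefore has
  exactly one ORF, at a known position; planted noncoding transcripts
  have none, whatever the noise realisation. Guard flanks and planted
  introns use the {A,G} alphabet, which is start- and stop-codon-free on
  *both* strands, so duplicate-copy border extensions and spliced-in
  intron content can never create or destroy an ORF. No attempt is made
  at realistic base composition or codon usage: every rule in the
  pipeline inspects ORF coordinates, A-runs and windows, none inspects
  nucleotide statistics.
* **Planted classes**: the default mix (30% coding, 12% NMD, 6% NSD,
  36% lncRNA across the four subtypes, 10% sncRNA, 6% pseudogene) keeps
  protein-coding and noncoding transcripts roughly balanced with NMD and
  antisense lncRNAs as the largest noncoding classes, the composition a
  deep multi-tissue catalogue shows. Hosted lncRNA subtypes are placed
  against protein-coding host genes (antisense in an intron on the
  opposite strand, sense-intronic in an intron, intragenic over the 3'
  UTR tail), one per host so no two hosted single-exon genes can fall in
  each other's promoter window. Bifunctional loci carry a nested NMD
  isoform in the host's last intron — same gene, unchanged span.
* **Duplicate groups** re-emit a template from other tissues with its
  borders extended outward by exactly `border_jitter` (default 40 nt,
  inside the 100-nt fuzz) and junctions shifted by exactly
  `junction_jitter` (default 0). The shifts are deterministic rather
  than sampled so that threshold experiments are sharp: recovery holds
  exactly up to the fuzz and fails exactly beyond it. Nonzero junction
  jitter corrupts planted coding sequence at exon boundaries, so biotype
  recovery is asserted only with the default.
* **Expression** is planted per duplicate group (one molecule):
  tissue-specific groups at ~30 RPKM in one tissue and 0.05 elsewhere,
  housekeepers at 10 everywhere, broad groups at 8 over a random
  multi-tissue subset covering every assembled tissue. Log-normal noise
  (σ = 0.25) is applied and clamped (expressed ≥ 2, silent ≤ 0.5 RPKM)
  so planted expressed/not-expressed calls survive; at σ = 0
  housekeepers give TSI exactly 0. Counts are derived by rounding
  against a 20M-read library; RPKM is the authoritative matrix.
* **Evidence** peaks sit inside the validation window of every planted
  supported end and decoys sit strictly outside every window (decoys
  that would graze another feature's window are dropped). Rescued
  single-exon genes get an H3K4me3 or ATAC peak at their promoter;
  non-rescued ones get only CTCF, which exercises the no-rescue rule.
* **QTLs** target only genes whose spans overlap no other gene, placed
  inside the body or 200–1,000 bp away — under half the 2.5-kb
  intergenic gap — so the planted target is provably the nearest
  expressed gene. Planted similar trait pairs share 80% of their gene
  sets.

What the generator does **not** emulate: read-level noise, realistic
ChIP peak shapes, incomplete assembly, mis-stranded models, chimeric
transcripts, or chromosome-name mismatches between annotations (identical
names are required and documented). Passing the recovery tests therefore
shows the rules are implemented exactly as specified, not that they are
robust to the failure modes of real assemblies.

## Problem sizes used by the checks

The test suite runs the recovery experiments on 40–60-gene catalogues
over 6–10 tissues, the oracle comparisons on 100 random Fisher tables,
all synthetic genes with up to 4 transcripts, and a 500-transcript
collapse, and the network calibration on 100 null and 40 planted
replicates of 20 traits against a 2,000-gene universe with 1,000
permutations each. These sizes give exact recovery checks and stable
Monte-Carlo fractions in a few minutes of CPU time; all of them scale
linearly if larger experiments are wanted.

## Known limitations

* The collapse closure can chain structurally drifting transcripts into
  one class when intermediates bridge them; this is inherent to making a
  non-transitive relation into a partition and is surfaced, not hidden.
* Gene-border extension comparison uses gene spans (not
  longest-transcript spans); with deeply nested isoforms the two differ.
* The axis correlation test inherits the independence assumption
  discussed above.
* `filter_support` treats a junction's canonical status as a property of
  the junction (any tissue's flag), and coverage tables carry only the
  per-tissue minimum — sufficient for the rule, but other aggregations
  require regenerating the table.
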