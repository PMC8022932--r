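---
title: "Prioritizing candidate genes from forward-genetic-screen resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes from forward-genetic-screen resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscreen)
```

## The analysis model

A forward genetic screen isolates mutant lines by phenotype and
resequences each line against a common reference. The signal — one causal
lesion per line — is buried under three kinds of noise, and the pipeline
removes each with a dedicated, order-dependent filter:

1. **Call-quality noise.** Variant callers annotate each site with quality
   statistics (quality-by-depth QD, RMS mapping quality MQ, site quality
   QUAL, mapping-quality and read-position rank-sum tests, strand-bias
   statistics SOR and FS). A call is removed when any exclusion
   inequality is strictly true: QD < 2.0, MQ < 40.0, QUAL < 100,
   MQRankSum < −12.5, SOR > 4.0, FS > 60.0, ReadPosRankSum < −8.0.
   Two conventions matter and are easy to get wrong. First, the
   inequalities are *exclusion* expressions: a variant at the boundary
   (e.g. SOR = 4.0 exactly) passes. Second, an absent metric cannot fail
   its criterion — rank-sum statistics are routinely missing at sites
   without heterozygous reads, and failing them would discard most of a
   real callset.
2. **Clonal background.** The mutagenized clone differs from the
   sequenced reference clone before any mutagen is applied, so those
   differences appear in *every* line. A variant whose identity key
   (contig:pos:ref:alt, exact match) occurs in all lines is removed.
   Deliberately, only *universal* sharing defines background: a variant
   in n−1 of n lines survives this stage.
3. **Recurrence and silence.** At candidate selection a second, stricter
   recurrence rule applies: variants present in more than two lines are
   discarded, since independently derived lines should not share a causal
   lesion; synonymous variants are discarded as phenotypically silent.
   The two recurrence rules are distinct parameters because they act at
   different stages and encode different assumptions.

Surviving exonic variants are grouped by gene and genes ranked by their
most severe variant: stop gain > frameshift indel > non-frameshift indel
> stop loss > nonsynonymous SNV, ties broken lexicographically by gene
id. The ordering encodes the screen's reasoning that outright
loss-of-function lesions are the most likely causes of a strong phenotype.

## Region classification and coding consequences

Coordinates are GFF3/VCF 1-based inclusive throughout; no conversion
layer exists. Each variant receives exactly one region class. The
variant's affected reference interval (pos .. pos + nchar(ref) − 1) is
intersected with typed gene segments, and when several classes apply —
across overlapping genes or across the bases of an indel — the
highest-precedence class wins:

exonic > 5′UTR > 3′UTR > intronic > upstream > downstream > intergenic.

Flanks are strand-aware windows of 1000 bases (the conventional default
of gene-based annotators; the value is a parameter). A variant upstream
of one gene and downstream of another is upstream. Intronic positions
within 2 bp of an exon boundary are *not* given a separate splicing
class, keeping the reported taxonomy closed under the seven classes.

Coding consequences are codon-level. For SNVs the affected codon is
located through the transcript-order CDS coordinate map (for minus-strand
genes translation order is reverse-genomic, and junction-spanning codons
assemble across segments), mutated, and translated with the standard
genetic code. Indels are classified by the number of *coding* bases they
add or remove: an insertion counts fully when its anchor base is coding;
a deletion counts only its deleted bases that fall inside CDS segments.
A net change divisible by three (including zero, for an indel that
touches an exon edge without changing coding length) is non-frameshift.
Conventions at boundaries were chosen to maximize sensitivity for
loss-of-function candidates: an indel overlapping any coding base is
exonic even if anchored outside.

Two closed-world choices keep count tables consistent: stop-loss SNVs
(real, but absent from the classic screen-summary layout) are folded into
the nonsynonymous column of summary tables while remaining distinct in
the API; codons containing N translate to "unknown" and such variants are
excluded from summaries with a warning rather than miscounted. By
construction every summary row satisfies total = Σ(seven region classes)
and exonic = Σ(five exonic subtypes).

One transcript per gene is used (the longest-CDS mRNA when a gene has
several, with a warning); genes whose total CDS length is not a multiple
of 3 are kept for region calls but excluded from consequence calls.
MNVs and symbolic alleles are skipped on input; indels are assumed
caller-normalized and are not re-normalized.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the analysis assumes.
Defaults: 15 lines, a 100 kb single-contig genome carrying 20
non-overlapping ORF genes (ATG … in-frame stop, no internal stop, 150–400
codons, 1–3 exons with 50–80 bp introns, 60–200 bp UTRs, random strands,
intergenic gaps ≥ 2.1 kb so 1 kb flanks never overlap a neighboring
gene), 50 universal background variants, 10 exonic nonsynonymous decoys
planted in 3 to n−1 lines, 10 private exonic synonymous decoys, 200
private spectrum variants per line, and one causal exonic
loss-of-function variant (stop-gain SNV or 1–2 bp frameshift insertion)
per line in a line-unique gene.

The EMS profile draws 90% G:C→A:T transitions, the literature-standard
spectrum for EMS mutagenesis (the source screen reports dose, not
spectrum, so the fraction is a configurable parameter); the UV profile
draws C→T at dipyrimidine contexts at the same configurable fraction.
Ten percent of private/background variants are indels of 1–6 bp. A
configurable fraction (default 20%) of private variants per line — an
exact count, so filter recovery is checkable — and background variants
(per-variant Bernoulli, consistent across lines) receive metrics
violating exactly one uniformly chosen hard-filter criterion, drawn
beyond its threshold; passing metrics are drawn from comfortable ranges
(QD 20–35, MQ 55–60, QUAL 300–1000, rank sums ±2, SOR 0.5–2, FS 0–10),
with the two rank-sum statistics occasionally absent as in real
callsets. Causal variants and decoys always receive passing metrics:
the generator tests filter logic, not caller realism.

The default 200 private variants per line keeps simulations at desk
scale; `paper_scale = TRUE` raises the load to ~2700 per line, the scale
reported for real EMS/UV mutant lines, and is used when measuring
mutation load. All randomness flows from one seed, and emitted
FASTA/GFF3/VCF/TSV files are byte-identical across runs with the same
seed (writers have fixed headers and no timestamps — the reason the VCF
and GFF3 emitters are in-package rather than delegated to writers that
stamp dates).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level artifacts (metrics are sampled, not
computed from alignments), heterokaryotic mixtures of nuclei that can
mask mutations in real protoplast-derived lines, repeat-driven
mis-mapping, clustered mutations, and multi-isoform genes. The truth
table records intended region, consequence, filter verdict and line
membership per variant; annotating the simulated variants with the
package's own annotator must reproduce the intended labels for ≥ 99.9%
of variants, with residual disagreements auditable junction cases.

## Numerical and degenerate-input choices

Thresholds are compared with plain floating-point `<`/`>`; no epsilon is
applied, matching the caller's own filter semantics. QUAL's printed
threshold has no decimals and is treated as 100.0. Duplicate identity
keys within a line are removed on cohort construction with a warning.
Empty callsets flow through every stage (header-only VCFs, all-zero
summary rows). Variant positions beyond contig bounds, REF alleles that
contradict the supplied genome, and unsorted input to the VCF writer are
errors, not warnings.

## Problem sizes used in the test suite

Oracle-equivalence checks run on a seeded 50 kb, 10-gene genome with
100,000 scanned positions for region classes and 1,000 random coding
SNVs plus 200 indels for consequences, against independently implemented
oracles (an exhaustive paint-the-array interval scan, and full-CDS
retranslation). The hard filter is verified exhaustively on a
threshold ± ε grid over all seven criteria including absent-metric
cases. End-to-end planted recovery runs the default 15-line
configuration. These sizes were chosen to exercise every code path —
both strands, junction codons, indels at exon edges — while keeping the
suite fast enough to run habitually.

## Known limitations

Single transcript per gene; no splice-site class; no MNVs; no indel
left-normalization; no noncoding candidate ranking (lines whose causal
lesion is noncoding — as inferred for two lines in the reference screen —
surface with empty candidate lists rather than a ranked noncoding set);
recurrence counts lines, not allele copies. One row of the published
screen-count table is internally inconsistent (its exonic column differs
from the sum of its subtype columns by one); the package reproduces the
arithmetic of the consistent rows and surfaces the discrepancy in its
tests rather than patching the published numbers.
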