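---
title: "Detecting genomic imprinting from reciprocal-cross seed RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from reciprocal-cross seed RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintcall)
```

## The problem

Imprinted genes express their maternally and paternally inherited alleles
unequally. In flowering plants this happens mostly in the endosperm, the
triploid seed tissue carrying two maternal and one paternal genome. Crossing
two accessions (Col-0 and Ler) in both directions and sequencing seed RNA
lets allele-diagnostic SNPs assign reads to a parent: a read matching the Col
haplotype is maternal in a Col x Ler seed and paternal in a Ler x Col seed.
Two confounders make a single cross insufficient: strain (cis) effects, where
one accession's allele is stronger regardless of parent, and carryover of
transcripts from the seed coat, a diploid maternal tissue dissected away
imperfectly. The package implements the full calling pipeline: read
assignment, an exact unconditional test against the tissue-specific dosage
null, confidence-bound fold factors, cis and contamination filters,
expression support, and genomic-context analyses, together with a synthetic
data generator that makes every stage testable without the original
sequencing data.

## The imprinting test

For a gene, let `a1`/`b1` be Col/Ler informative reads in the Col x Ler cross
(`n1` total) and `a2`/`b2` in the reciprocal (`n2`). Under no imprinting the
Col fraction is `p1_0 = p2_0 = 1/2` in embryo, and `p1_0 = 2/3`, `p2_0 = 1/3`
in endosperm (two maternal genome copies to one paternal; the constant is
used exactly as 2/3, not a printed rounding). The test is an exact
unconditional (Storer-Kim-type) comparison of the two binomials: the p-value
sums `Bin(i; n1, p1_0) * Bin(j; n2, p2_0)` over every outcome pair at least
as extreme as the observed one.

What "as extreme" means is a genuine design choice for the asymmetric
endosperm null, and several orderings are defensible. The default orders
outcomes by the absolute difference of *per-genome-copy* Col fractions: Col
counts are reweighted by `(1 - p0)/p0` (halved where Col is the mother in
endosperm), so the null fraction is 1/2 in both crosses, and the statistic is
the difference of those dosage-corrected fractions. Three properties decided
this:

* it reduces exactly to the classic `|p̂1 - p̂2|` construction when the null
  is symmetric (embryo), so only the endosperm case is generalised;
* it is exactly invariant under a pure strain effect (multiplying the Col
  allele's odds by any fold moves both per-copy fractions identically), so
  cis-biased genes do not leak into the imprinting test;
* on the worked-example genes with published per-cross counts it reproduces
  the reported p-value magnitudes much more closely than the raw deviation
  statistic `|(p̂1 - p1_0) - (p̂2 - p2_0)|`, which badly understates the
  evidence for near-monoallelic genes with unbalanced coverage (for the
  FIS2-like counts 13,0 | 6,16 it gives p = 0.016 where the per-copy ordering
  gives 0.0033).

The raw-deviation ordering remains available (`stat = "deviation"`), and the
cis test uses the classic pooled construction (below). Ties on the statistic
count as extreme (absolute tolerance 1e-12); a gene with reads in only one
cross has p = 1, because one cross cannot separate parent from strain.
The implementation collapses the inner sum to two binomial tails per
outcome of the first cross, which is algebraically identical to full
enumeration (the test suite proves equality on every outcome of every
sample-size pair up to 30) but runs in linear rather than quadratic time, so
genes with tens of thousands of informative reads are exact too.

## Factors: confident fold changes

Deep coverage makes trivial biases significant, so calls additionally
require an *imprinting factor* of at least 2: a lower 95% confidence bound
on the fold difference between the Col:Ler ratios of the two crosses.
Maternal counts are dosage-adjusted first (halved in endosperm), the
Haldane pseudocount 0.5 is added afterwards (keeping the null log-ratio
centred at zero), and a normal (Katz-type) interval is taken on
`log(r1/r2)` with `SE = sqrt(sum of reciprocals of the four adjusted
counts)`. The same adjusted counts give the cis factor, a confident
geometric-mean Col:Ler fold across crosses (`exp(|log(r1*r2)|/2 - z*SE/2)`),
and the differential-expression factor follows the same pattern on
upper-quartile-normalised library counts. The cis p-value compares the
maternal fractions of the two crosses (`a1/n1` versus `b2/n2`) in pooled
mode: equal maternal fractions characterise "no strain effect" whatever the
degree of imprinting.

A gene is called when it has at least 15 informative reads (crosses
combined, inclusive), raw p below 0.01 (q-values are reported alongside and
can be used as the cutoff instead; BH correction runs over the genes
passing the read filter, the tested universe), an imprinting factor of at
least 2, and no dominant cis effect (cis q below 0.01, cis factor at least
2 and exceeding the imprinting factor). Direction of the confident fold
decides MEG versus PEG.

## The contamination filter

Seed-coat carryover adds purely maternal transcripts, so it can fake MEGs
and only mask PEGs. The filter compares reference (microarray-scale, log2)
seed-coat and endosperm expression per gene: maternally biased candidates
whose seed-coat excess exceeds 1.04 (about two-fold) are removed;
paternally biased candidates are never touched; genes lacking reference
data are retained (a deliberate sensitivity-first choice that admits a
small, quantifiable false-positive remainder — the acceptance battery
measures it). A data-driven threshold (95th percentile of candidate-PEG
differences, which contamination cannot inflate) is available and agrees
with the fixed default on stable inputs; the fixed value is the default
because the percentile needs at least ~20 candidate PEGs to be stable.
The filter runs between the p-value stage and the final factor/cis calls in
the pipeline; because it only ever demotes maternally biased candidates,
applying it before or after the factor cutoff yields the same final set.

## The synthetic cohort

The generator draws, per gene: a class (biallelic, MEG, PEG, cis); a true
maternal transcript fraction (MEGs uniform on 0.85-1, PEGs on 0-0.45, so
partial imprinting is the rule and monoallelic expression the boundary); a
strain fold for cis genes (log-uniform on 2-6, random direction, applied to
the Col allele's odds); a shared per-gene expression factor (lognormal,
sd 1) and, given it, negative-binomial informative depths per cross (mean
150, size 10). The split of the overdispersion matters: expression
variation is shared between the reciprocal libraries (which profile the
same tissue and correlate near 1), so the heavy spread — including a
realistic share of genes below the 15-read filter — comes from the shared
lognormal factor, while conditional per-cross sampling adds only mild
library-level noise. Putting heavy dispersion in independent per-cross
draws instead would routinely produce genes with hundreds of reads in one
cross and almost none in the other, a pattern the design cannot actually
generate. Col/Ler counts are then binomial given the cross-specific Col
fraction. Defaults mirror the study's conditions: about 10,000 informative
genes, MEG and PEG fractions of 1.6% and 0.4% of the informative universe,
and 5% of genes seed-coat-contaminating (the fraction of informative genes
the published filter removed).

Contamination adds Poisson maternal-strain reads with mean
`kappa * depth * max(2^diff - 2, 0)`, where `diff` is the gene's log2
seed-coat minus tissue difference (uniform 1.5-4 for contaminating genes,
centred normal otherwise). The excess-above-two-fold coupling encodes the
same causal account the filter is built on — only genes whose seed-coat
abundance substantially exceeds their endosperm abundance shed carryover
that registers against their own signal — and keeps the `kappa = 0` null
calibration exact. A configurable fraction of genes (default 5%) lacks
reference data, which is what lets a residual of contaminated genes through
the filter, as it would with a real array platform.

What the generator does not model: transcript structure, sequencing error
and quality, mapping bias between accessions, replicate libraries, and
biological overdispersion of the allelic fraction (beta-binomial). Passing
tests therefore certify the statistics and the pipeline logic under clean
binomial sampling, not robustness to aligner artefacts or allelic
overdispersion; with one library per cross per tissue, as in the study
design, replicate-aware models are out of scope by construction.

The read-level generator builds a toy single-chromosome genome with
two-exon genes and exonic SNPs 100 bp apart, writes strain-labelled 36 bp
reads as SAM, and is exact by construction: classifying its output recovers
the generating counts read for read, which pins the whole
SAM-to-count-table path (MAPQ floor, spliced-block gene assignment,
all-SNPs-agree classification, conflict and ambiguity handling).

## Numerical and procedural choices

* Internal coordinates are 0-based half-open; SNP tables are 1-based (the
  field convention), GFF3 1-based inclusive, BED 0-based half-open — each
  converted at the boundary by the standard importers.
* Mapping uniqueness is approximated by MAPQ > 0, the closest SAM-level
  proxy for an aligner's discard of equal-score multi-mappers.
* A third allele at a SNP makes a read conflicting, not ignored
  (conservative reading of the all-SNPs-agree rule).
* Thresholds are inclusive (>= 15 reads, factor >= 2); statistic ties count
  as extreme at 1e-12 absolute tolerance.
* The 75th percentile for upper-quartile normalisation uses linear
  interpolation (type 7) over genes expressed in at least one library; the
  Fisher reference row is scaled to entries of about 1000 (a documented
  sensitivity knob — the reference row is a pseudo-library pinned at the
  null ratio).
* The DMR-association flank is 2 kb on each side; mini-clusters chain genes
  whose boundary-to-boundary distance is at most 10 kb (single linkage),
  and the random expectation in the enrichment test is the mean of 1,000
  seeded draws rather than a single draw.

## Problem sizes used by the tests and acceptance script

Exhaustive oracle equivalence covers every outcome of every sample-size
pair up to 30 in both test modes (about half a million p-values). Null
calibration uses 10,000 all-biallelic endosperm genes at depth ~50 per
cross; recovery uses 4,000 genes at depth 150 with 10% MEGs and 5% PEGs
(a benchmark mixture chosen for stable sensitivity/FDR estimates, not a
claim about prevalence); the contamination experiment uses 8,000 genes so
the post-filter false-discovery estimate, driven by the ~5% x 5%
contaminated-and-missing corner, has small variance. These sizes are the
package's benchmark design; all are reproducible from a single seed.

## Known limitations

The exact construction the original analysis used for the asymmetric
endosperm null is not fully recoverable from its description; the per-copy
ordering reproduces the published p-value magnitudes well for the anchor
genes but not digit for digit (one published value, for a gene with six
reads, is not reproduced by any ordering tried). The binomial model ignores
allelic overdispersion, so p-values on real replicate-free data are
anti-conservative to an unknown degree — the factor cutoff, not the
p-value, is the effective guard. The contamination filter depends on an
external reference's coverage; genes missing from it are retained by
design and set the floor of the post-filter false-discovery rate.
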