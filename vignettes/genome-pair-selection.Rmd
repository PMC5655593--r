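---
title: "Measuring purifying selection across genome-pair cohorts: methods and design"
author: "omegapair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring purifying selection across genome-pair cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the quantity

The efficiency of purifying selection in a lineage can be read off the
genome-wide ratio of nonsynonymous to synonymous substitution rates
(dN/dS, here ω) between orthologous genes of two closely related genomes:
the stronger purifying selection is, the lower ω falls below 1. Comparing
per-pair mean ω against genome size across a cohort of genome pairs asks
whether larger genomes experience weaker selection (a positive ω–size
association, the pattern expected from population-genetic theory and seen
in eukaryotes) or stronger selection (negative association). Coding
density against genome size asks the companion question about noncoding
DNA accumulation, and ANI (average nucleotide identity) controls that
pairs sit at comparable, shallow divergences.

`omegapair` implements that entire measurement chain — orthology, codon
alignment, counting-method ω estimation with saturation filters, ANI,
coding density, and Spearman rank correlations — together with a codon
substitution simulator that generates genome-pair cohorts with *known* ω,
κ, divergence and noncoding structure, so every stage is validated against
ground truth rather than against other software.

## Pipeline model, stage by stage

### Orthology

Within each genome, near-identical paralogs are collapsed first: proteins
are single-linkage clustered at ≥90% identity over ≥90% of both lengths
and each cluster keeps its longest member (ties broken lexicographically).
Collapsing precedes best-hit search so a recent duplicate cannot break
reciprocity. Cross-genome pairs are then bidirectional best hits (BBH):
each representative's best-scoring partner under exact Needleman–Wunsch
global alignment (BLOSUM62, affine gaps open 11 / extend 1), emitted only
when the relationship is mutual and the alignment reaches ≥30% identity
over ≥50% of both sequences. All tie-breaks are deterministic (score,
then percent identity, then lexicographic id), so runs are reproducible
bit for bit. A shared-4-mer prefilter restricts exact alignment to the few
most promising partners per gene (`n_candidates`, default 3; `Inf`
recovers the exact all-vs-all search, which the test suite compares
against a brute-force mutual-argmax oracle). For inputs beyond desk scale,
precomputed tabular search results can be supplied instead
(`bbh_from_hit_tables()`).

### Codon alignment

Protein alignments are back-threaded onto their coding sequences: each
aligned residue column maps to a codon pair, and columns containing a
gap, an ambiguous base (N), or a stop codon are dropped and counted. The
translation of every CDS is checked against its aligned residues before
threading; a mismatch is an error naming the gene, not a silent repair.

### dN/dS by counting methods

Two estimators are implemented from first principles and emit identical
record shapes:

* **NG86** (Nei–Gojobori 1986). Synonymous sites per codon are the sum
  over the three positions of the synonymous fraction among that
  position's single-nucleotide changes, with changes to stop codons
  excluded from the denominator; `s + n = 3` by construction. Observed
  differences between two codons are averaged over all orderings of the
  differing positions, excluding pathways through stop codons and
  renormalizing over the survivors (if *every* ordering is blocked the
  count falls back to an even split with a warning — the affected codon
  pairs are a handful involving near-stop codons). Proportions receive
  the Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`.

* **YN00** (Yang–Nielsen 2000 counting scheme). Codon frequencies are
  F3×4 estimated from the pair (position-specific nucleotide
  frequencies, floored at 1e-4 to keep pathway weights positive on short
  genes); κ is estimated from fourfold-degenerate and nondegenerate
  sites via K80 transitional/transversional distances pooled by site
  count; site counts weight each single-nucleotide change by
  `π(target) × κ^[transition]`, using the same per-position
  normalization as NG86 so that κ = 1 with uniform frequencies reduces
  to NG86 *exactly* (a tested identity); pathway averaging weights each
  surviving pathway by the product of its step rates
  (`π × κ^[ts] × ω^[nonsyn]`); and dS, dN are corrected with K80 applied
  to the synonymous and nonsynonymous transition/transversion splits. ω
  is iterated to `|Δω| < 1e-6` (cap 100 iterations; non-convergence is
  flagged, not hidden). This follows the published counting scheme at
  the granularity described; it is not a line-for-line port of any
  existing implementation.

Degenerate outcomes use sentinels so the filter stage handles every case
uniformly: `dS = 0` yields ω = 999 (always in the ">99" discard bucket);
a proportion at or beyond the correction's domain (p ≥ 3/4 for
Jukes–Cantor, log arguments ≤ 0 for K80) yields an infinite rate, which
the dS > 1.6 or ω > 99 filter removes.

### Filters and the retention rule

Per-ortholog estimates are discarded when `dS < 0.1` (too little
synonymous signal), `dS > 1.6` (saturation), or `dN/dS > 99` (unreliable
ratio); all three comparisons are strict, so the boundary values 0.1, 1.6
and 99 are retained. Each discard is labeled with the first matching
reason in that order. A genome pair then survives only if its retained
orthologs amount to **no less than 5%** (inclusive) of the pair's average
coding capacity, read as CDS count — the same unit as the CDS-based
genome-size axis. The per-pair statistic is the arithmetic mean of the
retained per-ortholog ω values with its standard error (mean of ratios,
not ratio of summed rates, because the per-pair SEM is over orthologs);
fewer than two retained orthologs leave the SEM undefined and force the
pair out.

### ANI

ANI is computed internally in the fragment convention: 1020-bp
consecutive fragments, each aligned to its best location in the partner
genome, kept when they reach ≥30% identity over ≥70% of their length;
the reported value is the mean identity of kept fragments, symmetrized
over both directions so argument order cannot matter. Best locations come
from exact 12-mer seed votes refined by Smith–Waterman in a window; a
placement supported by several seeds at one exact offset is scored
directly without dynamic programming (collinear case), and fragments
without any seed hit fall back to a full local alignment. When no
fragment passes the gate the ANI is *missing*, never 0. A precomputed-ANI
override exists for reruns that want to inject externally obtained
values.

### Correlations

Spearman rank correlation with midranks for ties; the two-sided P value
is exact (full enumeration of all n! permutations) for n ≤ 9 and a
t-approximation on n − 2 degrees of freedom above that, with |rs| = 1
falling back to the exact value 2/n!. The method used is recorded with
every result. Cohort panels are computed only over pairs that pass the
retention rule; pairs with missing ANI are dropped from the ANI panel
alone (pairwise deletion happens in the pipeline layer, never silently
inside the statistic).

Pair-level "genome size" for the panels is the mean of the two genomes'
sizes (configurable to min/max/first); the pair's coding density is
likewise the mean of the two genomes' densities.

### Coding density

`(length of coding sequence / total genome length) × 100`. The default
numerator is the union of CDS-covered positions, which guarantees a value
≤ 100 even with overlapping genes (a requirement for a sane correlation
input); a literal-sum mode reproduces the naive summed-lengths formula
for comparison. For non-overlapping annotations the two agree exactly.

## The simulator: what it emulates and what it does not

The generator is a GY94 codon model: a 61-state reversible Markov chain
with rate `π_j × κ^[transition] × ω^[nonsynonymous]` between
single-nucleotide neighbors, scaled to one expected substitution per
codon per unit branch length at stationarity. A genome pair descends from
a common ancestor along two branches of t/2 each, so the pairwise
divergence is t substitutions per codon. Genes are wrapped with ATG/TAA
and placed (random strand) on a single contig between noncoding spacers
sized to hit the requested noncoding fraction; spacers descend from a
shared ancestral sequence under Jukes–Cantor at the neutral per-site
rate, so ANI sees genome-wide divergence, and both genomes share one
layout.

Cohorts inject the structure the analysis is meant to detect: in the
archaeal-like regime the generating ω rises log-linearly from 0.08 to
0.32 across the genome-size gradient and the noncoding fraction rises
from 8% to 30%; in the bacterial-like regime ω falls across the same
gradient and the noncoding fraction stays flat at 12%. Divergences are
drawn uniformly on t ∈ [0.3, 0.6] substitutions/codon, which places
computed ANI in roughly the 80–92% range — inside the 75–95% band that
empirically delineates congeneric pairs. Default per-pair conditions for
validation runs are 500 genes × 300 codons, ω = 0.2, κ = 2, t = 0.3,
uniform codon frequencies, 15% noncoding; cohort genomes are smaller
(60–140 genes × 150 codons) so a 12-pair cohort analyzes in minutes.

What the simulator deliberately does **not** model: indels within genes
(back-threading is exercised by unit fixtures with gaps instead), gene
gain/loss and HGT, mobile-element or repeat structure in spacers,
among-gene and among-site ω variation (a single ω per pair, because the
pipeline estimates a genome-wide mean), and codon-usage differences
between the two genomes of a pair. Passing the recovery tests therefore
shows the estimation chain is correct and unbiased under the model's own
assumptions; it does not certify behavior on real genomes with
rearrangements, contamination, or annotation error.

## Numerical and design choices

* Genetic code table 11 (bacterial/archaeal) everywhere, configurable
  per genome; translation treats N-containing codons as X and they are
  excluded from dN/dS counting (pairwise deletion).
* Coordinates are 1-based inclusive end to end, matching GFF3 and the
  R/Bioconductor container conventions, so there is no internal
  coordinate translation to get wrong.
* The transition kernel `exp(Qt)` is computed by symmetric
  eigendecomposition of the reversible generator (exact to machine
  precision; tiny negative entries are clipped and rows renormalized).
* All randomness flows through explicit integer seeds; cohort members
  derive per-pair seeds from the cohort seed, and identical seeds give
  byte-identical FASTA/GFF3/TSV outputs (tested).
* κ estimation guards: classes with fewer than 4 comparable sites are
  ignored, an undefined or non-positive transversion distance falls back
  to κ = 1, and κ is capped to [0.01, 99].
* In the ω iteration, ω and κ are floored at 1e-6 inside pathway weights
  so a pure-nonsynonymous gene cannot zero out every pathway.

## Validation problem sizes

The test suite validates at the following scales, chosen to give tight
sampling error while keeping a full run in minutes: estimator recovery on
single alignments at 10,000–20,000 codons (sampling SEM on ω ≈ 1–2%);
pipeline recovery at 500 genes × 300 codons per ω in
{0.05, 0.2, 0.5, 1.0}; neutral calibration over 20 replicates of 20,000
codons; cohort sign recovery at 12 pairs per regime; determinism on
5-pair cohorts.

One validation outcome deserves its own paragraph. At neutral divergence
(ω = 1) with t = 0.3 substitutions per codon, the generating process has
dS = t/3 = 0.1 — *exactly* the dS < 0.1 discard boundary. Per-gene dS
estimates scatter around 0.1, the filter removes the lower half, and
because ω = dN/dS is anticorrelated with dS at fixed dN, the retained
mean ω is biased downward: about 0.87 for YN00 and 0.81 for NG86 (which
additionally carries the classic downward bias of κ-blind counting when
the true κ = 2). This is a real property of applying a hard dS floor to
near-neutral, shallowly diverged gene pairs — not an estimator defect;
the unfiltered YN00 mean at the same setting is 1.05. The recovery test
asserts the 15% band at every grid point regardless, so the NG86/ω = 1
case is expected to fail there and is documented here rather than
patched around. Practical reading: per-pair mean ω from this pipeline
(and from the filtering convention it reproduces) is conservative —
biased toward stronger apparent purifying selection — precisely when a
cohort contains near-neutral pairs at shallow divergence.

## Known limitations

* The exact-alignment BBH is O(n²) in proteome size without the k-mer
  prefilter and is meant for desk-scale and simulated genomes; real
  proteome pairs should come in through the external-hits interface.
* YN00 here is the counting scheme, not a reimplementation of any
  specific tool's numerical quirks; on borderline-saturated pairs
  different implementations legitimately disagree, which is why the
  filters discard that regime.
* ANI's seeded search assumes mostly collinear genomes at ≳75%
  identity; heavily rearranged genomes would rely on the full-alignment
  fallback, which is exact but slow.
* The union coding density treats any annotated CDS overlap as shared
  sequence; the literal mode exists to quantify how much that choice
  matters on a given annotation.
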