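---
title: "Methods: models, parameters and design choices in smallRNAome"
author: "smallRNAome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

smallRNAome analyses developmental small-RNA sequencing designs — a
handful of stages, few replicates, tens of millions of short single-end
reads — and answers the questions such studies ask: which mature miRNAs
are expressed and how strongly, which are cross-species homologs or
edited variants, which genomic clusters are active, which miRNAs change
between stages, how their trajectories group over time, which loci
harbor unannotated hairpins, and which target genes respond in the
opposite direction. This vignette documents the models behind each
stage, the tunable parameters, the synthetic benchmark and its limits,
and the design decisions taken where more than one defensible choice
existed.

## Read cleaning and collapsing

A read is kept only if it survives, in order: at most `maxN = 1` unknown
base; at most `maxLowQualityBases = 1` bases below Phred
`qualityThreshold = 20`; no 5' adapter at the read start (prefix match
of `adapterMatchMin = 8` nt); a 3' adapter present (leftmost exact match
of its 8 nt prefix — library preparation guarantees an adapter on any
genuine insert, so its absence marks an artifact); a non-empty insert
(an empty insert is an adapter dimer); an insert below `polyAFraction =
0.9` adenine (poly(A) carry-over; the threshold is deliberately high so
genuinely A-rich miRNAs are not discarded); and an insert length inside
`[16, 35]` nt. The lower bound is the conventional small-RNA limit; the
upper bound reflects the size selection of small-RNA libraries and is
exposed in `qcParams()`. A read is labeled with the *first* rule it
violates, which makes the per-reason counts a partition of the raw
reads — `total = kept + sum(rejected)` is asserted, not assumed.
Surviving inserts are collapsed to unique tags with per-library counts
(`collapseReads()`), the unit all downstream annotation works on;
collapsing is order-invariant by construction (lexicographic tag order).

Whole-read filtering only: there is no quality trimming, matching the
cleaning rules this pipeline models.

## Hierarchical annotation

Every tag receives exactly one category via a fixed priority:
ncRNA (GenBank-style rRNA/tRNA before Rfam-style snRNA/snoRNA) >
known miRNA > edited miRNA > cross-species homolog > repeat > exon >
novel-miRNA candidate > intron > unannotated.

*Known-miRNA matching* is tolerant of isomiR end variation: a tag hits a
mature arm iff it equals a precursor substring whose ends lie within
±2 nt of the annotated arm ends ("extending or shortening" is read
per-end, the isomiR convention, not as a total-length change). This is
implemented as an exact dictionary of all (off5, off3) windows, which
makes matching a hash join and — more importantly — makes the matcher's
semantics auditable: the test suite checks it against a brute-force
slide-and-compare oracle built on `Biostrings::neditStartingAt`.
Ties break by smaller `|off5| + |off3|`, then lexicographic id.
*Edited/SNP variants* are the same windows at exactly one mismatch,
reported in mature coordinates. *Homolog matching* aligns tags to
foreign-species arms with ≤2 mismatches and the same ±2 nt windows;
best hit = fewest mismatches, then smallest total offset, then id.
Foreign arms with identical sequences collapse to a single homolog
entity named without the species prefix, since the same mature sequence
recorded under several species is one biological entity. As the
homolog tier also captures own-species arms carrying non-templated 3'
additions, homolog counts are reported as their own category
(`homolog-miRNA`) rather than being folded into known miRNAs — the two
cannot be distinguished from sequence alone.

*Genome mapping* is exact and full-length on both strands
(`PDict`/`matchPDict`); tags with loci but no higher-priority hit fall
to repeat/exon by feature overlap, then to novel candidacy (outside
gene regions, approximated as per-gene exon spans ± `geneFlank` =
2 kb) or intron. One consequence worth stating: intron-hosted novel
hairpins (mirtrons) are not candidates under this rule. Multi-mapping
tags contribute to every locus when loci matter (feature overlap,
hairpin excision) but are counted once for quantification.

## Quantification, tiers and descriptive structure

Counts aggregate per mature id (isomiRs and single-mismatch edits
included) and per homolog entity. RPM uses the per-library count of
genome-mapped clean reads as denominator — "mapped reads" is ambiguous
between genome-mapped and miRNA-mapped, and the genome-mapped reading
was chosen and recorded in `colData()` so any analysis can audit it.
The overall average is the unweighted mean of per-library RPM (under
equal replication it equals the mean of stage means, which is exactly
the arithmetic the shipped published abundance table satisfies, and
the acceptance tests verify row by row). Retention requires overall
average > 1 RPM; tiers are low < 100 ≤ moderate < 1000 ≤ high, with the
>10,000 RPM set reported separately — thresholds taken from the
functional-abundance literature the study design follows. Percent of
total is computed over retained known miRNAs only, excluding homologs
and novels, so the shares match a known-miRNA table.

Genomic clusters are maximal same-chromosome runs of miRNA genes
(overall average > 100 RPM) whose adjacent gaps are ≤ `window`
(default 100 kb), reported at ≥ `minSize` = 3 members; detection is
order- and translation-invariant. Heatmap structure uses average-linkage
agglomeration on correlation distance of per-stage RPM rows, rows
pre-sorted by id so ties resolve deterministically; the two top-level
groups are the root's children.

## Differential expression

Between-library normalization is upper-quartile: the factor is the 75th
percentile of a library's nonzero counts rescaled to unit geometric
mean, and the effective library size is the mapped-read denominator
times the factor. A common negative-binomial dispersion is estimated by
maximizing the conditional (qCML-style) log-likelihood over replicate
groups — conditioning on within-group sums removes the unknown means —
after quantile-scaling counts to a common effective size (rounding half
away from zero); the search is bounded to [0, 5] at tolerance 1e-6,
with the Poisson limit at zero. The two-group test conditions on the
pooled total and sums the probabilities of all group-A totals at most
as likely as the observed one (the "small-p" two-sided rule); with
equal per-library means the conditional law is free of the mean, a
negative-hypergeometric mass computed stably in log space. The test is
anchored by two independent oracles in the suite: direct `dnbinom`
enumeration, and edgeR's exact test with the same rejection region.
Fold changes are `log2((meanB + 0.5)/(meanA + 0.5))` on scaled counts —
the 0.5 pseudo-count (no value is prescribed by the rule set this
implements; 0.5 is the customary stabilizer) is recorded here and in
the function documentation. Positive log2FC means higher in the later
stage. Calls require `|log2FC| ≥ 1` and BH FDR ≤ 0.05 within each
comparison.

## Temporal model profiles

Trajectories are per-stage means of `log2(RPM + 1)` — the +1 offset
handles zero RPM, which the bare log transform cannot. All integer
template profiles starting at 0 with per-step changes in [-c, c] are
enumerated ((2c+1)^(T-1) = 27 at the defaults c = 1, T = 4, within the
30-profile cap; when over the cap, greedy max–min Euclidean selection
seeded from the flat profile keeps the most distinct templates). Each
DE miRNA joins the profile maximizing Pearson correlation (flat
trajectories go to the flat profile). Significance: expected
per-profile counts come from re-assigning every miRNA under all T! = 24
stage-order permutations; the p-value is the upper-tail binomial
probability of the observed count at that expected rate, Bonferroni
corrected across profiles (the conservative correction is the cited
algorithm family's default; the suite verifies family-wise error ≤
0.05 plus simulation margin over 200 null replicates).

## Novel miRNA discovery

Unannotated genome-mapped tags are clustered (same chromosome/strand,
gaps ≤ 30 nt); clusters with ≥ 5 reads yield two candidate windows
anchored on the dominant read (block − 70 nt upstream, and + 70 nt
downstream), the hairpin-scale excision a precursor search needs even
when scattered reads chain into long blocks. Candidates are folded with
a deliberately simplified, fully specified energy model: stacked-pair
energies GC/CG −3.0, AU/UA −2.0, GU/UG −1.0 kcal/mol (each adjacency
contributes the mean of its two pair energies, so a uniform stem of
k+1 pairs scores k times the pair energy), hairpin loops ≥ 3 nt, flat
penalties +3 (hairpin), +2 (interior/bulge), +3 (multiloop), interior
loops capped at 30 nt. This is not the Turner model; it preserves the
semantics of an MFE threshold while remaining short enough to verify
against exhaustive structure enumeration (which the tests do for
sequences up to 16 nt, using an independent energy evaluator over pair
sets).

Two detectors vote. Detector A scores
`3·(fraction of reads consistent with one dominant arm ±2 nt) +
1.5·(star-arm read support) + 1.5·(MFE < −18) + 1.5·(≥14 mature bases
paired)` and passes at ≥ 5, so a read stack can only pass with a
dominant arm plus at least two structural/star corroborations.
Detector B is rule-based: MFE < −18 kcal/mol, mature arm entirely
within one stem arm, ≤ 4 nt 5'-end variability, precursor 60–110 nt. A
call requires both detectors *and* a dinucleotide-shuffling p-value
< 0.05 (fraction of 100 composition-preserving shuffles folding at or
below the observed MFE) — under this permissive energy model random
~100-mers reach −35 to −45 kcal/mol, so the randomization test, not the
absolute threshold, carries most of the specificity. Calls sharing a
mature sequence collapse to one mature with all precursor records
(the intersection key is exact mature identity), and names are
assigned by descending total count.

## Target prediction and enrichment

Three archetypal site finders run on identical inputs and only
unanimous (miRNA, gene) pairs survive — the intersection is the decision
rule being modeled; the finders themselves are transparent archetypes
of the usual tool trio. (1) Seed scan: 7mer-m8 (reverse complement of
positions 2–8), 7mer-A1 (positions 2–7 plus a genomic A opposite
position 1), 8mer (both). (2) Weighted local alignment: +5 Watson–
Crick, +1 G:U, −3 mismatch, gaps −8/−2, seed positions ×2, threshold
140 — a perfect 22-mer complement scores 145, a perfect 21-mer exactly
140, so shorter miRNAs need near-perfect sites. (3) Intermolecular
duplex energy under the same stacking table (loops ≤ 8 nt, threshold
−15 kcal/mol); under this permissive model the duplex filter is the
least selective of the three, which is why it is never used alone.
Pairs are then restricted to miRNAs differentially expressed in the
comparison with overall average > 100 RPM (the functional-abundance
focus) and kept only when the mRNA log2 fold change is nonzero with
the opposite sign; no mRNA fold-change magnitude threshold is applied
(sign-only rule; a magnitude cut can be layered on the returned table).
Enrichment against user-supplied gene sets is upper-tail
hypergeometric with an optional EASE variant (overlap decremented by
one), BH-corrected, with the background equal to the genes actually
scanned (all genes with UTRs supplied) rather than a genome-wide
universe.

## The synthetic benchmark: what it emulates, and what it does not

`buildReference()`/`buildTruthTable()`/`simulateLibraries()` generate a
self-consistent reference bundle and stage-structured libraries with
planted, recoverable truths. The default study conditions are four
stages (E45, E60, E105, B3) × 2 replicates × 200,000 reads of 50 nt,
~300 miRNA genes (mature lengths peaked at 22 nt) of which 50 form a
cluster inside a 1 Mb window of one chromosome carrying two planted
co-expression programs, 60 designed 4-fold DE miRNAs at balanced stage
transitions (base 500–3000 RPM), a constant ~10,000 RPM sentinel with a
fixed absolute read share, 10 single-base editing events at rate 0.15,
foreign homolog donors at exactly two substitutions (verified ≥ 2
mismatches from every own-species window, so homolog truth is
unambiguous) plus 3'-addition entries, 10 novel hairpins (one planted
at two genomic copies; imperfect stems with three star substitutions
and complementary lower stems), six decoy loci receiving scattered
reads, and read-class fractions (62% miRNA, 10% ncRNA, 4% homolog, 13%
genomic feature/background, 11% rejection classes) chosen to give
~89% clean reads and ~84% genome-mapped clean reads. Replicate-level
biological noise is gamma-distributed with squared CV φ = 0.1 and is
drawn in the truth table, so the stored per-library proportions are
the exact binomial expectations of the simulated counts — recovery
tests use exact 3σ binomial bounds, not loose heuristics. isomiR ends
shift independently per end with P(0, ±1, ±2) = (0.6, 0.15, 0.05);
shifts are templated, so matcher truth stays unambiguous. Cluster
genes sit on a jittered ~20 kb grid so every adjacent gap is far below
the 100 kb detection window at any seed.

What passing these tests does *not* show about real data: no
sequencing-error model beyond the planted classes (no quality-by-cycle
decay, no PCR duplicates), uniform random genome (no repeat families
or GC structure, so multi-mapping is much rarer than in a real
genome), ncRNA contaminants absent from the genome, UTRs independent
of the genome, and hairpins with cleaner read stacks than degradation
products produce. The benchmark measures whether the implementations
do what their definitions say under the stated noise model — it cannot
certify performance on a real muscle miRNAome.

Problem sizes were chosen so the full benchmark (simulation through
novel calling) runs in about two minutes and the complete test suite
in under four on a single core, while keeping every planted effect in
the regime the methods are designed for (counts of tens to thousands
per library). The DE recall criterion is intrinsically tight at these
conditions: with two replicates and φ = 0.1 the biological standard
deviation of an estimated log2 fold change is ≈ 0.46, so recall of
planted 4-fold changes at |log2FC| ≥ 1 and FDR ≤ 0.05 sits near
0.9–0.93; the packaged benchmark seed yields 0.915.

## Known limitations

Besides the synthetic-data caveats above: genome mapping is exact-match
only (no mismatch allowance, as specified for this design); the
annotation hierarchy acknowledges but does not resolve the
homolog/3'-modification ambiguity; the folding model has no pseudoknots
or Turner-accurate loop energies; tagwise or trended dispersion
shrinkage, GLM designs and batch covariates are out of scope; and the
profile permutation scheme assumes exchangeable stages under the null,
which short strongly-autocorrelated designs can violate.
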