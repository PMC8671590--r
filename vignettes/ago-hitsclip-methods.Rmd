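---
title: "Methods: from CLIP tags to miRNA targetomes and super-enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CLIP tags to miRNA targetomes and super-enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agoclip)
```

## What the package computes

Argonaute (Ago) HITS-CLIP captures short sequencing tags wherever an
Ago–miRNA complex was crosslinked to an mRNA in vivo. From aligned tags,
`agoclip` reconstructs the regulatory readout of such an experiment across
developmental stages:

1. **Cluster calling** (`call_clusters()`): overlapping same-strand tags in a
   stage (replicates pooled) are grouped into clusters — candidate
   Ago-binding sites. Each cluster carries its peak height (maximum per-base
   tag depth), summit (leftmost base attaining it), tag count and replicate
   support.
2. **Annotation** (`annotate_clusters()`): clusters are assigned to a
   transcript feature at their summit.
3. **Targetome** (`build_targetome()`): cluster sequences (sense strand) are
   scanned for canonical miRNA seed matches, producing one miRNA–mRNA
   interaction per seed locus.
4. **miRNA profiles** (`quantify_mirnas()`, `cluster_stage_profiles()`):
   Ago-bound miRNA abundances per stage, grouped into stage-enriched
   clusters.
5. **Motif enrichment** (`kmer_enrichment()`): a z-score test of k-mer
   over-representation in cluster sequences against dinucleotide-preserving
   shuffles.
6. **Knockout validation** (`ks_shift_test()`): a one-sided two-sample
   Kolmogorov–Smirnov test of target de-repression in knockout expression
   data.
7. **Super-enhancers** (`stitch_peaks()`, `hockey_stick_cutoff()`,
   `assign_se_to_tss()`): ROSE-style identification from H3K27ac peaks and
   assignment to the nearest gene/miRNA TSS.

A synthetic-data generator (`synth_config()`, `generate_reference()` and the
`simulate_*()` family) plants known target sites, expression shifts and
super-enhancers and exports the truth tables, so every stage is testable
end to end without external data.

## Cluster calling

Two tags belong to one cluster iff they are connected by a chain of
same-strand interval overlaps of at least one shared base; BED half-open
semantics are strict, so bookended tags (`[0,10)`, `[10,20)`) do not merge.
Peak height and summit are computed from per-base coverage; the summit
tie-break is the leftmost maximal base, which makes annotation
deterministic.

"High-confidence" filtering is not standardised in the field; the defaults
`min_peak_height = 5` and `min_replicates = 2` reflect a two-replicate
design in which a reproducible binding site should be sampled several times
in at least both replicates. Both are arguments, not constants. Replicates
are pooled per stage before calling, and replicate support is evaluated on
the pooled cluster, which matches per-stage targetome reporting. Duplicate
tags are counted, not collapsed: PCR-duplicate removal belongs to upstream
read processing.

## Annotation choices

A cluster is annotated at its summit because the summit marks the densest
part of the Ago footprint, and point assignment makes the priority rule
unambiguous. When the summit hits features of several transcripts, the
priority is `3UTR > 5UTR > CDS > ncRNA_exon > intron` (configurable): the
3'UTR is the primary functional compartment for seed-mediated repression,
so ambiguous summits resolve toward it. Any transcript of any gene may
claim a summit (union annotation across transcript models). A cluster must
match the gene's strand to be genic; otherwise it is intergenic.

## Seed-match taxonomy

For a miRNA with mature sequence $m$, seed positions 2–7 (seed6) and 2–8
(seed7) define four canonical site types on the mRNA sense strand:
`6mer` = revcomp(seed6), `7mer-m8` = revcomp(seed7),
`7mer-A1` = revcomp(seed6)+`A`, `8mer` = revcomp(seed7)+`A`. The `A` anchor
is required in the mRNA regardless of the miRNA's first base
(TargetScan-style). A locus is identified by its 6mer core position, and
only the strongest satisfied type is reported there
(`8mer > 7mer-m8 > 7mer-A1 > 6mer`). Non-canonical sites (G:U wobbles,
seedless interactions) are out of scope, as is context scoring. The same
rules are applied in every transcript region; the region label is carried
in the output so 3'UTR-only analyses are a filter away.

## Abundance profiles and stage clustering

miRNA abundance is reported as reads per million miRNA-mapped tags (RPM);
mature miRNA lengths are nearly constant, so a length-normalised axis
(FPKM-like) differs only by a constant factor. Stage profiles are z-scored
per miRNA and clustered hierarchically with correlation distance
(1 − Pearson) and average linkage; the tree is cut at `k = 5` groups by
default, one per developmental stage of the design, and each group is
labelled by the stage at which its mean z-profile peaks. Distance and
linkage follow the goal of grouping by expression *pattern* rather than
magnitude; both are stated defaults, not inevitabilities, and `k` is an
argument. Constant profiles carry no pattern and are excluded with a
warning. Stage log2 fold changes use a 1 RPM pseudocount.

A miRNA is "expressed" in a stage when its RPM reaches half of its own
across-stage maximum. This profile-relative rule tracks stage-restricted
expression regardless of absolute abundance and determines which miRNAs are
scanned against each stage's clusters.

## Motif enrichment

The k-mer test counts overlapping occurrences across cluster sequences and
compares them with `n_shuffles` per-sequence dinucleotide-preserving
shuffles (random Euler path on the dinucleotide transition multigraph,
Altschul–Erickson construction, implemented in C++ for speed and seeded for
reproducibility). Enrichment is `z = (obs − mean)/sd` over shuffles; a
k-mer with `sd = 0` is unenrichable under this background and gets `z = 0`
rather than an infinity. `k = 7` matches the seed-match length;
`n_shuffles = 100` keeps the sd estimate stable enough that, on null
sequences, fewer than 1% of k-mers reach `z > 3` (the acceptance suite
measures this). Ties in z order lexicographically. This bespoke test
replaces external motif-discovery tooling so the analysis is
self-contained; it reports enriched exact k-mers, not position-weight
matrices.

## Knockout CDF-shift test

Losing a miRNA de-represses its targets, shifting their log2 fold-change
(KO vs WT) distribution to the right. The test statistic is the one-sided
two-sample Kolmogorov–Smirnov quantity
$D = \sup_x\,[F_{\mathrm{background}}(x) - F_{\mathrm{test}}(x)]$
with right-continuous ECDFs evaluated at pooled sample points (ties need no
jitter). The p-value is the one-sided asymptotic bound
$p = \exp(-2 D^2 mn/(m+n))$, or, when $m+n \le 16$ (or on request), the
exact permutation probability over all $\binom{m+n}{m}$ label assignments.
The one-sided direction is fixed so that "targets up in KO" is the
alternative. Gene classes are mutually exclusive: `clip_target` (an
Ago-bound site for the miRNA in the chosen region), `seed_only` (a seed
match in the annotated region but no CLIP site — CLIP evidence dominates),
and `background` (everything else in the expression universe, i.e.
excluding both other classes).

## Super-enhancers

Peaks whose gap is at most 12.5 kb (the published ROSE stitching default;
boundary-inclusive) are chained into stitched regions whose signal is the
sum of constituent scores, optionally input-subtracted and clipped at zero.
On the rank-vs-signal curve with both axes scaled to [0, 1], the cutoff is
the discrete tangent point of a slope-1 line — the first point minimising
`scaled_y − scaled_x`. Regions strictly above the cutoff are
super-enhancers. The discrete tangent was chosen over a smoothed geometric
tangent because it is deterministic and directly checkable against planted
signal mixtures; a scan rule based on consecutive-point slopes was
considered and rejected because adjacent high-signal regions of similar
magnitude produce an interior slope below 1 and make the rule miss planted
super-enhancers. No TSS-exclusion zone is applied. Each super-enhancer is
assigned to the nearest gene or miRNA TSS within ±100 kb, measured from the
region boundary (0 inside), with distance ties resolved toward the miRNA
class.

## The synthetic study and what it does (not) show

The generator emulates a five-stage (e12.5, e15.5, e18.5, P7, adult),
two-replicate design:

* **Reference**: random chromosomes; single-exon gene models with
  non-overlapping 5'UTR/CDS/3'UTR on either strand; a 20–24 nt miRNA
  catalog, each miRNA enriched in exactly one stage (round-robin).
* **Planted sites**: per miRNA, seed-match strings written into gene
  regions (60/30/10% across 3'UTR/CDS/5'UTR by default), one site per gene
  region, truth exported.
* **Tags**: per replicate, a planted site draws
  `Poisson(site_rate × activity)` tags fully covering it (activity 1 in the
  enriched stage, 0.05 elsewhere), over a homogeneous Poisson background of
  0.2 tags/kb/strand. Lengths are a discretised Normal(22, 1.5) clipped to
  [18, 40], reproducing the 22 nt mode expected of Ago-bound tags.
* **KO expression**: targets of the knocked-out miRNA from
  Normal(shift, sigma), everything else Normal(0, sigma); defaults
  shift 0.5, sigma 0.5, a mid-sized de-repression against realistic
  microarray-scale noise.
* **H3K27ac**: 30 well-separated constituent-peak groups; a planted
  fraction (10%) are super-enhancers with per-peak gamma signal at 15× the
  typical mean, placed near a designated miRNA TSS; with stage labels, a
  super-enhancer is "on" only in its miRNA's enriched stage.

Problem sizes used in tests and in the acceptance script (2 × 500 kb
chromosomes, 40 genes, 25 miRNAs, ~75 planted sites; 10–20 seeds per
property) were chosen so the whole suite runs comfortably on a laptop while
keeping Monte-Carlo error well inside the asserted margins.

Passing on synthetic data demonstrates the *algorithms* — grouping,
scanning, ranking, testing — recover exactly what was planted under the
stated noise models. It does not demonstrate robustness to features of real
CLIP data that are deliberately not simulated: crosslink-induced mutations,
mapping ambiguity and multimapping, PCR duplication, isoform complexity and
overlapping genes, chimeric reads, or non-canonical binding. Dataset-scale
figures from real experiments (tens of thousands of clusters, a million
interactions) depend on sequencing depth and genome/annotation versions and
are not reproduced at this scale.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere in memory and in BED output;
  GTF is written 1-based inclusive per the standard.
* Cluster summit ties break to the leftmost base; z-score ties in motif
  tables break lexicographically; equal-RPM ties in top-n selections break
  lexicographically by miRNA name; TSS-distance ties prefer the miRNA
  class, then the smaller coordinate.
* Empty inputs that make a statistic undefined (no tags, no clusters, empty
  expression universe, all sequences shorter than k) raise errors naming
  the problem; recoverable oddities (unknown chromosome, constant profiles,
  sequences shorter than k, n beyond the catalog) warn and continue.
* All simulators are pure functions of their configuration and seed; the
  pipeline writes byte-identical output trees for identical configurations.

## Known limitations

* Seed-only scanning (no binding-energy or conservation context) means
  chance 6mer matches inside genuine clusters appear as low-grade
  interactions; gene-level precision on planted data stays above 0.9, with
  the remainder being exactly such chance seed occurrences.
* The exact KS enumeration is limited to small samples
  (`m + n ≤ 16` by default) before combinatorics dominate; larger samples
  use the asymptotic bound, which is conservative.
* Stage clustering assumes profiles are comparable after z-scoring; miRNAs
  with near-constant profiles are excluded rather than forced into a group.
* The hockey-stick cutoff assumes at least a weakly bimodal signal
  distribution; on unimodal data it still flags a top tail, which is why
  planted-truth checks, not the cutoff alone, validate super-enhancer
  calls.
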