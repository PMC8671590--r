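# agoclip

Analysis toolkit for **Argonaute (Ago) HITS-CLIP** experiments across
developmental stages. Ago HITS-CLIP sequences the short RNA tags that were
crosslinked to Ago–miRNA complexes in vivo, marking where miRNAs actually
bind. Starting from aligned tags, `agoclip` reconstructs the regulatory
readout of such an experiment:

- **Cluster calling** — overlapping same-strand tags (replicates pooled per
  stage) become Ago-binding clusters with peak height (maximum per-base
  depth), summit, tag count and replicate support; clusters below
  configurable peak-height/replicate filters are dropped.
- **Feature annotation** — each cluster is labelled at its summit
  (`3UTR > 5UTR > CDS > ncRNA_exon > intron`, else intergenic) from GTF gene
  models.
- **Seed-match targetome** — cluster sequences are scanned for the four
  canonical site types of each expressed miRNA (for seed positions 2–7/2–8:
  `6mer` = revcomp(seed6), `7mer-m8` = revcomp(seed7), `7mer-A1` =
  revcomp(seed6)+A, `8mer` = revcomp(seed7)+A, strongest type per locus),
  yielding a miRNA–mRNA interaction table.
- **Stage profiles** — Ago-bound miRNA abundances in RPM, hierarchically
  clustered (z-scored rows, 1 − Pearson distance, average linkage, cut at
  k = 5) into stage-enriched groups.
- **Motif enrichment** — k-mer z-scores against dinucleotide-preserving
  shuffled backgrounds (seeded Altschul–Erickson Euler-path shuffle),
  matched back to miRNA seed complements.
- **Knockout validation** — a one-sided two-sample Kolmogorov–Smirnov test
  of target de-repression, `D = sup_x [F_background(x) − F_test(x)]` with
  `p = exp(−2D²mn/(m+n))` or exact permutation for small samples.
- **Super-enhancers** — ROSE-style peak stitching (12.5 kb gap), a
  hockey-stick slope-1 tangent cutoff on rank-scaled signal, and assignment
  to the nearest gene/miRNA TSS within ±100 kb.

A synthetic-data generator plants ground-truth target sites, knockout
shifts and super-enhancers, and exports truth tables, so the entire
pipeline is testable end to end with no downloads. All user-facing
functions take and return tibbles and compose with the pipe; fitted KS
objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(agoclip)

cfg <- synth_config(rng_seed = 7, n_genes = 20, n_mirnas = 10, sites_per_mirna = 2)
ref  <- generate_reference(cfg)          # genome + gene models + planted sites
clip <- simulate_clip_tags(ref)          # 5 stages x 2 replicates of tags

modal_length(tag_length_distribution(clip$tags))
#> [1] 22

clusters <- call_clusters(clip$tags, min_peak_height = 5, min_replicates = 2)
labeled  <- annotate_clusters(clusters, gene_feature_table(ref))
feature_distribution(labeled)
#> # A tibble: 6 x 3
#>   feature     n fraction
#> 1 3UTR       19   0.543
#> 2 5UTR        3   0.0857
#> 3 CDS        13   0.371
#> # ...

profiles <- quantify_mirnas(simulate_mirna_counts(ref))
ia <- build_targetome(labeled, ref$genome, ref$mirnas, expressed_mirnas(profiles))
head(ia, 3)
#> # A tibble: 3 x 7
#>   mirna   gene_id cluster_id region site_type stage offset
#> 1 mir-004 gene010 P7_c00004  3UTR   7mer-A1   P7        17
#> 2 mir-004 gene019 P7_c00002  CDS    7mer-m8   P7        15
#> 3 mir-009 gene004 P7_c00003  3UTR   7mer-A1   P7        17
```

The interaction table recovers all 19 distinct planted (miRNA, gene) pairs
of this configuration. The 22 nt modal tag length is the expected signature
of Ago-bound tags; the feature fractions say where binding concentrated
(here 54% of clusters sit in 3'UTRs). Knockout de-repression of a target
set shows up as a rightward CDF shift:

```r
universe <- sprintf("g%04d", 1:1000)
fc <- simulate_log2fc(universe, universe[1:100], shift = 0.5, sigma = 0.5, seed = 7)
ks_shift_test(fc$log2fc[1:100], fc$log2fc[101:1000])
#> One-sided two-sample Kolmogorov-Smirnov shift test
#>   alternative: test sample shifted up
#>   D = 0.4533, p = 8.602e-17 (asymptotic), m = 100, n = 900

hockey_stick_cutoff(c(1, 2, 3, 100))
#> $cutoff
#> [1] 3
#> $is_SE
#> [1] FALSE FALSE FALSE  TRUE
```

`run_pipeline(pipeline_config(synth_config(rng_seed = 1)), outdir = "out")`
executes every stage in order and writes per-stage files plus
`summary.json` and a `manifest.tsv`; identical configurations reproduce
byte-identical outputs. A thin CLI lives at `exec/agoclip`
(`agoclip --config cfg.yaml --seed 1 --outdir out`).

## Vignette

`vignettes/ago-hitsclip-methods.Rmd` documents the models and assumptions:
the cluster and seed-site definitions, the KS test construction, the
hockey-stick geometry, what the synthetic generator does and does not
emulate, and the package's numerical conventions and limitations.
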