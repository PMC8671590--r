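# Shared fixture builders for the test suite.

# A small but complete study configuration, fast enough to simulate in tests.
small_config <- function(rng_seed = 1L, ...) {
  synth_config(
    rng_seed = rng_seed,
    n_chroms = 2L, chrom_length = 200000L,
    n_genes = 16L, n_mirnas = 10L,
    sites_per_mirna = 2L,
    n_h3k27ac_regions = 6L,
    ...
  )
}

# Random tag tables for oracle comparisons.
random_tags <- function(n_tags, span = 300L, n_replicates = 2L) {
  start <- sample.int(span, n_tags, replace = TRUE) - 1L
  len <- sample(3:40, n_tags, replace = TRUE)
  tibble::tibble(
    chrom = sample(c("c1", "c2"), n_tags, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n_tags, replace = TRUE),
    stage = "s1",
    replicate = sample.int(n_replicates, n_tags, replace = TRUE)
  )
}

random_catalog <- function(n, len_range = 20:24) {
  tibble::tibble(
    name = sprintf("m%02d", seq_len(n)),
    seq = vapply(sample(len_range, n, replace = TRUE), function(L) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1))
  )
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Hand-built two-transcript GTF fixture: transcript A's CDS and transcript
# B's 3'UTR overlap on chrT:+, so a summit in the overlap probes the
# annotation priority rule. B is multi-exon so the reader derives an intron.
write_two_transcript_gtf <- function(path) {
  lines <- c(
    # transcript A: exon 1-1000 (1-based), CDS 201-800 -> 5UTR 1-200, 3UTR 801-1000
    'chrT\ttest\texon\t1\t1000\t.\t+\t.\tgene_id "geneA"; transcript_id "geneA.t1";',
    'chrT\ttest\tCDS\t201\t800\t.\t+\t0\tgene_id "geneA"; transcript_id "geneA.t1";',
    # transcript B: exons 301-700 and 901-1200, CDS 301-400 -> 3UTR 401-700,901-1200
    'chrT\ttest\texon\t301\t700\t.\t+\t.\tgene_id "geneB"; transcript_id "geneB.t1";',
    'chrT\ttest\texon\t901\t1200\t.\t+\t.\tgene_id "geneB"; transcript_id "geneB.t1";',
    'chrT\ttest\tCDS\t301\t400\t.\t+\t0\tgene_id "geneB"; transcript_id "geneB.t1";',
    # transcript C: no CDS -> ncRNA exons
    'chrT\ttest\texon\t2001\t2300\t.\t-\t.\tgene_id "geneC"; transcript_id "geneC.t1";',
    # transcript D: two exons with a bare intron 3101-3300 (1-based gap)
    'chrT\ttest\texon\t3001\t3100\t.\t+\t.\tgene_id "geneD"; transcript_id "geneD.t1";',
    'chrT\ttest\texon\t3301\t3400\t.\t+\t.\tgene_id "geneD"; transcript_id "geneD.t1";',
    'chrT\ttest\tCDS\t3001\t3100\t.\t+\t0\tgene_id "geneD"; transcript_id "geneD.t1";'
  )
  writeLines(lines, path)
  path
}
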