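test_that("configuration validation rejects impossible studies", {
  expect_error(synth_config(n_replicates = 0), "n_replicates")
  expect_error(synth_config(site_rate = 0), "site_rate")
  expect_error(synth_config(se_fraction = 1), "se_fraction")
  expect_error(synth_config(stages = c("a", "a")), "distinct")
  # genes cannot fit on the chromosome
  expect_error(
    generate_reference(synth_config(chrom_length = 5000, n_genes = 10)),
    "too small to place"
  )
})

test_that("reference generation is deterministic and well-formed", {
  cfg <- small_config(rng_seed = 42)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(ref1$sites, ref2$sites)
  expect_identical(ref1$mirnas, ref2$mirnas)

  # catalog: requested count, mature lengths 20-24 over the RNA alphabet
  expect_equal(nrow(ref1$mirnas), 10)
  expect_true(all(nchar(ref1$mirnas$seq) >= 20 & nchar(ref1$mirnas$seq) <= 24))
  expect_false(any(grepl("[^ACGU]", ref1$mirnas$seq)))

  # gene regions are disjoint and ordered 5'UTR-CDS-3'UTR in transcript sense
  g <- ref1$genes
  expect_true(all(g$start < g$end))
  for (i in seq_len(nrow(g))) {
    ivs <- rbind(c(g$utr5_start[i], g$utr5_end[i]),
                 c(g$cds_start[i], g$cds_end[i]),
                 c(g$utr3_start[i], g$utr3_end[i]))
    ivs <- ivs[order(ivs[, 1]), ]
    expect_true(all(ivs[-3, 2] <= ivs[-1, 1]))
  }
  pos <- g[g$strand == "+", ]
  expect_true(all(pos$utr5_end <= pos$cds_start & pos$cds_end <= pos$utr3_start))
  neg <- g[g$strand == "-", ]
  expect_true(all(neg$utr3_end <= neg$cds_start & neg$cds_end <= neg$utr5_start))
})

test_that("empty reference (n_genes = 0) exports a GTF with zero records", {
  cfg <- synth_config(rng_seed = 1, n_genes = 0, n_mirnas = 3,
                      sites_per_mirna = 0)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$genes), 0)
  expect_equal(nrow(gene_feature_table(ref)), 0)
  dir <- withr::local_tempdir()
  paths <- write_reference(ref, dir)
  gtf_lines <- readLines(paths[["gtf"]])
  expect_equal(length(gtf_lines[!grepl("^#", gtf_lines) & nzchar(gtf_lines)]), 0)
})

test_that("written reference files are byte-identical across runs", {
  cfg <- small_config(rng_seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(generate_reference(cfg), d1)
  write_reference(generate_reference(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted site sequences on the transcript strand equal their match string", {
  ref <- generate_reference(small_config(rng_seed = 5))
  got <- cluster_sequences(ref$sites, ref$genome)
  expect_identical(got$seq, got$match)
  # every planted site lies inside its declared gene region
  joined <- dplyr::left_join(ref$sites, ref$genes, by = "gene_id")
  reg_start <- dplyr::case_when(
    joined$region == "3UTR" ~ joined$utr3_start,
    joined$region == "CDS" ~ joined$cds_start,
    TRUE ~ joined$utr5_start
  )
  reg_end <- dplyr::case_when(
    joined$region == "3UTR" ~ joined$utr3_end,
    joined$region == "CDS" ~ joined$cds_end,
    TRUE ~ joined$utr5_end
  )
  expect_true(all(joined$start.x >= reg_start & joined$end.x <= reg_end))
})

test_that("truth table is complete and references only existing entities", {
  cfg <- small_config(rng_seed = 13)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$sites), cfg$n_mirnas * cfg$sites_per_mirna)
  expect_equal(anyDuplicated(ref$sites[, c("chrom", "start", "end")]), 0L)
  expect_true(all(ref$sites$gene_id %in% ref$genes$gene_id))
  expect_true(all(ref$sites$mirna %in% ref$mirnas$name))
  expect_true(all(unlist(strsplit(ref$sites$active_stages, ",")) %in% cfg$stages))
})

test_that("with zero background every tag covers a planted site", {
  cfg <- synth_config(rng_seed = 2, n_chroms = 1, chrom_length = 50000,
                      n_genes = 2, n_mirnas = 1, sites_per_mirna = 1,
                      site_rate = 50, background_rate = 0, off_activity = 0)
  ref <- generate_reference(cfg)
  clip <- simulate_clip_tags(ref)
  site <- ref$sites
  expect_gt(nrow(clip$tags), 0)
  expect_true(all(clip$tags$start <= site$start & clip$tags$end >= site$end))
  expect_true(all(clip$tags$chrom == site$chrom))
  # activity gating: tags only in the site's active stage
  expect_setequal(unique(clip$tags$stage), site$active_stages)
  # all tags inside chromosome bounds
  expect_true(all(clip$tags$start >= 0 & clip$tags$end <= cfg$chrom_length))
})

test_that("per-site tag counts are Poisson with the configured mean", {
  base <- synth_config(rng_seed = 2, n_chroms = 1, chrom_length = 50000,
                       n_genes = 2, n_mirnas = 1, sites_per_mirna = 1,
                       stages = "adult", n_replicates = 1,
                       site_rate = 50, background_rate = 0, off_activity = 0)
  ref <- generate_reference(base)
  n_sim <- 500
  counts <- vapply(seq_len(n_sim), function(i) {
    cfg_i <- synth_config(rng_seed = 1000 + i, n_chroms = 1,
                          chrom_length = 50000, n_genes = 2, n_mirnas = 1,
                          sites_per_mirna = 1, stages = "adult",
                          n_replicates = 1, site_rate = 50,
                          background_rate = 0, off_activity = 0)
    nrow(simulate_clip_tags(ref, cfg_i)$tags)
  }, numeric(1))
  se <- sqrt(50 / n_sim)
  expect_lt(abs(mean(counts) - 50), 3 * se)
})

test_that("knockout log2FC simulation plants the configured shift", {
  universe <- sprintf("g%04d", 1:2000)
  targets <- universe[1:500]

  # planted mean recovered within Monte-Carlo error
  fc <- simulate_log2fc(universe, targets, shift = 0.5, sigma = 0.5, seed = 7)
  expect_equal(nrow(fc), length(universe))
  expect_equal(anyDuplicated(fc$gene_id), 0L)
  se <- 0.5 / sqrt(500)
  expect_lt(abs(mean(fc$log2fc[fc$gene_id %in% targets]) - 0.5), 3 * se)

  # noise-free limit
  fc0 <- simulate_log2fc(universe, targets, shift = 1, sigma = 1e-9, seed = 7)
  expect_true(all(abs(fc0$log2fc[fc0$gene_id %in% targets] - 1) < 1e-6))
  expect_true(all(abs(fc0$log2fc[!fc0$gene_id %in% targets]) < 1e-6))

  # null case: target and background draws are exchangeable
  fcn <- simulate_log2fc(universe, targets, shift = 0, sigma = 0.5, seed = 7)
  p <- suppressWarnings(stats::ks.test(
    fcn$log2fc[fcn$gene_id %in% targets],
    fcn$log2fc[!fcn$gene_id %in% targets]
  )$p.value)
  expect_gt(p, 0.01)

  # unknown target gene is a consistency error
  expect_error(simulate_log2fc(universe, "nope", 0.5, 0.5, 1), "absent")
})

test_that("simulate_ko_expression marks exactly the planted targets", {
  ref <- generate_reference(small_config(rng_seed = 3))
  ko_mirna <- ref$mirnas$name[1]
  fc <- simulate_ko_expression(ref, ko_mirna)
  planted <- unique(ref$sites$gene_id[ref$sites$mirna == ko_mirna])
  expect_setequal(fc$gene_id[fc$is_target], planted)
  expect_equal(nrow(fc), nrow(ref$genes))
  expect_error(simulate_ko_expression(ref, "mir-xyz"), "unknown miRNA")
})

test_that("H3K27ac truth plants the requested super-enhancer fraction near miRNA TSSs", {
  cfg <- synth_config(rng_seed = 8, n_genes = 10, n_mirnas = 8,
                      se_fraction = 0.1, n_h3k27ac_regions = 10,
                      chrom_length = 400000, n_chroms = 2)
  ref <- generate_reference(cfg)
  h3 <- simulate_h3k27ac(ref)
  expect_equal(nrow(h3$truth), 10)
  expect_equal(sum(h3$truth$is_SE), 1)   # round(0.1 * 10)
  se <- h3$truth[h3$truth$is_SE, ]
  expect_true(se$mirna %in% ref$mirnas$name)
  expect_lte(abs(se$tss_distance), 100000)
  tss <- ref$mirnas[ref$mirnas$name == se$mirna, ]
  expect_identical(se$chrom, tss$chrom)

  # se_fraction = 0 plants nothing
  cfg0 <- synth_config(rng_seed = 8, n_genes = 10, n_mirnas = 8,
                       se_fraction = 0, n_h3k27ac_regions = 10,
                       chrom_length = 400000, n_chroms = 2)
  h30 <- simulate_h3k27ac(generate_reference(cfg0))
  expect_equal(sum(h30$truth$is_SE), 0)
})

test_that("planted site coverage clears the background 99th percentile", {
  # asserted over 20 seeds: at >= 95% of planted sites, pooled-tag coverage
  # at the site exceeds the 99th percentile of background per-base coverage
  # empirical 99th percentile of per-base coverage over a whole chromosome
  # strand (planted sites occupy a negligible base fraction)
  cov_q99 <- function(tg, chrom_len) {
    if (nrow(tg) == 0) return(0)
    cov <- IRanges::coverage(IRanges::IRanges(tg$start + 1L, tg$end),
                             width = chrom_len)
    vals <- S4Vectors::runValue(cov)
    lens <- S4Vectors::runLength(cov)
    o <- order(vals)
    cum <- cumsum(lens[o])
    vals[o][which(cum >= 0.99 * chrom_len)[1]]
  }
  hits <- 0L
  total <- 0L
  for (s in 1:20) {
    cfg <- small_config(rng_seed = 500 + s)
    ref <- generate_reference(cfg)
    clip <- simulate_clip_tags(ref)
    for (i in seq_len(nrow(ref$sites))) {
      site <- ref$sites[i, ]
      st <- strsplit(site$active_stages, ",")[[1]][1]
      tg <- clip$tags[clip$tags$stage == st & clip$tags$chrom == site$chrom &
                        clip$tags$strand == site$strand, ]
      cov_at_site <- sum(tg$start <= site$start & tg$end >= site$end)
      total <- total + 1L
      if (cov_at_site > cov_q99(tg, cfg$chrom_length)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
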