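test_that("seed match strings are the Watson-Crick complements of the seed", {
  ms <- seed_match_strings("UGGACCCUAGG")
  expect_equal(ms$match[ms$site_type == "6mer"], "GGGTCC")
  expect_equal(ms$match[ms$site_type == "7mer-m8"], "AGGGTCC")
  expect_equal(ms$match[ms$site_type == "7mer-A1"], "GGGTCCA")
  expect_equal(ms$match[ms$site_type == "8mer"], "AGGGTCCA")

  # boundary length: an 8 nt miRNA still defines all four strings
  ms8 <- seed_match_strings("UGGACCCU")
  expect_equal(nrow(ms8), 4)
  expect_false(any(is.na(ms8$match)))

  expect_error(seed_match_strings("UGGACCCTAGG"), "RNA alphabet")
  expect_error(seed_match_strings("UGGACCC"), "at least 8")
})

test_that("match strings round-trip to the seed over random catalogs", {
  set.seed(19)
  for (i in 1:100) {
    cat1 <- random_catalog(1)
    ms <- seed_match_strings(cat1$seq)
    core <- ms$match[ms$site_type == "6mer"]
    # reverse-complementing the core (via Biostrings) must read back the seed
    back <- chartr("T", "U", as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(core))
    ))
    expect_identical(back, substr(cat1$seq, 2, 7))
    m7 <- ms$match[ms$site_type == "7mer-m8"]
    back7 <- chartr("T", "U", as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(m7))
    ))
    expect_identical(back7, substr(cat1$seq, 2, 8))
  }
})

test_that("scanner reports the dominant site type per locus", {
  catalog <- tibble::tibble(name = "mir-x", seq = "UGGACCCUAGGCAGUGCAAU")
  hit <- scan_sequence("TTAGGGTCCATT", catalog)
  expect_equal(nrow(hit), 1)  # one locus, reported once as 8mer
  expect_equal(hit$site_type, "8mer")
  expect_equal(hit$offset, 2L)

  two <- scan_sequence("GGGTCCGGGTCC", catalog)
  expect_equal(two$site_type, c("6mer", "6mer"))
  expect_equal(two$offset, c(0L, 6L))

  expect_equal(nrow(scan_sequence("TTTTTTTTTTTT", catalog)), 0)
  expect_equal(nrow(scan_sequence("", catalog)), 0)
})

test_that("scanner equals the brute-force enumeration oracle", {
  set.seed(23)
  for (i in 1:100) {
    catalog <- random_catalog(sample(1:4, 1))
    seq <- random_dna_seq(sample(20:80, 1))
    got <- scan_sequence(seq, catalog)
    exp <- oracle_scan(seq, catalog)
    expect_equal(got$mirna, exp$mirna)
    expect_equal(got$offset, exp$offset)
    expect_equal(got$site_type, exp$site_type)
    expect_equal(got$match, exp$match)
  }
})

test_that("no-noise synthetic study recovers every planted interaction", {
  cfg <- small_config(rng_seed = 31, background_rate = 0, off_activity = 0)
  ref <- generate_reference(cfg)
  clip <- simulate_clip_tags(ref)
  cl <- call_clusters(clip$tags)
  lab <- annotate_clusters(cl, gene_feature_table(ref))
  ia <- build_targetome(lab, ref$genome, ref$mirnas, expressed = NULL)

  planted <- dplyr::distinct(ref$sites, mirna, gene_id, region)
  found <- dplyr::distinct(ia, mirna, gene_id, region)
  expect_equal(nrow(dplyr::anti_join(planted, found,
                                     by = c("mirna", "gene_id", "region"))), 0)
})

test_that("interactions respect stage gating of planted sites", {
  cfg <- small_config(rng_seed = 37, background_rate = 0, off_activity = 0)
  ref <- generate_reference(cfg)
  clip <- simulate_clip_tags(ref)
  lab <- annotate_clusters(call_clusters(clip$tags), gene_feature_table(ref))
  ia <- build_targetome(lab, ref$genome, ref$mirnas, expressed = NULL)
  planted <- dplyr::inner_join(
    ia, dplyr::select(ref$sites, mirna, gene_id, region, active_stages),
    by = c("mirna", "gene_id", "region")
  )
  # every interaction involving a planted (mirna, gene, region) occurs in
  # that site's active stage (no tags elsewhere at off_activity = 0)
  expect_true(all(planted$stage == planted$active_stages))
})

test_that("minus-strand sites are only found after reverse-complement extraction", {
  # hand-built genome: plant the 8mer match AGGGTCCA as its reverse
  # complement on the reference, gene on the minus strand
  catalog <- tibble::tibble(name = "mir-x", seq = "UGGACCCUAGGCAGUGCAAU")
  insert <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTAGGGTCCATT")
  ))
  left <- "ACGTACGTACGTACGTACGT"
  right <- "TGCATGCATGCATGCATGCA"
  genome <- Biostrings::DNAStringSet(paste0(left, insert, right))
  names(genome) <- "chrM"
  cl <- tibble::tibble(
    cluster_id = "c1", chrom = "chrM",
    start = nchar(left), end = nchar(left) + nchar(insert)
  )
  plus <- scan_sequence(cluster_sequences(dplyr::mutate(cl, strand = "+"),
                                          genome)$seq, catalog)
  minus <- scan_sequence(cluster_sequences(dplyr::mutate(cl, strand = "-"),
                                           genome)$seq, catalog)
  expect_equal(nrow(plus), 0)
  expect_equal(minus$site_type, "8mer")
})

test_that("seed coverage fraction counts clusters with any site and is monotone", {
  catalog <- random_catalog(6)
  set.seed(41)
  noise <- vapply(1:10, function(i) random_dna_seq(40), character(1))
  core1 <- seed_match_strings(catalog$seq[1])
  with_site <- paste0(substr(noise[1:6], 1, 20),
                      core1$match[core1$site_type == "8mer"],
                      substr(noise[1:6], 21, 40))
  clusters <- tibble::tibble(seq = c(with_site, noise[7:10]))

  expect_equal(seed_coverage_fraction(clusters,
                                      catalog_subset = catalog[0, ]), 0)
  frac1 <- seed_coverage_fraction(clusters, catalog_subset = catalog[1, ])
  expect_gte(frac1, 0.6)
  fracs <- vapply(1:6, function(k) {
    seed_coverage_fraction(clusters, catalog_subset = catalog[1:k, ])
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_error(seed_coverage_fraction(clusters[0, ], catalog_subset = catalog),
               "no clusters")
})

test_that("target set comparison is exact set arithmetic", {
  same <- compare_target_sets(c("a", "b"), c("b", "a"))
  expect_equal(same$n_common, 2)
  expect_equal(same$n_a_only, 0)
  expect_equal(same$n_b_only, 0)

  cmp <- compare_target_sets(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(cmp$n_common, 2)
  expect_equal(cmp$n_a_only, 1)
  expect_equal(cmp$n_b_only, 2)
  expect_equal(cmp$frac_a_shared, 2 / 3)
})

test_that("validated-target worked example yields a 50% detected fraction", {
  # synthetic stand-in for an externally validated miR-122 target list:
  # 42 genes of which 21 are in the CLIP-identified target set
  fixture <- read.delim(system.file("extdata",
                                    "synthetic_validated_mir122_targets.tsv",
                                    package = "agoclip"))
  clip_targets <- c(fixture$gene_id[fixture$detected_by_clip],
                    sprintf("synOther%03d", 1:30))
  cmp <- compare_target_sets(clip_targets, fixture$gene_id)
  expect_equal(cmp$n_b, 42)
  expect_equal(cmp$n_common, 21)
  expect_equal(cmp$frac_b_shared, 0.5)
})

test_that("top_expressed ranks by RPM with lexicographic ties", {
  profiles <- tibble::tibble(
    mirna = c("b", "a", "c"), stage = "s1", rpm = c(5e5, 3e5, 2e5)
  )
  expect_equal(top_expressed(profiles, "s1", 2), c("b", "a"))
  tie <- tibble::tibble(mirna = c("b", "a"), stage = "s1", rpm = c(5e5, 5e5))
  expect_equal(top_expressed(tie, "s1", 1), "a")
})
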