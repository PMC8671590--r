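mk_peaks <- function(start, end, score, chrom = "c1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), score = score)
}

test_that("stitching honours the boundary-inclusive gap rule", {
  # gap of exactly 12500 stitches
  p <- mk_peaks(c(0, 12600), c(100, 12700), c(1, 1))
  expect_equal(nrow(stitch_peaks(p)), 1)
  # gap of 12501 does not
  p2 <- mk_peaks(c(0, 12601), c(100, 12701), c(1, 1))
  expect_equal(nrow(stitch_peaks(p2)), 2)
  # single peak: identity
  one <- stitch_peaks(mk_peaks(5, 105, 3.5))
  expect_equal(one$start, 5L)
  expect_equal(one$end, 105L)
  expect_equal(one$signal, 3.5)
  expect_equal(one$n_constituents, 1L)

  expect_error(stitch_peaks(mk_peaks(0, 10, -1)), "non-negative")
})

test_that("input subtraction clips constituent signal at zero", {
  p <- mk_peaks(c(0, 200), c(100, 300), c(5, 2))
  p$input_score <- c(1, 4)
  st <- stitch_peaks(p, stitch_distance = 1000)
  expect_equal(st$signal, 4)  # (5-1) + max(0, 2-4)
})

test_that("stitching equals the pairwise-chaining oracle", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    start <- sort(sample.int(100000, n))
    p <- mk_peaks(start, start + sample(50:500, n, replace = TRUE),
                  stats::runif(n, 0, 10),
                  chrom = sample(c("c1", "c2"), n, replace = TRUE))
    dist <- sample(c(0, 1000, 12500), 1)
    got <- stitch_peaks(p, stitch_distance = dist)
    exp <- oracle_stitch(p, dist)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$signal, exp$signal, tolerance = 1e-9)
    expect_equal(got$n_constituents, exp$n)
  }
})

test_that("hockey-stick cutoff isolates the disproportionate tail", {
  res <- hockey_stick_cutoff(c(1, 2, 3, 100))
  expect_equal(res$cutoff, 3)
  expect_identical(res$is_SE, c(FALSE, FALSE, FALSE, TRUE))

  expect_warning(flat <- hockey_stick_cutoff(rep(5, 10)), "all signals equal")
  expect_equal(sum(flat$is_SE), 0)
  expect_equal(flat$cutoff, 5)

  expect_error(hockey_stick_cutoff(c(1, 2)), "at least 3")
})

test_that("SE count is monotone non-increasing in the slope threshold", {
  set.seed(29)
  signals <- c(rgamma(90, 4, scale = 2.5), rgamma(10, 4, scale = 50))
  n_se <- vapply(c(0.5, 1, 2), function(t) {
    sum(hockey_stick_cutoff(signals, slope_threshold = t)$is_SE)
  }, numeric(1))
  expect_true(all(diff(n_se) <= 0))
})

test_that("bimodal planted signals are recovered as super-enhancers", {
  recovered <- 0L
  for (s in 1:2) {
    set.seed(700 + s)
    signals <- c(rgamma(90, 4, scale = 2.5), rgamma(10, 4, scale = 50))
    flags <- hockey_stick_cutoff(signals)$is_SE
    recovered <- recovered + sum(flags[91:100])
  }
  expect_gte(recovered / 20, 0.9)
})

test_that("tibble interface ranks regions and attaches the cutoff", {
  st <- tibble::tibble(
    region_id = sprintf("r%d", 1:4), chrom = "c1",
    start = c(0L, 1000L, 2000L, 3000L), end = c(10L, 1010L, 2010L, 3010L),
    n_constituents = 1L, signal = c(1, 2, 3, 100)
  )
  out <- hockey_stick_cutoff(st)
  expect_equal(attr(out, "cutoff"), 3)
  expect_equal(out$rank, 1:4)
  expect_equal(out$scaled_x, (1:4) / 4)
  expect_equal(out$scaled_y, c(0.01, 0.02, 0.03, 1))
  expect_s3_class(plot_hockey_stick(out), "ggplot")
})

test_that("TSS assignment picks the nearest site within the window", {
  regions <- tibble::tibble(region_id = "r1", chrom = "c1",
                            start = 100000L, end = 110000L)
  tss <- tibble::tibble(
    id = c("geneX", "mirY", "geneZ"), class = c("gene", "miRNA", "gene"),
    chrom = "c1", position = c(160000L, 190000L, 105000L)
  )
  # TSS inside the region
  a <- assign_se_to_tss(regions, tss)
  expect_equal(a$tss_id, "geneZ")
  expect_equal(a$distance, 0L)

  # nearest of two outside candidates (50 kb beats 80 kb)
  a2 <- assign_se_to_tss(regions, tss[1:2, ])
  expect_equal(a2$tss_id, "geneX")
  expect_equal(a2$distance, 160000L - 110000L + 1L)

  # all beyond the window: unassigned
  far <- tibble::tibble(id = "geneF", class = "gene", chrom = "c1",
                        position = 260001L)
  a3 <- assign_se_to_tss(regions, far)
  expect_true(is.na(a3$tss_id))

  # distance tie prefers the miRNA class
  tie <- tibble::tibble(
    id = c("geneT", "mirT"), class = c("gene", "miRNA"), chrom = "c1",
    position = c(100000L - 5000L, 110000L + 5000L - 1L)
  )
  a4 <- assign_se_to_tss(regions, tie)
  expect_equal(a4$tss_id, "mirT")
})

test_that("stage-dynamic planted SEs are flagged only in their active stage", {
  cfg <- synth_config(rng_seed = 44, n_genes = 10, n_mirnas = 10,
                      se_fraction = 0.2, n_h3k27ac_regions = 20,
                      chrom_length = 450000)
  ref <- generate_reference(cfg)
  h3 <- simulate_h3k27ac(ref, stages = ref$stages)
  se_truth <- h3$truth[h3$truth$is_SE, ]
  # pick two planted SEs active in different stages
  stopifnot(length(unique(se_truth$active_stages)) >= 2)
  a <- se_truth[1, ]
  b <- se_truth[se_truth$active_stages != a$active_stages, ][1, ]

  flag_for <- function(se_row, st) {
    pk <- h3$peaks[h3$peaks$stage == st, ]
    flagged <- hockey_stick_cutoff(stitch_peaks(pk))
    ov <- flagged$chrom == se_row$chrom &
      flagged$start <= se_row$start & flagged$end >= se_row$end
    any(flagged$is_SE[ov])
  }
  # each SE is called in its own active stage, not in the other's
  expect_true(flag_for(a, a$active_stages))
  expect_true(flag_for(b, b$active_stages))
  expect_false(flag_for(a, b$active_stages))
  expect_false(flag_for(b, a$active_stages))
})

test_that("planted SE truth is recovered end to end with TSS assignment", {
  cfg <- synth_config(rng_seed = 50, n_genes = 10, n_mirnas = 10,
                      se_fraction = 0.1, n_h3k27ac_regions = 20,
                      chrom_length = 450000)
  ref <- generate_reference(cfg)
  h3 <- simulate_h3k27ac(ref)
  flagged <- hockey_stick_cutoff(stitch_peaks(h3$peaks))
  expect_equal(sum(flagged$is_SE), sum(h3$truth$is_SE))
  se_truth <- dplyr::arrange(h3$truth[h3$truth$is_SE, ], chrom, start)
  se_called <- dplyr::arrange(flagged[flagged$is_SE, ], chrom, start)
  expect_equal(se_called$start, se_truth$start)
  expect_equal(se_called$end, se_truth$end)
  # every called SE is assigned a miRNA TSS within the window, and the
  # assignment is at least as close as the designated miRNA
  mir_tss <- ref$tss[ref$tss$class == "miRNA", ]
  asg <- dplyr::arrange(
    dplyr::left_join(assign_se_to_tss(se_called, mir_tss), se_called,
                     by = "region_id"),
    chrom, start
  )
  expect_false(any(is.na(asg$tss_id)))
  expect_true(all(abs(asg$distance) <= abs(se_truth$tss_distance)))
})
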