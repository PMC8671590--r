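#' Configuration for the synthetic HITS-CLIP study generator
#'
#' Builds a validated configuration object for the synthetic-data generators
#' ([generate_reference()], [simulate_clip_tags()], [simulate_mirna_counts()],
#' [simulate_ko_expression()], [simulate_h3k27ac()]). The defaults describe a
#' miniature five-stage developmental study (e12.5, e15.5, e18.5, P7, adult)
#' with two biological replicates per stage, mirroring the design of an Ago
#' HITS-CLIP time course on developing mouse liver.
#'
#' @param rng_seed Integer seed; every generator output is a pure function of
#'   the configuration and this seed.
#' @param n_chroms,chrom_length Number of chromosomes and their common length
#'   in bases.
#' @param n_genes Number of protein-coding gene models to place (each with
#'   5'UTR, CDS and 3'UTR on one strand; may be 0).
#' @param n_mirnas Number of miRNAs in the catalog (mature length 20-24 nt).
#' @param stages Character vector of stage labels (default the five
#'   developmental stages).
#' @param n_replicates Biological replicates per stage.
#' @param sites_per_mirna Planted seed-match target sites per miRNA.
#' @param site_rate Expected CLIP tags per planted site per replicate in a
#'   stage where the site is active (Poisson mean).
#' @param background_rate Expected background tags per kilobase per strand per
#'   replicate file (homogeneous Poisson process).
#' @param off_activity Relative activity of a planted site outside its miRNA's
#'   enriched stage (0 for a hard on/off design).
#' @param region_weights Named numeric weights over `3UTR`, `CDS`, `5UTR`
#'   giving where planted sites land.
#' @param tag_len_mean,tag_len_sd Tag length model: lengths are a discretised
#'   Normal clipped to \[18, 40\], so the modal tag length is 22 nt by default.
#' @param ko_shift Planted mean log2 fold change (KO vs WT) for true targets
#'   of the knocked-out miRNA.
#' @param ko_sigma Standard deviation of log2 fold-change noise.
#' @param se_fraction Fraction of stitched H3K27ac regions planted as
#'   super-enhancers (in \[0, 1)).
#' @param n_h3k27ac_regions Number of stitched H3K27ac regions to plant.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(rng_seed = 1, n_genes = 10, n_mirnas = 5)
#' cfg$stages
synth_config <- function(rng_seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 500000L,
                         n_genes = 40L,
                         n_mirnas = 25L,
                         stages = c("e12.5", "e15.5", "e18.5", "P7", "adult"),
                         n_replicates = 2L,
                         sites_per_mirna = 3L,
                         site_rate = 30,
                         background_rate = 0.2,
                         off_activity = 0.05,
                         region_weights = c("3UTR" = 0.6, "CDS" = 0.3, "5UTR" = 0.1),
                         tag_len_mean = 22,
                         tag_len_sd = 1.5,
                         ko_shift = 0.5,
                         ko_sigma = 0.5,
                         se_fraction = 0.1,
                         n_h3k27ac_regions = 30L) {
  assert_scalar_number(rng_seed, "rng_seed")
  assert_scalar_number(n_chroms, "n_chroms", min = 1)
  assert_scalar_number(chrom_length, "chrom_length", min = 1000)
  assert_scalar_number(n_genes, "n_genes", min = 0)
  assert_scalar_number(n_mirnas, "n_mirnas", min = 0)
  if (!is.character(stages) || length(stages) < 1 || anyDuplicated(stages)) {
    rlang::abort("`stages` must be a character vector of distinct labels")
  }
  assert_scalar_number(n_replicates, "n_replicates", min = 1)
  assert_scalar_number(sites_per_mirna, "sites_per_mirna", min = 0)
  assert_scalar_number(site_rate, "site_rate", min = 0, strict_min = TRUE)
  assert_scalar_number(background_rate, "background_rate", min = 0)
  assert_scalar_number(off_activity, "off_activity", min = 0, max = 1)
  assert_scalar_number(tag_len_mean, "tag_len_mean", min = 15, max = 60)
  assert_scalar_number(tag_len_sd, "tag_len_sd", min = 0)
  assert_scalar_number(ko_sigma, "ko_sigma", min = 0)
  assert_scalar_number(se_fraction, "se_fraction", min = 0)
  if (se_fraction >= 1) rlang::abort("`se_fraction` must be in [0, 1)")
  assert_scalar_number(n_h3k27ac_regions, "n_h3k27ac_regions", min = 3)
  if (!all(c("3UTR", "CDS", "5UTR") %in% names(region_weights)) ||
      any(region_weights < 0) || sum(region_weights) <= 0) {
    rlang::abort("`region_weights` must be non-negative weights named 3UTR, CDS, 5UTR")
  }
  # Planted sites must rise above background coverage: expected background tags
  # over a site footprint (~8 bp) must stay below the per-site Poisson mean.
  if (site_rate <= background_rate * 8 / 1000) {
    rlang::abort("`site_rate` must exceed expected background tags over a site span")
  }

  structure(
    list(
      rng_seed = as.integer(rng_seed),
      n_chroms = as.integer(n_chroms),
      chrom_length = as.integer(chrom_length),
      n_genes = as.integer(n_genes),
      n_mirnas = as.integer(n_mirnas),
      stages = stages,
      n_replicates = as.integer(n_replicates),
      sites_per_mirna = as.integer(sites_per_mirna),
      site_rate = site_rate,
      background_rate = background_rate,
      off_activity = off_activity,
      region_weights = region_weights / sum(region_weights),
      tag_len_mean = tag_len_mean,
      tag_len_sd = tag_len_sd,
      ko_shift = ko_shift,
      ko_sigma = ko_sigma,
      se_fraction = se_fraction,
      n_h3k27ac_regions = as.integer(n_h3k27ac_regions)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %d chrom(s) x %d bp, %d genes, %d miRNAs\n",
              x$n_chroms, x$chrom_length, x$n_genes, x$n_mirnas))
  cat(sprintf("  stages: %s; %d replicate(s)\n",
              paste(x$stages, collapse = ", "), x$n_replicates))
  cat(sprintf("  site_rate %.3g tags/site, background %.3g tags/kb, seed %d\n",
              x$site_rate, x$background_rate, x$rng_seed))
  invisible(x)
}
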