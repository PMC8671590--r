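#' Assemble a pipeline configuration
#'
#' Bundles the synthetic-study configuration with every stage threshold the
#' pipeline uses. All thresholds mirror the defaults of the corresponding
#' stage functions.
#'
#' @param synth A [synth_config()] describing the study to simulate.
#' @param min_peak_height,min_replicates Cluster-calling filters
#'   ([call_clusters()]).
#' @param k Number of stage-profile groups ([cluster_stage_profiles()]).
#' @param kmer_k,n_shuffles Motif-enrichment parameters ([kmer_enrichment()]).
#' @param stitch_distance,tss_window Super-enhancer parameters
#'   ([stitch_peaks()], [assign_se_to_tss()]).
#' @param pseudocount Pseudocount for stage log2 fold changes.
#' @param expressed_threshold Profile-relative expression threshold
#'   ([expressed_mirnas()]).
#' @param top_n Catalog size for the "top expressed" seed-coverage readout.
#' @param ko_mirna miRNA knocked out in the simulated expression comparison;
#'   `NULL` picks the miRNA with the most distinct 3'UTR target genes (ties
#'   broken lexicographically).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            min_peak_height = 5L, min_replicates = 2L,
                            k = 5L, kmer_k = 7L, n_shuffles = 50L,
                            stitch_distance = 12500, tss_window = 100000,
                            pseudocount = 1, expressed_threshold = 0.5,
                            top_n = 100L, ko_mirna = NULL) {
  stopifnot(inherits(synth, "synth_config"))
  structure(
    list(synth = synth, min_peak_height = min_peak_height,
         min_replicates = min_replicates, k = k, kmer_k = kmer_k,
         n_shuffles = n_shuffles, stitch_distance = stitch_distance,
         tss_window = tss_window, pseudocount = pseudocount,
         expressed_threshold = expressed_threshold, top_n = top_n,
         ko_mirna = ko_mirna),
    class = "pipeline_config"
  )
}

#' Run the full HITS-CLIP analysis pipeline on a synthetic study
#'
#' Executes every stage in dependency order — reference simulation, CLIP tag
#' simulation, cluster calling, feature annotation, miRNA profiling and stage
#' clustering, targetome construction, seed coverage, motif enrichment,
#' knockout KS shift, and super-enhancer identification — writing each
#' stage's outputs under `outdir` together with `summary.json` and
#' `manifest.tsv`. Re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `summary` (the summary statistics, also
#'   written as JSON) and `manifest` (tibble of written files).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  note <- function(path) { files <<- c(files, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)))
    })
  }

  ref <- stage("reference", generate_reference(config$synth))
  for (p in write_reference(ref, file.path(outdir, "reference"))) note(p)

  clip <- stage("clip_tags", simulate_clip_tags(ref))
  man <- write_tags_bed(clip$tags, file.path(outdir, "tags"))
  for (p in c(man$path, file.path(outdir, "tags", "manifest.tsv"))) note(p)

  clusters <- stage("clusters", call_clusters(
    clip$tags, min_peak_height = config$min_peak_height,
    min_replicates = config$min_replicates
  ))
  write_clusters_bed(clusters, note(file.path(outdir, "clusters.bed")))

  feats <- gene_feature_table(ref)
  labeled <- stage("annotate", annotate_clusters(clusters, feats))
  readr::write_tsv(labeled, note(file.path(outdir, "clusters_annotated.tsv")),
                   progress = FALSE)
  fd <- stage("annotate", feature_distribution(labeled))
  readr::write_tsv(fd, note(file.path(outdir, "feature_distribution.tsv")),
                   progress = FALSE)

  counts <- stage("profiles", simulate_mirna_counts(ref))
  profiles <- stage("profiles", quantify_mirnas(counts))
  readr::write_tsv(profiles, note(file.path(outdir, "mirna_profiles.tsv")),
                   progress = FALSE)
  expressed <- expressed_mirnas(profiles, config$expressed_threshold)
  assignments <- stage("profiles", cluster_stage_profiles(
    profiles, k = min(config$k, nrow(ref$mirnas))
  ))
  readr::write_tsv(assignments, note(file.path(outdir, "stage_clusters.tsv")),
                   progress = FALSE)
  writeLines(attr(assignments, "newick"),
             note(file.path(outdir, "stage_clusters.nwk")))

  interactions <- stage("targetome", build_targetome(
    labeled, ref$genome, ref$mirnas, expressed
  ))
  readr::write_tsv(interactions, note(file.path(outdir, "interactions.tsv")),
                   progress = FALSE)
  tcounts <- target_counts(interactions)
  readr::write_tsv(tcounts, note(file.path(outdir, "target_counts.tsv")),
                   progress = FALSE)

  utr3 <- labeled[labeled$feature == "3UTR", ]
  seed_cov <- if (nrow(utr3) > 0) {
    utr3_seq <- cluster_sequences(utr3, ref$genome)
    top_names <- unique(unlist(lapply(
      names(expressed),
      function(s) top_expressed(profiles, s, config$top_n)
    )))
    list(
      top_expressed = seed_coverage_fraction(
        utr3_seq, catalog_subset = ref$mirnas[ref$mirnas$name %in% top_names, ]
      ),
      all_mirnas = seed_coverage_fraction(utr3_seq, catalog_subset = ref$mirnas)
    )
  } else {
    list(top_expressed = NA_real_, all_mirnas = NA_real_)
  }

  motif_summary <- stage("motifs", {
    purrr::map(setNames(nm = config$synth$stages), function(st) {
      seqs <- cluster_sequences(utr3[utr3$stage == st, ], ref$genome)$seq
      seqs <- seqs[nchar(seqs) >= config$kmer_k]
      if (length(seqs) < 3) return(NULL)
      tab <- kmer_enrichment(seqs, k = config$kmer_k,
                             n_shuffles = config$n_shuffles,
                             rng_seed = derive_seed(config$synth$rng_seed, 606L))
      tab <- match_motifs_to_seeds(tab, ref$mirnas, expressed[[st]])
      list(top_kmer = tab$kmer[1], z = tab$z[1],
           matched = tab$matched_mirnas[1])
    })
  })

  ks_summary <- stage("ko_shift", {
    utr3_targets <- interactions |>
      dplyr::filter(.data$region == "3UTR") |>
      dplyr::distinct(.data$mirna, .data$gene_id) |>
      dplyr::count(.data$mirna)
    if (nrow(utr3_targets) == 0) {
      NULL
    } else {
      ko_mirna <- config$ko_mirna %||%
        utr3_targets$mirna[order(-utr3_targets$n, utr3_targets$mirna)][1]
      ko <- simulate_ko_expression(ref, ko_mirna)
      seed_genes <- scan_gene_regions(
        feats, ref$genome, ref$mirnas[ref$mirnas$name == ko_mirna, ]
      )$gene_id
      part <- partition_genes(interactions, ko_mirna, seed_genes,
                              ko$gene_id)
      fc <- dplyr::left_join(part, ko, by = "gene_id")
      ks_clip <- ks_shift_test(
        fc$log2fc[fc$label == "clip_target"],
        fc$log2fc[fc$label == "background"], method = "asymptotic"
      )
      readr::write_tsv(ks_clip$ecdf, note(file.path(outdir, "ks_ecdf.tsv")),
                       progress = FALSE)
      list(ko_mirna = ko_mirna,
           n_clip_target = sum(part$label == "clip_target"),
           n_seed_only = sum(part$label == "seed_only"),
           n_background = sum(part$label == "background"),
           D = ks_clip$D, p = ks_clip$p)
    }
  })

  se_summary <- stage("superenhancer", {
    h3 <- simulate_h3k27ac(ref)
    stitched <- stitch_peaks(h3$peaks,
                             stitch_distance = config$stitch_distance)
    flagged <- hockey_stick_cutoff(stitched)
    write_bed6(
      dplyr::mutate(flagged, name = .data$region_id, score = .data$signal),
      note(file.path(outdir, "stitched_regions.bed")),
      extra_cols = "is_SE"
    )
    assignments_se <- assign_se_to_tss(
      flagged[flagged$is_SE, ], ref$tss, window = config$tss_window
    )
    readr::write_tsv(assignments_se,
                     note(file.path(outdir, "se_assignments.tsv")),
                     progress = FALSE)
    list(n_regions = nrow(flagged), n_SE = sum(flagged$is_SE),
         cutoff = attr(flagged, "cutoff"),
         assigned = assignments_se$tss_id)
  })

  summary <- list(
    rng_seed = config$synth$rng_seed,
    n_tags = nrow(clip$tags),
    modal_tag_length = modal_length(tag_length_distribution(clip$tags)),
    n_clusters = nrow(clusters),
    clusters_per_stage = as.list(table(clusters$stage)),
    feature_fractions = setNames(as.list(fd$fraction), fd$feature),
    seed_coverage = seed_cov,
    n_interactions = nrow(interactions),
    stage_cluster_sizes = as.list(table(assignments$cluster)),
    stage_cluster_stages = sort(unique(assignments$enriched_stage)),
    motifs = motif_summary,
    ks = ks_summary,
    superenhancers = se_summary
  )
  json_path <- note(file.path(outdir, "summary.json"))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  manifest <- tibble::tibble(path = files, exists = file.exists(files))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  invisible(list(summary = summary, manifest = manifest))
}
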