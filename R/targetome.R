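#' Extract strand-aware cluster sequences from a genome
#'
#' Returns each cluster's sequence in transcript (sense) orientation: the
#' reference slice for `+` clusters, its reverse complement for `-` clusters.
#'
#' @param clusters Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return The input tibble with a `seq` character column.
#' @export
cluster_sequences <- function(clusters, genome) {
  assert_cols(clusters, c("chrom", "start", "end", "strand"))
  if (nrow(clusters) == 0) return(dplyr::mutate(clusters, seq = character(0)))
  bad_chrom <- setdiff(unique(clusters$chrom), names(genome))
  if (length(bad_chrom) > 0) {
    rlang::abort(sprintf("chromosome(s) not in genome: %s",
                         paste(bad_chrom, collapse = ", ")))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  oob <- which(clusters$start < 0 | clusters$end > lens[clusters$chrom])
  if (length(oob) > 0) {
    id <- if ("cluster_id" %in% names(clusters)) {
      clusters$cluster_id[oob[1]]
    } else {
      as.character(oob[1])
    }
    rlang::abort(sprintf("cluster %s lies outside chromosome bounds", id))
  }
  seqs <- as.character(Biostrings::subseq(
    genome[clusters$chrom], start = clusters$start + 1L, end = clusters$end
  ))
  neg <- clusters$strand == "-"
  seqs[neg] <- revcomp_dna(seqs[neg])
  dplyr::mutate(clusters, seq = unname(seqs))
}

#' Build the miRNA-mRNA interaction table (targetome)
#'
#' Scans every genic annotated cluster, in sense orientation, against the
#' miRNAs expressed in that cluster's stage, recording one interaction row per
#' (miRNA, cluster, seed locus) with the strongest site type at the locus.
#'
#' @param labeled Annotated cluster tibble ([annotate_clusters()] output;
#'   intergenic clusters are skipped).
#' @param genome A [Biostrings::DNAStringSet].
#' @param catalog miRNA tibble with `name`, `seq`.
#' @param expressed Optional named list: stage label -> character vector of
#'   expressed miRNA names ([expressed_mirnas()] output). `NULL` scans the
#'   whole catalog in every stage.
#' @return Interaction tibble: `mirna`, `gene_id`, `cluster_id`, `region`,
#'   `site_type`, `stage`, `offset`.
#' @export
build_targetome <- function(labeled, genome, catalog, expressed = NULL) {
  assert_cols(labeled, c("cluster_id", "chrom", "start", "end", "strand",
                         "stage", "feature", "gene_id"))
  empty <- tibble::tibble(
    mirna = character(), gene_id = character(), cluster_id = character(),
    region = character(), site_type = character(), stage = character(),
    offset = integer()
  )
  genic <- labeled |>
    dplyr::filter(.data$feature != "intergenic", !is.na(.data$gene_id))
  if (nrow(genic) == 0) return(empty)
  genic <- cluster_sequences(genic, genome)

  out <- purrr::pmap(
    list(genic$cluster_id, genic$gene_id, genic$feature, genic$stage,
         genic$seq),
    function(cluster_id, gene_id, region, stage, seq) {
      cat_stage <- if (is.null(expressed)) {
        catalog
      } else {
        catalog[catalog$name %in% (expressed[[stage]] %||% character(0)), ]
      }
      if (nrow(cat_stage) == 0) return(NULL)
      hits <- scan_sequence(seq, cat_stage)
      if (nrow(hits) == 0) return(NULL)
      tibble::tibble(
        mirna = hits$mirna, gene_id = gene_id, cluster_id = cluster_id,
        region = region, site_type = hits$site_type, stage = stage,
        offset = hits$offset
      )
    }
  ) |> dplyr::bind_rows()
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$stage, .data$mirna, .data$gene_id, .data$offset)
}

#' Per-miRNA target-gene counts by region
#'
#' Collapses an interaction table to unique target genes per (miRNA, region),
#' the shape in which per-miRNA targetomes are usually reported.
#'
#' @param interactions [build_targetome()] output.
#' @return Tibble with `mirna`, `region`, `n_genes`.
#' @export
target_counts <- function(interactions) {
  assert_cols(interactions, c("mirna", "gene_id", "region"))
  interactions |>
    dplyr::distinct(.data$mirna, .data$region, .data$gene_id) |>
    dplyr::count(.data$mirna, .data$region, name = "n_genes")
}

#' Fraction of clusters containing at least one seed site
#'
#' @param clusters Cluster tibble (typically 3'UTR-annotated) with `chrom`,
#'   `start`, `end`, `strand`, or with a precomputed `seq` column.
#' @param genome A [Biostrings::DNAStringSet]; ignored when `clusters$seq`
#'   exists.
#' @param catalog_subset miRNA tibble (`name`, `seq`); an empty subset gives
#'   fraction 0. The fraction is monotone non-decreasing in the subset.
#' @return A single number in \[0, 1\].
#' @export
seed_coverage_fraction <- function(clusters, genome = NULL, catalog_subset) {
  if (nrow(clusters) == 0) {
    rlang::abort("no clusters: seed coverage undefined")
  }
  if (nrow(catalog_subset) == 0) return(0)
  if (!"seq" %in% names(clusters)) {
    clusters <- cluster_sequences(clusters, genome)
  }
  has_site <- vapply(clusters$seq, function(s) {
    nrow(scan_sequence(s, catalog_subset)) > 0
  }, logical(1))
  mean(has_site)
}

#' Top-n expressed miRNAs of a stage
#'
#' Ranks miRNAs by stage RPM (ties broken lexicographically by name) and
#' returns the top `n` names, the "top expressed" subset used for seed
#' coverage.
#'
#' @param profiles [quantify_mirnas()] output.
#' @param stage Stage label.
#' @param n Number of miRNAs to keep.
#' @return Character vector of miRNA names.
#' @export
top_expressed <- function(profiles, stage, n) {
  assert_cols(profiles, c("mirna", "stage", "rpm"))
  sub <- profiles[profiles$stage == stage, ]
  if (nrow(sub) == 0) rlang::abort(sprintf("unknown stage `%s`", stage))
  sub <- dplyr::arrange(sub, dplyr::desc(.data$rpm), .data$mirna)
  utils::head(sub$mirna, n)
}

#' Compare two target gene sets
#'
#' Plain set arithmetic behind targetome comparisons (e.g. CLIP-identified
#' targets vs an externally validated list): intersection and set-difference
#' counts plus the fraction of each set shared.
#'
#' @param set_a,set_b Character vectors of gene identifiers (duplicates are
#'   collapsed).
#' @return One-row tibble: `n_a`, `n_b`, `n_common`, `n_a_only`, `n_b_only`,
#'   `frac_a_shared`, `frac_b_shared`.
#' @export
#' @examples
#' compare_target_sets(c("a", "b", "c"), c("b", "c", "d", "e"))
compare_target_sets <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  common <- length(intersect(a, b))
  tibble::tibble(
    n_a = length(a), n_b = length(b), n_common = common,
    n_a_only = length(a) - common, n_b_only = length(b) - common,
    frac_a_shared = if (length(a) == 0) NA_real_ else common / length(a),
    frac_b_shared = if (length(b) == 0) NA_real_ else common / length(b)
  )
}

#' Genes with a seed match anywhere in an annotated region
#'
#' Scans the full annotated region (default the whole 3'UTR) of every gene for
#' seed sites of one miRNA — the "purely seed-predicted" gene set used as a
#' comparison class for CLIP-identified targets.
#'
#' @param features Feature tibble ([gene_feature_table()] /
#'   [read_gene_models()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param catalog miRNA tibble (`name`, `seq`), typically one row.
#' @param region Feature label to scan (default `"3UTR"`).
#' @return Tibble with `gene_id`, `mirna` for every gene carrying >= 1 site.
#' @export
scan_gene_regions <- function(features, genome, catalog, region = "3UTR") {
  assert_cols(features, c("gene_id", "chrom", "strand", "feature",
                          "start", "end"))
  reg <- features[features$feature == region, ]
  if (nrow(reg) == 0) {
    return(tibble::tibble(gene_id = character(), mirna = character()))
  }
  reg <- cluster_sequences(reg, genome)
  out <- purrr::pmap(list(reg$gene_id, reg$seq), function(gene_id, seq) {
    hits <- scan_sequence(seq, catalog)
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(gene_id = gene_id, mirna = unique(hits$mirna))
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(), mirna = character()))
  }
  dplyr::distinct(out)
}
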