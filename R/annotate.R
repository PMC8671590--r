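#' Annotate clusters to transcript features at their summit
#'
#' Each cluster is assigned exactly one feature label by the position of its
#' summit (the Ago footprint centre): if the summit falls in features of
#' several transcripts, the priority 3UTR > 5UTR > CDS > ncRNA_exon > intron
#' decides (any transcript of any gene may claim the summit — union
#' annotation). A cluster is genic only when its strand matches the gene
#' strand; otherwise, or when nothing overlaps, it is `intergenic`.
#'
#' @param clusters Cluster tibble from [call_clusters()] (needs `chrom`,
#'   `strand`, `summit`).
#' @param features Feature tibble from [gene_feature_table()] or
#'   [read_gene_models()].
#' @param priority Character vector ordering genic labels, strongest first.
#' @return The cluster tibble with `feature` (one of 3UTR, 5UTR, CDS,
#'   ncRNA_exon, intron, intergenic) and `gene_id` (`NA` for intergenic).
#' @export
annotate_clusters <- function(clusters, features,
                              priority = c("3UTR", "5UTR", "CDS",
                                           "ncRNA_exon", "intron")) {
  assert_cols(clusters, c("chrom", "strand", "summit"))
  assert_cols(features, c("gene_id", "chrom", "strand", "feature",
                          "start", "end"))
  if (nrow(clusters) == 0) {
    return(dplyr::mutate(clusters, feature = character(0),
                         gene_id = character(0)))
  }
  unknown_chrom <- setdiff(unique(clusters$chrom), unique(features$chrom))
  if (length(unknown_chrom) > 0 && nrow(features) > 0) {
    rlang::warn(sprintf(
      "chromosome(s) absent from gene models (annotated intergenic): %s",
      paste(unknown_chrom, collapse = ", ")
    ))
  }

  if (nrow(features) == 0) {
    return(dplyr::mutate(clusters, feature = "intergenic",
                         gene_id = NA_character_))
  }

  feat_gr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1L, features$end),
    strand = features$strand
  )
  summit_gr <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$summit + 1L, width = 1L),
    strand = clusters$strand
  )
  GenomeInfoDb::seqlevels(summit_gr) <- union(
    GenomeInfoDb::seqlevels(summit_gr), GenomeInfoDb::seqlevels(feat_gr)
  )
  GenomeInfoDb::seqlevels(feat_gr) <- GenomeInfoDb::seqlevels(summit_gr)
  ov <- GenomicRanges::findOverlaps(summit_gr, feat_gr)  # strand-aware

  hit <- tibble::tibble(
    cl = S4Vectors::queryHits(ov),
    feature = features$feature[S4Vectors::subjectHits(ov)],
    gene_id = features$gene_id[S4Vectors::subjectHits(ov)]
  ) |>
    dplyr::mutate(rank = match(.data$feature, priority)) |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::arrange(.data$cl, .data$rank, .data$gene_id) |>
    dplyr::distinct(.data$cl, .keep_all = TRUE)

  clusters$feature <- "intergenic"
  clusters$gene_id <- NA_character_
  clusters$feature[hit$cl] <- hit$feature
  clusters$gene_id[hit$cl] <- hit$gene_id
  clusters
}

#' Genomic feature distribution of annotated clusters
#'
#' @param labeled Output of [annotate_clusters()].
#' @return Tibble with `feature`, `n`, `fraction` over all six labels
#'   (fractions sum to 1).
#' @export
feature_distribution <- function(labeled) {
  assert_cols(labeled, "feature")
  if (nrow(labeled) == 0) {
    rlang::abort("no labeled clusters: feature distribution undefined")
  }
  labels <- c(.feature_priority, "intergenic")
  labeled |>
    dplyr::count(feature = factor(.data$feature, levels = labels),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(feature = as.character(.data$feature),
                  fraction = .data$n / sum(.data$n))
}
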