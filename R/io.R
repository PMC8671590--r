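# Plain BED6(+extra) readers/writers. BED is 0-based half-open, no header.

.bed6_cols <- c("chrom", "start", "end", "name", "score", "strand")

#' Read a BED6(+extra) file into a tibble
#'
#' @param path File path.
#' @param extra_cols Names for any columns beyond the six BED fields.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open) plus any `extra_cols`.
#' @export
read_bed6 <- function(path, extra_cols = character(0)) {
  df <- readr::read_tsv(
    path, col_names = c(.bed6_cols, extra_cols),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      name = readr::col_character(),
      strand = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  tibble::as_tibble(df)
}

#' Write a tibble as BED6(+extra)
#'
#' Columns beyond the six BED fields are appended in the given order.
#'
#' @param df Tibble with at least `chrom`, `start`, `end`; missing `name`,
#'   `score`, `strand` are filled with `"."`, `0`, `"."`.
#' @param path Output path.
#' @param extra_cols Extra column names to append after the BED6 fields.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(df, path, extra_cols = character(0)) {
  assert_cols(df, c("chrom", "start", "end"))
  out <- tibble::tibble(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0L,
    strand = if ("strand" %in% names(df)) df$strand else "."
  )
  for (col in extra_cols) out[[col]] <- df[[col]]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write per-(stage, replicate) CLIP tag BED6 files
#'
#' One `tags_<stage>_rep<k>.bed` per combination (name = tag id, score = 1),
#' plus a `manifest.tsv` mapping each file to its stage and replicate.
#'
#' @param tags Tag tibble as returned by [simulate_clip_tags()].
#' @param dir Output directory.
#' @return Invisibly, the manifest tibble (`path`, `stage`, `replicate`).
#' @export
write_tags_bed <- function(tags, dir) {
  assert_cols(tags, c("chrom", "start", "end", "strand", "stage", "replicate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  combos <- dplyr::distinct(tags, .data$stage, .data$replicate)
  manifest <- purrr::pmap(combos, function(stage, replicate) {
    sub <- tags[tags$stage == stage & tags$replicate == replicate, ]
    path <- file.path(dir, sprintf("tags_%s_rep%d.bed", stage, replicate))
    sub$score <- 1L
    write_bed6(sub, path)
    tibble::tibble(path = path, stage = stage, replicate = replicate)
  }) |> dplyr::bind_rows()
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Read CLIP tags from per-file BED6 via a stage/replicate manifest
#'
#' @param manifest Tibble (or path to a TSV) with columns `path`, `stage`,
#'   `replicate`.
#' @return One tag tibble with `stage` and `replicate` columns.
#' @export
read_tags_bed <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  assert_cols(manifest, c("path", "stage", "replicate"))
  purrr::pmap(manifest, function(path, stage, replicate, ...) {
    read_bed6(path) |>
      dplyr::mutate(stage = stage, replicate = replicate)
  }) |> dplyr::bind_rows()
}

#' Read gene models from a GTF/GFF file into a feature table
#'
#' Imports `exon` and `CDS` records (via \pkg{rtracklayer}) and derives, per
#' transcript, the strand-resolved 5'UTR, 3'UTR and intron intervals; exons of
#' transcripts without any CDS become `ncRNA_exon`. `gene_id` and
#' `transcript_id` attributes are required.
#'
#' @param path GTF2.2 / GFF3 file path.
#' @return Feature tibble with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `feature`, `start`, `end` (0-based half-open), the input format of
#'   [annotate_clusters()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  keep <- tolower(as.character(gr$type)) %in% c("exon", "cds")
  gr <- gr[keep]
  if (length(gr) == 0) {
    return(tibble::tibble(
      gene_id = character(), transcript_id = character(), chrom = character(),
      strand = character(), feature = character(),
      start = integer(), end = integer()
    ))
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id)) {
    rlang::abort("GTF/GFF must carry gene_id and transcript_id attributes")
  }
  df <- tibble::tibble(
    type = tolower(as.character(gr$type)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr)
  )
  split(df, df$transcript_id) |>
    purrr::map(derive_transcript_features) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Turn one transcript's exon/CDS rows into disjoint feature intervals.
derive_transcript_features <- function(tx) {
  exons <- tx[tx$type == "exon", ]
  cds <- tx[tx$type == "cds", ]
  if (nrow(exons) == 0) exons <- cds
  strand <- exons$strand[1]
  chrom <- exons$chrom[1]
  gene_id <- exons$gene_id[1]
  transcript_id <- exons$transcript_id[1]

  exon_ir <- IRanges::reduce(IRanges::IRanges(exons$start + 1L, exons$end))
  feat <- list()
  add <- function(ir, label) {
    if (length(ir) == 0) return()
    feat[[length(feat) + 1]] <<- tibble::tibble(
      gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
      strand = strand, feature = label,
      start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir)
    )
  }

  # introns: gaps between exons
  add(IRanges::gaps(exon_ir,
                    start = min(BiocGenerics::start(exon_ir)),
                    end = max(BiocGenerics::end(exon_ir))), "intron")

  if (nrow(cds) == 0) {
    add(exon_ir, "ncRNA_exon")
  } else {
    cds_ir <- IRanges::reduce(IRanges::IRanges(cds$start + 1L, cds$end))
    add(cds_ir, "CDS")
    utr <- IRanges::setdiff(exon_ir, cds_ir)
    if (length(utr) > 0) {
      cds_lo <- min(BiocGenerics::start(cds_ir))
      cds_hi <- max(BiocGenerics::end(cds_ir))
      left <- utr[BiocGenerics::end(utr) < cds_lo]
      right <- utr[BiocGenerics::start(utr) > cds_hi]
      if (strand == "-") {
        add(left, "3UTR"); add(right, "5UTR")
      } else {
        add(left, "5UTR"); add(right, "3UTR")
      }
    }
  }
  dplyr::bind_rows(feat)
}
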