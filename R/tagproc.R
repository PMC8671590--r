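#' Tag length distribution and modal length
#'
#' CLIP tags mark Ago footprints; the miRNA-driven mode of the tag length
#' distribution sits at 22 nt in a well-behaved library, so the histogram is a
#' first-line QC readout.
#'
#' @param tags Tag tibble with 0-based half-open `start`, `end`.
#' @return Tibble with `length` and `n`, one row per observed length, sorted by
#'   length. The modal length (ties resolved to the smallest length) is
#'   attached as attribute `"modal_length"` and retrievable with
#'   [modal_length()].
#' @export
#' @examples
#' tags <- tibble::tibble(start = c(0, 5, 10), end = c(22, 27, 40))
#' modal_length(tag_length_distribution(tags))
tag_length_distribution <- function(tags) {
  assert_cols(tags, c("start", "end"))
  if (nrow(tags) == 0) rlang::abort("no tags: length distribution undefined")
  len <- tags$end - tags$start
  if (any(len <= 0)) rlang::abort("malformed tag interval: start >= end")
  dist <- tibble::tibble(length = len) |>
    dplyr::count(.data$length, name = "n") |>
    dplyr::arrange(.data$length)
  mode <- dist$length[dist$n == max(dist$n)][1]  # ties -> smallest length
  attr(dist, "modal_length") <- mode
  dist
}

#' @rdname tag_length_distribution
#' @param dist A distribution tibble from [tag_length_distribution()], or a raw
#'   tag tibble.
#' @export
modal_length <- function(dist) {
  if (!is.null(attr(dist, "modal_length"))) return(attr(dist, "modal_length"))
  attr(tag_length_distribution(dist), "modal_length")
}

#' Call Ago-binding clusters from aligned CLIP tags
#'
#' Overlapping same-strand tags within a stage (replicates pooled) are grouped
#' into clusters: two tags belong to one cluster iff they are connected by a
#' chain of interval overlaps of at least one shared base (bookended tags do
#' not merge). Each cluster records its tag count, peak height (PH, the
#' maximum per-base tag depth), summit (leftmost base attaining PH) and
#' replicate support; clusters below `min_peak_height` or `min_replicates`
#' are discarded.
#'
#' @param tags Tag tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `stage`, `replicate`.
#' @param min_peak_height Minimum peak height to keep a cluster.
#' @param min_replicates Minimum number of replicates contributing at least
#'   one tag.
#' @return Tibble of clusters sorted by (`stage`, `chrom`, `start`):
#'   `cluster_id`, `chrom`, `start`, `end`, `strand`, `stage`, `tag_count`,
#'   `peak_height`, `summit` (0-based), `replicate_support`.
#' @export
#' @examples
#' tags <- tibble::tibble(
#'   chrom = "chr1", start = c(100L, 110L), end = c(122L, 132L),
#'   strand = "+", stage = "adult", replicate = c(1L, 2L)
#' )
#' call_clusters(tags, min_peak_height = 2)
call_clusters <- function(tags, min_peak_height = 5L, min_replicates = 2L) {
  assert_cols(tags, c("chrom", "start", "end", "strand", "stage", "replicate"))
  assert_scalar_number(min_peak_height, "min_peak_height", min = 1)
  assert_scalar_number(min_replicates, "min_replicates", min = 1)
  empty <- tibble::tibble(
    cluster_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), stage = character(),
    tag_count = integer(), peak_height = integer(), summit = integer(),
    replicate_support = integer()
  )
  if (nrow(tags) == 0) return(empty)
  bad <- which(tags$start >= tags$end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "malformed tag interval (start >= end) at row %d: %s:%d-%d",
      bad[1], tags$chrom[bad[1]], tags$start[bad[1]], tags$end[bad[1]]
    ))
  }

  groups <- tags |>
    dplyr::group_by(.data$stage, .data$chrom, .data$strand) |>
    dplyr::group_split()

  out <- purrr::map(groups, function(g) {
    ir <- IRanges::IRanges(g$start + 1L, g$end)
    # min.gapwidth = 0 merges only truly overlapping ranges (>= 1 shared base)
    regions <- IRanges::reduce(ir, min.gapwidth = 0L)
    if (length(regions) == 0) return(NULL)
    cov <- IRanges::coverage(ir)
    v <- IRanges::Views(cov, BiocGenerics::start(regions),
                        BiocGenerics::end(regions))
    peak <- IRanges::viewMaxs(v)
    summit1 <- IRanges::viewWhichMaxs(v)  # leftmost position of the max
    hits <- IRanges::countOverlaps(regions, ir, minoverlap = 1L)
    ov <- IRanges::findOverlaps(regions, ir, minoverlap = 1L)
    rep_support <- tibble::tibble(
      region = S4Vectors::queryHits(ov),
      replicate = g$replicate[S4Vectors::subjectHits(ov)]
    ) |>
      dplyr::distinct() |>
      dplyr::count(.data$region, name = "replicate_support")
    tibble::tibble(
      chrom = g$chrom[1],
      start = BiocGenerics::start(regions) - 1L,
      end = BiocGenerics::end(regions),
      strand = g$strand[1],
      stage = g$stage[1],
      tag_count = as.integer(hits),
      peak_height = as.integer(peak),
      summit = as.integer(summit1) - 1L,
      replicate_support = rep_support$replicate_support[
        match(seq_along(regions), rep_support$region)
      ]
    )
  }) |> dplyr::bind_rows()

  out <- out |>
    dplyr::filter(.data$peak_height >= min_peak_height,
                  .data$replicate_support >= min_replicates) |>
    dplyr::arrange(.data$stage, .data$chrom, .data$start)
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::mutate(cluster_id = sprintf("%s_c%05d", .data$stage,
                                       dplyr::row_number()),
                  .before = "chrom")
}

#' Write called clusters as BED6+3
#'
#' name = cluster id, score = peak height; extra columns `tag_count`,
#' `summit`, `replicate_support`.
#'
#' @param clusters Cluster tibble from [call_clusters()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_bed <- function(clusters, path) {
  clusters |>
    dplyr::mutate(name = .data$cluster_id, score = .data$peak_height) |>
    write_bed6(path, extra_cols = c("tag_count", "summit", "replicate_support"))
}
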