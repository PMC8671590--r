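#' Stitch H3K27ac peaks into candidate enhancer regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap is at most
#' `stitch_distance` (boundary-inclusive, strandless) are chained into one
#' stitched region; region signal is the sum of constituent scores. When an
#' `input_score` column is present, each constituent contributes
#' `max(0, score - input_score)` (input subtraction).
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `score` (>= 0), optionally `input_score`.
#' @param stitch_distance Maximum gap in bases (default 12500, the published
#'   ROSE default).
#' @return Tibble sorted by (`chrom`, `start`): `region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, `signal`.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  assert_cols(peaks, c("chrom", "start", "end", "score"))
  assert_scalar_number(stitch_distance, "stitch_distance", min = 0)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_constituents = integer(), signal = numeric()))
  }
  if (any(peaks$score < 0)) rlang::abort("peak scores must be non-negative")
  if (any(peaks$start >= peaks$end)) {
    rlang::abort("malformed peak interval: start >= end")
  }
  signal <- if ("input_score" %in% names(peaks)) {
    pmax(0, peaks$score - peaks$input_score)
  } else {
    peaks$score
  }
  peaks |>
    dplyr::mutate(.signal = signal) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .prev_end = dplyr::lag(cummax(.data$end)),
      .gap_break = !is.na(.data$.prev_end) &
        .data$start - .data$.prev_end > stitch_distance,
      .region = cumsum(.data$.gap_break)
    ) |>
    dplyr::group_by(.data$chrom, .data$.region) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_constituents = dplyr::n(), signal = sum(.data$.signal),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(region_id = sprintf("sr%05d", dplyr::row_number()),
                  .before = "chrom") |>
    dplyr::select("region_id", "chrom", "start", "end", "n_constituents",
                  "signal")
}

#' Hockey-stick cutoff separating super-enhancers
#'
#' Implements the ROSE tangent rule on the rank-signal ("hockey stick")
#' curve in discrete form: signals are sorted ascending, both axes are scaled
#' to \[0, 1\], and the cutoff is the signal at the point where a line of
#' slope `slope_threshold` is tangent to the curve — the first point
#' minimising `scaled_y - slope_threshold * scaled_x`. Regions with signal
#' strictly above the cutoff are flagged super-enhancers. The tangent point
#' of an all-equal signal vector is the curve's right end, so no region is
#' flagged and a warning is raised.
#'
#' @param stitched Tibble from [stitch_peaks()] (needs `signal`), or a bare
#'   numeric vector of signals.
#' @param slope_threshold Scaled-slope threshold (default 1, the tangent
#'   slope of the ROSE rule).
#' @return For tibble input, the tibble with `rank`, `scaled_x`, `scaled_y`
#'   and `is_SE` columns and the cutoff as attribute `"cutoff"`; for vector
#'   input, a list with `cutoff` and logical `is_SE` in input order.
#' @export
#' @examples
#' hockey_stick_cutoff(c(1, 2, 3, 100))$is_SE
hockey_stick_cutoff <- function(stitched, slope_threshold = 1) {
  vec_input <- is.numeric(stitched)
  signals <- if (vec_input) stitched else stitched$signal
  N <- length(signals)
  if (N < 3) rlang::abort("need at least 3 regions for a hockey-stick cutoff")
  if (any(!is.finite(signals)) || any(signals < 0)) {
    rlang::abort("signals must be finite and non-negative")
  }

  y_sorted <- sort(signals)
  if (max(y_sorted) == min(y_sorted)) {
    rlang::warn("all signals equal: no hockey-stick elbow, zero super-enhancers")
    cutoff <- max(y_sorted)
  } else {
    sy <- y_sorted / max(y_sorted)
    sx <- seq_len(N) / N
    # tangent point of a slope-`slope_threshold` line on the scaled curve
    cutoff <- y_sorted[which.min(sy - slope_threshold * sx)]
  }
  is_se <- signals > cutoff

  if (vec_input) {
    return(list(cutoff = cutoff, is_SE = is_se))
  }
  out <- stitched
  out$rank <- rank(signals, ties.method = "first")
  out$scaled_x <- out$rank / N
  out$scaled_y <- signals / max(signals)
  out$is_SE <- is_se
  attr(out, "cutoff") <- cutoff
  out
}

#' Assign super-enhancers to the nearest TSS within a window
#'
#' Each region is assigned to the nearest transcription start site (gene or
#' miRNA) by distance from the region boundary: 0 when the TSS lies inside
#' the region, otherwise the signed base distance (negative upstream of the
#' region start, positive downstream of the region end). TSSs farther than
#' `window` leave the region unassigned (`tss_id = NA`). Distance ties prefer
#' the miRNA class, then the smaller coordinate.
#'
#' @param regions Stitched-region tibble (needs `region_id`, `chrom`,
#'   `start`, `end`; typically filtered to `is_SE`).
#' @param tss Tibble with `id`, `class` (`"gene"` or `"miRNA"`), `chrom`,
#'   `position` (0-based).
#' @param window Maximum absolute distance in bases (default 100000).
#' @return Tibble with `region_id`, `tss_id`, `tss_class`, `distance`.
#' @export
assign_se_to_tss <- function(regions, tss, window = 100000) {
  assert_cols(regions, c("region_id", "chrom", "start", "end"))
  assert_cols(tss, c("id", "class", "chrom", "position"))
  purrr::pmap(
    regions[, c("region_id", "chrom", "start", "end")],
    function(region_id, chrom, start, end) {
      cand <- tss[tss$chrom == chrom, ]
      if (nrow(cand) > 0) {
        dist <- ifelse(
          cand$position >= start & cand$position < end, 0L,
          ifelse(cand$position < start,
                 cand$position - start,
                 cand$position - end + 1L)
        )
        keep <- abs(dist) <= window
        cand <- cand[keep, ]
        dist <- dist[keep]
      } else {
        dist <- integer(0)
      }
      if (nrow(cand) == 0) {
        return(tibble::tibble(region_id = region_id, tss_id = NA_character_,
                              tss_class = NA_character_,
                              distance = NA_integer_))
      }
      o <- order(abs(dist), cand$class != "miRNA", cand$position)
      tibble::tibble(
        region_id = region_id,
        tss_id = cand$id[o[1]],
        tss_class = cand$class[o[1]],
        distance = as.integer(dist[o[1]])
      )
    }
  ) |> dplyr::bind_rows()
}
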