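#' Quantify Ago-bound miRNA abundance as reads per million (RPM)
#'
#' Pools replicate counts per (miRNA, stage) and normalises each stage to one
#' million miRNA-mapped tags: `RPM[m, s] = count[m, s] / sum_m count[m, s] *
#' 1e6`. miRNA mature lengths are nearly constant, so RPM reproduces a
#' length-normalised abundance axis up to a constant factor.
#'
#' @param counts Tibble with `mirna`, `stage`, `count` and optionally
#'   `replicate` (replicates are summed).
#' @return Tibble with `mirna`, `stage`, `count` (pooled), `rpm`.
#' @export
quantify_mirnas <- function(counts) {
  assert_cols(counts, c("mirna", "stage", "count"))
  if (nrow(counts) == 0) rlang::abort("no counts supplied")
  if (any(counts$count < 0) || any(counts$count != floor(counts$count))) {
    rlang::abort("`count` must be non-negative integers")
  }
  pooled <- counts |>
    dplyr::group_by(.data$mirna, .data$stage) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  totals <- pooled |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  dead <- totals$stage[totals$total == 0]
  if (length(dead) > 0) {
    rlang::abort(sprintf("stage(s) with all-zero counts: %s",
                         paste(dead, collapse = ", ")))
  }
  pooled |>
    dplyr::left_join(totals, by = "stage") |>
    dplyr::mutate(rpm = .data$count / .data$total * 1e6) |>
    dplyr::select("mirna", "stage", "count", "rpm") |>
    dplyr::arrange(.data$mirna, .data$stage)
}

#' Combined abundance share of the top-n miRNAs in a stage
#'
#' @param profiles [quantify_mirnas()] output.
#' @param stage Stage label.
#' @param n Number of top miRNAs (by RPM, ties broken lexicographically).
#' @return Fraction of the stage's total abundance carried by the top `n`
#'   miRNAs, in (0, 1\]; non-decreasing in `n`. If `n` exceeds the catalog the
#'   share over all miRNAs (1) is returned with a warning.
#' @export
top_share <- function(profiles, stage, n) {
  assert_cols(profiles, c("mirna", "stage", "rpm"))
  assert_scalar_number(n, "n", min = 1)
  sub <- profiles[profiles$stage == stage, ]
  if (nrow(sub) == 0) rlang::abort(sprintf("unknown stage `%s`", stage))
  if (n > nrow(sub)) {
    rlang::warn(sprintf("n = %d exceeds the %d catalogued miRNAs; share over all",
                        n, nrow(sub)))
    n <- nrow(sub)
  }
  sub <- dplyr::arrange(sub, dplyr::desc(.data$rpm), .data$mirna)
  sum(sub$rpm[seq_len(n)]) / sum(sub$rpm)
}

#' Per-miRNA log2 fold change between two stages
#'
#' `log2(RPM_b + pc) - log2(RPM_a + pc)` with a pseudocount `pc` (default
#' 1 RPM); exactly antisymmetric in the two stages.
#'
#' @param profiles [quantify_mirnas()] output.
#' @param stage_a,stage_b Baseline and comparison stage labels.
#' @param pseudocount Positive pseudocount in RPM units.
#' @return Tibble with `mirna`, `rpm_a`, `rpm_b`, `log2fc`.
#' @export
stage_log2fc <- function(profiles, stage_a, stage_b, pseudocount = 1) {
  assert_cols(profiles, c("mirna", "stage", "rpm"))
  assert_scalar_number(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  for (s in c(stage_a, stage_b)) {
    if (!s %in% profiles$stage) rlang::abort(sprintf("unknown stage `%s`", s))
  }
  a <- profiles[profiles$stage == stage_a, c("mirna", "rpm")]
  b <- profiles[profiles$stage == stage_b, c("mirna", "rpm")]
  dplyr::inner_join(a, b, by = "mirna", suffix = c("_a", "_b")) |>
    dplyr::mutate(log2fc = log2(.data$rpm_b + pseudocount) -
                    log2(.data$rpm_a + pseudocount)) |>
    dplyr::arrange(.data$mirna)
}

#' Cluster stage-resolved miRNA profiles into stage-enriched groups
#'
#' Rows (miRNAs) are z-scored across stages and clustered hierarchically with
#' correlation distance (1 - Pearson) and average linkage; the tree is cut
#' into `k` groups and each group is labelled by the stage at which its mean
#' z-profile peaks. Clustering by correlation of z-scored rows groups miRNAs
#' by expression *pattern*, not magnitude, so uniform rescaling of a profile
#' does not move it between groups.
#'
#' @param profiles [quantify_mirnas()] output.
#' @param k Number of groups (default 5, one per developmental stage).
#' @return Tibble of class `stage_clusters` with `mirna`, `cluster` (1..k),
#'   `enriched_stage`; the dendrogram is attached as attribute `"hclust"` and
#'   its Newick string as attribute `"newick"`.
#' @export
cluster_stage_profiles <- function(profiles, k = 5) {
  assert_cols(profiles, c("mirna", "stage", "rpm"))
  assert_scalar_number(k, "k", min = 1)
  wide <- profiles |>
    dplyr::select("mirna", "stage", "rpm") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "rpm")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$mirna
  if (ncol(m) < 2) rlang::abort("need at least two stages to cluster profiles")
  if (anyNA(m)) rlang::abort("profiles must cover every (mirna, stage) pair")

  constant <- apply(m, 1, function(r) sd(r) == 0)
  if (any(constant)) {
    rlang::warn(sprintf(
      "excluding %d constant-profile miRNA(s) (zero variance): %s",
      sum(constant), paste(head(rownames(m)[constant], 5), collapse = ", ")
    ))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < k) {
    rlang::abort(sprintf("k = %d exceeds the %d usable (non-constant) profiles",
                         k, nrow(m)))
  }
  z <- t(scale(t(m)))
  d <- as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, k = k)

  stage_names <- colnames(m)
  enriched <- vapply(seq_len(k), function(g) {
    zm <- colMeans(z[grp == g, , drop = FALSE])
    stage_names[which.max(zm)]
  }, character(1))

  out <- tibble::tibble(
    mirna = rownames(m),
    cluster = as.integer(grp),
    enriched_stage = enriched[grp]
  )
  attr(out, "hclust") <- hc
  attr(out, "newick") <- ape::write.tree(ape::as.phylo(hc))
  class(out) <- c("stage_clusters", class(out))
  out
}

#' miRNAs expressed in each stage
#'
#' A miRNA counts as expressed in a stage when its stage RPM reaches
#' `threshold` times its own maximum RPM across stages — a profile-relative
#' rule that tracks stage-restricted expression regardless of absolute
#' abundance.
#'
#' @param profiles [quantify_mirnas()] output.
#' @param threshold Fraction of the miRNA's maximum RPM (default 0.5).
#' @return Named list: stage label -> character vector of miRNA names.
#' @export
expressed_mirnas <- function(profiles, threshold = 0.5) {
  assert_cols(profiles, c("mirna", "stage", "rpm"))
  assert_scalar_number(threshold, "threshold", min = 0, max = 1)
  flagged <- profiles |>
    dplyr::group_by(.data$mirna) |>
    dplyr::mutate(expressed = .data$rpm >= threshold * max(.data$rpm)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$expressed)
  stages <- unique(profiles$stage)
  setNames(
    lapply(stages, function(s) sort(flagged$mirna[flagged$stage == s])),
    stages
  )
}
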