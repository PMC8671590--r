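#' Partition the expression universe into target / seed-only / background
#'
#' Genes with at least one Ago-bound CLIP site for the miRNA (in the chosen
#' region) are `clip_target`; genes with a seed match in the annotated region
#' but no CLIP site are `seed_only` (CLIP evidence dominates); everything else
#' in the universe is `background`. The three labels are mutually exclusive
#' and exhaustive over the universe.
#'
#' @param interactions Interaction tibble ([build_targetome()] output).
#' @param mirna miRNA name to partition for.
#' @param seed_genes Character vector of genes with a region-wide seed match
#'   ([scan_gene_regions()] output `gene_id`s).
#' @param universe Character vector of all genes in the expression table.
#' @param region Region label to restrict CLIP sites to (default `"3UTR"`;
#'   use `"CDS"` for the coding-region variant, or `NULL` for any region).
#' @return Tibble with `gene_id`, `label`.
#' @export
partition_genes <- function(interactions, mirna, seed_genes, universe,
                            region = "3UTR") {
  if (length(universe) == 0) rlang::abort("expression universe is empty")
  assert_cols(interactions, c("mirna", "gene_id", "region"))
  sub <- interactions[interactions$mirna == mirna, ]
  if (!is.null(region)) sub <- sub[sub$region == region, ]
  clip <- intersect(unique(sub$gene_id), universe)
  seed_only <- setdiff(intersect(seed_genes, universe), clip)
  tibble::tibble(gene_id = universe) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$gene_id %in% clip ~ "clip_target",
      .data$gene_id %in% seed_only ~ "seed_only",
      TRUE ~ "background"
    ))
}

#' One-sided two-sample Kolmogorov-Smirnov shift test
#'
#' Tests whether the `test` sample is stochastically shifted towards larger
#' values than `background` (alternative `"greater"`: de-repressed targets
#' move right, lowering their empirical CDF). The statistic is
#' `D = sup_x [F_background(x) - F_test(x)]` (roles swapped for
#' `"less"`), with right-continuous ECDFs evaluated at the pooled sample
#' points (ties need no jitter). The p-value is either the one-sided
#' asymptotic bound `exp(-2 D^2 m n / (m + n))` or, for small samples
#' (`m + n <= exact_threshold`) or on request, the exact permutation
#' probability over all `choose(m + n, m)` label assignments.
#'
#' @param test,background Numeric vectors of finite values (e.g. log2 fold
#'   changes of targets and background genes).
#' @param alternative `"greater"` (test shifted up; default) or `"less"`.
#' @param method `"auto"` (exact when `m + n <= exact_threshold`),
#'   `"asymptotic"`, or `"exact"`.
#' @param exact_threshold Largest `m + n` at which `"auto"` enumerates.
#' @return An object of class `ks_shift`: a list with `D`, `p`, `m`, `n`,
#'   `alternative`, `method`, and `ecdf` (tibble of both ECDFs at the pooled
#'   points, for plotting). Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' ks_shift_test(c(3, 4), c(1, 2), method = "exact")
ks_shift_test <- function(test, background,
                          alternative = c("greater", "less"),
                          method = c("auto", "asymptotic", "exact"),
                          exact_threshold = 16) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  m <- length(test)
  n <- length(background)
  if (m < 1 || n < 1) rlang::abort("both samples must be non-empty")
  if (!all(is.finite(test)) || !all(is.finite(background))) {
    rlang::abort("samples must contain only finite values")
  }

  D <- ks_shift_statistic(test, background, alternative)
  use_exact <- method == "exact" ||
    (method == "auto" && (m + n) <= exact_threshold)
  if (use_exact) {
    p <- ks_exact_p(test, background, D, alternative)
    method_used <- "exact_permutation"
  } else {
    p <- exp(-2 * D^2 * m * n / (m + n))
    method_used <- "asymptotic"
  }
  p <- min(max(p, .Machine$double.xmin), 1)

  pooled <- sort(unique(c(test, background)))
  ecdf_tab <- tibble::tibble(
    x = pooled,
    F_test = ecdf(test)(pooled),
    F_background = ecdf(background)(pooled)
  )
  structure(
    list(D = D, p = p, m = m, n = n, alternative = alternative,
         method = method_used, ecdf = ecdf_tab),
    class = "ks_shift"
  )
}

# D at pooled points; right-continuous ECDFs.
ks_shift_statistic <- function(test, background, alternative) {
  pooled <- sort(unique(c(test, background)))
  ft <- ecdf(test)(pooled)
  fb <- ecdf(background)(pooled)
  d <- if (alternative == "greater") fb - ft else ft - fb
  max(c(0, d))
}

# Exact permutation p-value: enumerate all C(m+n, m) assignments of the
# pooled values to the test sample; vectorised over assignment columns.
ks_exact_p <- function(test, background, D_obs, alternative) {
  m <- length(test)
  n <- length(background)
  sorted <- sort(c(test, background))
  N <- m + n
  # enumerate which sorted pooled ranks belong to the test sample; with tied
  # values duplicate assignments are counted with exactly the multiplicity
  # the permutation null assigns them
  combos <- combn(N, m)
  ind <- matrix(FALSE, N, ncol(combos))
  ind[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = m))] <- TRUE
  # at tied pooled values only the last row of the tie block is a valid
  # evaluation point of both right-continuous ECDFs
  valid <- c(sorted[-N] != sorted[-1], TRUE)
  cum_t <- apply(ind, 2, cumsum)
  rows <- seq_len(N)
  ft <- cum_t / m
  fb <- (rows - cum_t) / n
  diff <- if (alternative == "greater") fb - ft else ft - fb
  diff <- diff[valid, , drop = FALSE]
  D_all <- apply(diff, 2, max)
  D_all <- pmax(D_all, 0)
  mean(D_all >= D_obs - 1e-12)
}

#' @export
print.ks_shift <- function(x, ...) {
  cat("One-sided two-sample Kolmogorov-Smirnov shift test\n")
  cat(sprintf("  alternative: test sample shifted %s\n",
              if (x$alternative == "greater") "up" else "down"))
  cat(sprintf("  D = %.4g, p = %.4g (%s), m = %d, n = %d\n",
              x$D, x$p, x$method, x$m, x$n))
  invisible(x)
}

#' @rdname ks_shift_test
#' @param x A `ks_shift` object.
#' @param ... Unused.
#' @export
tidy.ks_shift <- function(x, ...) {
  tibble::tibble(
    statistic = x$D, p.value = x$p, m = x$m, n = x$n,
    alternative = x$alternative, method = x$method
  )
}

#' @rdname ks_shift_test
#' @export
glance.ks_shift <- function(x, ...) tidy.ks_shift(x)
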